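# Conventional atomic weights (Da).
.atomic_weights <- c(H = 1.008, B = 10.811, C = 12.011, N = 14.007,
                     O = 15.999, F = 18.998, P = 30.974, S = 32.067,
                     Cl = 35.453, Br = 79.904, I = 126.904)

as_molecule <- function(mol) {
  if (inherits(mol, "lit_molecule")) mol else parse_smiles(mol)
}

#' Molecular weight
#'
#' Sum of standard atomic weights over heavy atoms plus implicit hydrogens.
#' Additive over disconnected fragments (dot-separated SMILES).
#'
#' @param mol A `lit_molecule` or SMILES string.
#' @return Weight in Da.
#' @export
molecular_weight <- function(mol) {
  mol <- as_molecule(mol)
  el <- mol$atoms$element
  unknown <- setdiff(el, names(.atomic_weights))
  if (length(unknown)) stop("unknown element: ", unknown[1])
  sum(.atomic_weights[el]) +
    sum(mol$atoms$implicit_h) * .atomic_weights[["H"]]
}

#' Lipinski hydrogen-bond donor and acceptor counts
#'
#' The original rule-of-five conventions: donors are N or O atoms bearing at
#' least one hydrogen; acceptors are all N or O atoms.  (Toolkit-specific
#' donor/acceptor perception differs; this convention is pinned.)
#'
#' @param mol A `lit_molecule` or SMILES string.
#' @return Integer count.
#' @export
count_hbd <- function(mol) {
  mol <- as_molecule(mol)
  sum(mol$atoms$element %in% c("N", "O") & mol$atoms$implicit_h >= 1L)
}

#' @rdname count_hbd
#' @export
count_hba <- function(mol) {
  mol <- as_molecule(mol)
  sum(mol$atoms$element %in% c("N", "O"))
}

# is atom `a` part of any 3-membered ring?
in_three_ring <- function(mol, a) {
  any(vapply(mol$rings, function(r) length(r) == 3L && a %in% r, logical(1)))
}

#' Topological polar surface area (Ertl fragment contributions)
#'
#' Sums the published fragment contributions over nitrogen and oxygen
#' environments; with `extended = TRUE` sulfur and phosphorus environments
#' are included as well.  An environment missing from the contribution table
#' contributes 0 with a warning.
#'
#' @param mol A `lit_molecule` or SMILES string.
#' @param extended Include S and P contributions (default `FALSE`).
#' @return TPSA in square Angstroms.
#' @export
tpsa <- function(mol, extended = FALSE) {
  mol <- as_molecule(mol)
  total <- 0
  for (a in seq_len(nrow(mol$atoms))) {
    el <- mol$atoms$element[a]
    if (!(el %in% c("N", "O")) && !(extended && el %in% c("S", "P"))) next
    contrib <- tpsa_contribution(mol, a)
    if (is.na(contrib)) {
      warning("no TPSA contribution for ", el, " environment at atom ", a,
              "; contributing 0")
      contrib <- 0
    }
    total <- total + contrib
  }
  total
}

tpsa_contribution <- function(mol, a) {
  at <- mol$atoms[a, ]
  nb <- atom_neighbors(mol, a)
  nH <- at$implicit_h
  chg <- at$charge
  n_sing <- sum(nb$order == 1 & !nb$aromatic)
  n_doub <- sum(nb$order == 2)
  n_trip <- sum(nb$order == 3)
  n_arom <- sum(nb$aromatic)
  deg <- nrow(nb)
  three <- in_three_ring(mol, a)
  if (at$element == "O") {
    if (at$aromatic) return(13.14)
    if (chg < 0) return(23.06)
    if (n_doub >= 1) return(17.07)
    if (nH >= 1) return(20.23)
    if (n_sing == 2) return(if (three) 12.53 else 9.23)
    return(NA_real_)
  }
  if (at$element == "N") {
    if (at$aromatic) {
      if (chg > 0) {
        if (nH >= 1) return(14.14)
        if (n_sing >= 1) return(3.88)
        return(4.10)
      }
      if (nH >= 1) return(15.79)
      if (n_arom == 3) return(4.41)
      if (n_doub == 1) return(8.39)
      if (n_sing == 1) return(4.93)
      if (n_arom == 2 && deg == 2) return(12.89)
      return(NA_real_)
    }
    if (chg == 0) {
      if (nH == 0) {
        if (n_trip == 1 && n_doub == 1) return(13.60)
        if (n_trip == 1) return(23.79)
        if (n_doub == 2) return(11.68)  # uncharged nitro
        if (n_doub == 1 && n_sing >= 1) return(12.36)
        if (n_doub == 1 && deg == 1) return(12.36)
        if (n_sing == 3) return(if (three) 3.01 else 3.24)
      } else if (nH == 1) {
        if (n_doub == 1) return(23.85)
        if (n_sing == 2) return(if (three) 21.94 else 12.03)
      } else if (nH >= 2) {
        if (n_sing == 1) return(26.02)
      }
      return(NA_real_)
    }
    if (chg > 0) {
      if (nH == 0) {
        if (n_trip == 1) return(4.36)
        if (n_doub == 1) return(3.01)
        if (n_sing == 4) return(0.00)
      } else if (nH == 1) {
        if (n_doub == 1) return(13.97)
        if (n_sing == 3) return(4.44)
      } else if (nH == 2) {
        if (n_doub == 1) return(25.59)
        if (n_sing == 2) return(16.61)
      } else if (nH >= 3) {
        return(27.64)
      }
      return(NA_real_)
    }
    return(NA_real_)
  }
  if (at$element == "S") {
    if (at$aromatic) return(if (n_doub >= 1) 21.70 else 28.24)
    if (nH >= 1) return(38.80)
    if (n_doub == 2 && n_sing == 2) return(8.38)
    if (n_doub == 1 && n_sing == 2) return(19.21)
    if (n_doub == 1 && deg == 1) return(32.09)
    if (n_sing == 2) return(25.30)
    return(NA_real_)
  }
  if (at$element == "P") {
    if (n_doub == 1 && n_sing == 3) return(9.81)
    if (n_doub == 1 && nH >= 1) return(23.47)
    if (n_doub == 1 && n_sing >= 1) return(34.14)
    if (n_sing == 3) return(13.59)
    return(NA_real_)
  }
  NA_real_
}

#' Rotatable bond count
#'
#' Non-ring single bonds between two heavy atoms that each bear at least one
#' further heavy neighbor, excluding amide C-N bonds.
#'
#' @param mol A `lit_molecule` or SMILES string.
#' @return Integer count.
#' @export
rotatable_bonds <- function(mol) {
  mol <- as_molecule(mol)
  b <- mol$bonds
  if (nrow(b) == 0L) return(0L)
  deg <- integer(nrow(mol$atoms))
  for (k in seq_len(nrow(b))) {
    deg[b$a1[k]] <- deg[b$a1[k]] + 1L
    deg[b$a2[k]] <- deg[b$a2[k]] + 1L
  }
  is_amide_cn <- function(a_c, a_n) {
    if (mol$atoms$element[a_c] != "C" || mol$atoms$element[a_n] != "N") {
      return(FALSE)
    }
    nb <- atom_neighbors(mol, a_c)
    any(nb$order == 2 & mol$atoms$element[nb$nbr] == "O")
  }
  cnt <- 0L
  for (k in seq_len(nrow(b))) {
    if (b$in_ring[k] || b$aromatic[k] || b$order[k] != 1) next
    a1 <- b$a1[k]; a2 <- b$a2[k]
    if (deg[a1] < 2L || deg[a2] < 2L) next
    if (is_amide_cn(a1, a2) || is_amide_cn(a2, a1)) next
    cnt <- cnt + 1L
  }
  cnt
}

#' Band a clogP value
#'
#' `aqueous` below 0 (high affinity for the aqueous phase), `high` at or
#' above 5 (poor absorption/permeation), `optimal` in between; zero is not
#' negative, so 0 is `optimal`.
#'
#' @param clogp Finite numeric value.
#' @return One of `"aqueous"`, `"optimal"`, `"high"`.
#' @export
clogp_band <- function(clogp) {
  if (!is.finite(clogp)) stop("non-finite clogp")
  if (clogp < 0) "aqueous" else if (clogp >= 5.0) "high" else "optimal"
}

#' Hashed circular-environment fingerprint
#'
#' Morgan-style bits: each atom starts from an invariant (element, charge,
#' degree, hydrogen count, aromaticity, ring membership); for each radius
#' round the identifier is rehashed together with the sorted (bond order,
#' neighbor identifier) list.  All identifiers from radius 0 to `radius` are
#' folded modulo `n_bits`.  Deterministic; a molecule with at least one atom
#' always sets at least one bit.
#'
#' @param mol A `lit_molecule` or SMILES string.
#' @param n_bits Fingerprint length (default 1024).
#' @param radius Environment radius (default 2).
#' @return Integer 0/1 vector of length `n_bits`.
#' @export
fingerprint <- function(mol, n_bits = 1024L, radius = 2L) {
  mol <- as_molecule(mol)
  na <- nrow(mol$atoms)
  inv <- vapply(seq_len(na), function(a) {
    at <- mol$atoms[a, ]
    nb_n <- sum(mol$bonds$a1 == a | mol$bonds$a2 == a)
    paste(at$element, at$charge, nb_n, at$implicit_h,
          as.integer(at$aromatic), as.integer(at$in_ring), sep = "|")
  }, character(1))
  ids <- fnv_id31(inv, 0L)
  all_ids <- ids
  if (radius >= 1L) {
    nbrs <- lapply(seq_len(na), function(a) atom_neighbors(mol, a))
    for (r in seq_len(radius)) {
      new_ids <- vapply(seq_len(na), function(a) {
        nb <- nbrs[[a]]
        if (nrow(nb) == 0L) return(ids[a])
        parts <- sort(paste0(nb$order, ":", ids[nb$nbr]))
        fnv_id31(paste0(ids[a], "|", paste(parts, collapse = ",")), 0L)
      }, integer(1))
      ids <- new_ids
      all_ids <- c(all_ids, ids)
    }
  }
  bits <- integer(n_bits)
  bits[(unique(all_ids) %% n_bits) + 1L] <- 1L
  bits
}
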