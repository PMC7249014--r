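#' Parse a SMILES string into a molecule
#'
#' A self-contained SMILES reader covering the organic subset
#' (B, C, N, O, P, S, F, Cl, Br, I and their aromatic lowercase forms),
#' bracket atoms with isotope, charge and explicit hydrogen counts (stereo
#' marks are accepted and ignored), branches, ring-closure digits including
#' `%nn`, and dot-separated fragments.  Aromatic systems should be written
#' in aromatic (lowercase) form; Kekule input is additionally perceived as
#' aromatic for six-membered C/N rings with alternating single/double
#' bonds.  Implicit hydrogens follow the standard valence rules
#' (aromatic bonds counting 3/2).  Identical SMILES always yield identical
#' descriptor inputs.
#'
#' @param smiles A non-empty SMILES string.
#' @return A `lit_molecule`: list with `atoms` (element, aromatic, charge,
#'   implicit_h, in_ring), `bonds` (a1, a2, order, aromatic, in_ring) and
#'   `rings` (list of atom-index cycles).
#' @export
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(smiles)) {
    stop("SMILES syntax error: empty input")
  }
  chars <- strsplit(smiles, "")[[1]]
  n <- length(chars)
  atoms <- list()   # element, aromatic, charge, hcount (NA = implicit)
  bonds <- list()   # a1, a2, sym ("", "-", "=", "#", ":")
  stack <- integer(0)
  prev <- NA_integer_
  pending_bond <- ""
  ring_open <- list()  # digit -> list(atom, sym)
  i <- 1L
  add_atom <- function(element, aromatic, charge = 0L, hcount = NA_integer_) {
    atoms[[length(atoms) + 1L]] <<- list(element = element,
                                         aromatic = aromatic,
                                         charge = charge, hcount = hcount)
    length(atoms)
  }
  add_bond <- function(a1, a2, sym) {
    bonds[[length(bonds) + 1L]] <<- list(a1 = a1, a2 = a2, sym = sym)
  }
  connect <- function(idx) {
    if (!is.na(prev)) add_bond(prev, idx, pending_bond)
    pending_bond <<- ""
    prev <<- idx
  }
  organic2 <- c("Cl", "Br")
  organic1 <- c("B", "C", "N", "O", "P", "S", "F", "I")
  aromatic1 <- c("b", "c", "n", "o", "p", "s")
  while (i <= n) {
    ch <- chars[i]
    two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
    if (two %in% organic2) {
      connect(add_atom(two, FALSE))
      i <- i + 2L
    } else if (ch %in% organic1) {
      connect(add_atom(ch, FALSE))
      i <- i + 1L
    } else if (ch %in% aromatic1) {
      connect(add_atom(toupper(ch), TRUE))
      i <- i + 1L
    } else if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("SMILES syntax error: unclosed bracket in ", smiles)
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      at <- parse_bracket_atom(body, smiles)
      connect(add_atom(at$element, at$aromatic, at$charge, at$hcount))
      i <- j + 1L
    } else if (ch %in% c("-", "=", "#", ":")) {
      pending_bond <- ch
      i <- i + 1L
    } else if (ch %in% c("/", "\\")) {
      pending_bond <- "-"  # stereo bonds read as single
      i <- i + 1L
    } else if (ch == "(") {
      if (is.na(prev)) stop("SMILES syntax error: branch before any atom")
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) {
        stop("SMILES syntax error: unmatched ')' in ", smiles)
      }
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (grepl("[0-9]", ch) || ch == "%") {
      if (ch == "%") {
        if (i + 2L > n) stop("SMILES syntax error: bad %% ring closure")
        lab <- paste(chars[(i + 1L):(i + 2L)], collapse = "")
        i <- i + 3L
      } else {
        lab <- ch
        i <- i + 1L
      }
      if (is.na(prev)) stop("SMILES syntax error: ring digit before atom")
      if (!is.null(ring_open[[lab]])) {
        op <- ring_open[[lab]]
        sym <- if (nzchar(pending_bond)) pending_bond else op$sym
        add_bond(op$atom, prev, sym)
        ring_open[[lab]] <- NULL
      } else {
        ring_open[[lab]] <- list(atom = prev, sym = pending_bond)
      }
      pending_bond <- ""
    } else if (ch == ".") {
      prev <- NA_integer_
      pending_bond <- ""
      i <- i + 1L
    } else if (ch %in% c(" ", "\t")) {
      i <- i + 1L
    } else {
      stop("SMILES syntax error: unexpected '", ch, "' in ", smiles)
    }
  }
  if (length(stack) > 0L) {
    stop("SMILES syntax error: unmatched '(' in ", smiles)
  }
  open_labs <- names(ring_open)[!vapply(ring_open, is.null, logical(1))]
  if (length(open_labs)) {
    stop("SMILES syntax error: unclosed ring bond ", open_labs[1])
  }
  if (length(atoms) == 0L) stop("SMILES syntax error: no atoms in ", smiles)
  finalize_molecule(atoms, bonds, smiles)
}

parse_bracket_atom <- function(body, smiles) {
  m <- regmatches(body, regexec(
    "^([0-9]*)([A-Z][a-z]?|[a-z])(@{0,2}H?[0-9]*)?([+-][0-9+-]*)?(:[0-9]+)?$",
    body))[[1]]
  if (length(m) == 0L) {
    stop("SMILES syntax error: bad bracket atom [", body, "] in ", smiles)
  }
  sym <- m[3]
  aromatic <- sym == tolower(sym)
  element <- if (aromatic) {
    paste0(toupper(substr(sym, 1, 1)), substring(sym, 2))
  } else sym
  hpart <- m[4]
  hcount <- 0L
  hm <- regmatches(hpart, regexec("H([0-9]*)", hpart))[[1]]
  if (length(hm)) {
    hcount <- if (nzchar(hm[2])) as.integer(hm[2]) else 1L
  }
  cpart <- m[5]
  charge <- 0L
  if (nzchar(cpart)) {
    digits <- regmatches(cpart, regexpr("[0-9]+", cpart))
    mag <- if (length(digits) && nzchar(digits)) as.integer(digits)
           else nchar(gsub("[^+-]", "", cpart))
    charge <- if (substr(cpart, 1, 1) == "+") mag else -mag
  }
  list(element = element, aromatic = aromatic, charge = charge,
       hcount = hcount)
}

# --- graph utilities -------------------------------------------------------

mol_adjacency <- function(n_atoms, bonds_df) {
  adj <- vector("list", n_atoms)
  for (k in seq_len(nrow(bonds_df))) {
    a <- bonds_df$a1[k]; b <- bonds_df$a2[k]
    adj[[a]] <- c(adj[[a]], k)
    adj[[b]] <- c(adj[[b]], k)
  }
  adj
}

# Is each bond part of a ring?  A bond is a ring bond iff its endpoints stay
# connected when the bond is removed.
bonds_in_ring <- function(n_atoms, bonds_df) {
  adj <- mol_adjacency(n_atoms, bonds_df)
  vapply(seq_len(nrow(bonds_df)), function(k) {
    src <- bonds_df$a1[k]; dst <- bonds_df$a2[k]
    seen <- logical(n_atoms)
    seen[src] <- TRUE
    queue <- src
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      for (bk in adj[[cur]]) {
        if (bk == k) next
        nxt <- if (bonds_df$a1[bk] == cur) bonds_df$a2[bk] else bonds_df$a1[bk]
        if (!seen[nxt]) {
          if (nxt == dst) return(TRUE)
          seen[nxt] <- TRUE
          queue <- c(queue, nxt)
        }
      }
    }
    FALSE
  }, logical(1))
}

# Smallest cycle through each ring bond (BFS), deduplicated: an adequate
# ring set for the small molecules this package triages.
find_rings <- function(n_atoms, bonds_df, ring_bond) {
  adj <- mol_adjacency(n_atoms, bonds_df)
  rings <- list()
  for (k in which(ring_bond)) {
    src <- bonds_df$a1[k]; dst <- bonds_df$a2[k]
    parent <- rep(NA_integer_, n_atoms)
    seen <- logical(n_atoms)
    seen[src] <- TRUE
    queue <- src
    found <- FALSE
    while (length(queue) && !found) {
      cur <- queue[1]; queue <- queue[-1]
      for (bk in adj[[cur]]) {
        if (bk == k) next
        nxt <- if (bonds_df$a1[bk] == cur) bonds_df$a2[bk] else bonds_df$a1[bk]
        if (!seen[nxt]) {
          parent[nxt] <- cur
          if (nxt == dst) { found <- TRUE; break }
          seen[nxt] <- TRUE
          queue <- c(queue, nxt)
        }
      }
    }
    if (found) {
      path <- dst
      while (!is.na(parent[path[length(path)]])) {
        path <- c(path, parent[path[length(path)]])
      }
      ring <- sort(path)
      key <- paste(ring, collapse = ",")
      if (!key %in% names(rings)) rings[[key]] <- path
    }
  }
  unname(rings)
}

default_valences <- function(element, charge) {
  base <- switch(element,
                 B = 3L, C = 4L, N = c(3L, 5L), O = 2L, P = c(3L, 5L),
                 S = c(2L, 4L, 6L), F = 1L, Cl = 1L, Br = 1L, I = 1L,
                 H = 1L,
                 stop("unknown element: ", element))
  if (charge != 0L) {
    if (element == "N" && charge == 1L) base <- 4L
    else if (element == "N" && charge == -1L) base <- 2L
    else if (element == "O" && charge == 1L) base <- 3L
    else if (element == "O" && charge == -1L) base <- 1L
    else if (element == "S" && charge == -1L) base <- 1L
    else if (element == "C" && abs(charge) == 1L) base <- 3L
  }
  base
}

finalize_molecule <- function(atoms, bonds, smiles) {
  na <- length(atoms)
  adf <- data.frame(
    element = vapply(atoms, `[[`, character(1), "element"),
    aromatic = vapply(atoms, `[[`, logical(1), "aromatic"),
    charge = vapply(atoms, `[[`, integer(1), "charge"),
    hcount = vapply(atoms, `[[`, integer(1), "hcount"),
    stringsAsFactors = FALSE)
  bdf <- if (length(bonds)) {
    data.frame(a1 = vapply(bonds, `[[`, integer(1), "a1"),
               a2 = vapply(bonds, `[[`, integer(1), "a2"),
               sym = vapply(bonds, `[[`, character(1), "sym"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(a1 = integer(), a2 = integer(), sym = character(),
               stringsAsFactors = FALSE)
  }
  ring_bond <- if (nrow(bdf)) bonds_in_ring(na, bdf) else logical(0)
  rings <- find_rings(na, bdf, ring_bond)
  # aromatic bonds: explicit ':', or unspecified between two aromatic atoms
  # within a ring
  bdf$aromatic <- (bdf$sym == ":") |
    (bdf$sym == "" & adf$aromatic[bdf$a1] & adf$aromatic[bdf$a2] & ring_bond)
  # Kekule aromatic perception: six-membered all-C/N rings with alternating
  # single/double bonds
  for (ring in rings) {
    if (length(ring) != 6L) next
    ridx <- ring
    if (!all(adf$element[ridx] %in% c("C", "N"))) next
    if (any(adf$aromatic[ridx])) next
    kb <- which((bdf$a1 %in% ridx) & (bdf$a2 %in% ridx) & ring_bond)
    if (length(kb) != 6L) next
    ords <- ifelse(bdf$sym[kb] == "=", 2L, 1L)
    if (sum(ords == 2L) == 3L && sum(ords == 1L) == 3L) {
      # check alternation around the cycle
      ok <- TRUE
      for (a in ridx) {
        inc <- kb[bdf$a1[kb] == a | bdf$a2[kb] == a]
        if (sum(ifelse(bdf$sym[inc] == "=", 1L, 0L)) != 1L) { ok <- FALSE }
      }
      if (ok) {
        adf$aromatic[ridx] <- TRUE
        bdf$aromatic[kb] <- TRUE
      }
    }
  }
  bdf$order <- ifelse(bdf$aromatic, 1.5,
                      ifelse(bdf$sym == "=", 2,
                             ifelse(bdf$sym == "#", 3, 1)))
  # implicit hydrogens and valence checking
  bond_sum <- numeric(na)
  for (k in seq_len(nrow(bdf))) {
    bond_sum[bdf$a1[k]] <- bond_sum[bdf$a1[k]] + bdf$order[k]
    bond_sum[bdf$a2[k]] <- bond_sum[bdf$a2[k]] + bdf$order[k]
  }
  degree <- integer(na)
  for (k in seq_len(nrow(bdf))) {
    degree[bdf$a1[k]] <- degree[bdf$a1[k]] + 1L
    degree[bdf$a2[k]] <- degree[bdf$a2[k]] + 1L
  }
  implicit_h <- integer(na)
  for (a in seq_len(na)) {
    vals <- default_valences(adf$element[a], adf$charge[a])
    if (!is.na(adf$hcount[a])) {
      implicit_h[a] <- adf$hcount[a]
      if (ceiling(bond_sum[a]) + adf$hcount[a] > max(vals) + 1L) {
        stop("valence violation at atom ", a, " (", adf$element[a], ") in ",
             smiles)
      }
    } else if (adf$aromatic[a]) {
      # aromatic convention: lowercase c carries H up to 3 connections;
      # lowercase n/o/s without brackets carry none (pyrrole-type NH must be
      # written [nH])
      implicit_h[a] <- if (adf$element[a] == "C") {
        max(0L, 3L - degree[a])
      } else 0L
    } else {
      used <- ceiling(bond_sum[a])
      fit <- vals[vals >= used]
      if (length(fit) == 0L) {
        stop("valence violation at atom ", a, " (", adf$element[a], ") in ",
             smiles)
      }
      implicit_h[a] <- as.integer(fit[1] - used)
    }
  }
  adf$implicit_h <- implicit_h
  adf$hcount <- NULL
  atom_in_ring <- logical(na)
  for (k in seq_len(nrow(bdf))) {
    if (length(ring_bond) && ring_bond[k]) {
      atom_in_ring[bdf$a1[k]] <- TRUE
      atom_in_ring[bdf$a2[k]] <- TRUE
    }
  }
  adf$in_ring <- atom_in_ring
  bdf$in_ring <- ring_bond
  bdf$sym <- NULL
  structure(list(atoms = adf, bonds = bdf, rings = rings, smiles = smiles),
            class = "lit_molecule")
}

#' @export
print.lit_molecule <- function(x, ...) {
  cat(sprintf("<lit_molecule> %d heavy atoms, %d bonds (%s)\n",
              nrow(x$atoms), nrow(x$bonds), x$smiles))
  invisible(x)
}

# neighbor atom indices (with bond rows) for one atom
atom_neighbors <- function(mol, a) {
  b <- mol$bonds
  rows <- which(b$a1 == a | b$a2 == a)
  data.frame(bond = rows,
             nbr = ifelse(b$a1[rows] == a, b$a2[rows], b$a1[rows]),
             order = b$order[rows],
             aromatic = b$aromatic[rows],
             in_ring = b$in_ring[rows])
}
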