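# Wildman-Crippen atom-contribution logP.  Atom types follow the published
# parameter table; typing is an ordered decision procedure equivalent to the
# published SMARTS priority list, restricted to the elements the SMILES
# parser accepts.

.crippen_logp <- c(
  C1 = 0.1441, C2 = 0, C3 = -0.2035, C4 = -0.2051, C5 = -0.2783,
  C6 = 0.1551, C7 = 0.0017, C8 = 0.08452, C9 = -0.1444, C10 = -0.0516,
  C11 = 0.1193, C12 = -0.0967, C13 = -0.5443, C14 = 0, C15 = 0.245,
  C16 = 0.198, C17 = 0, C18 = 0.1581, C19 = 0.2955, C20 = 0.2713,
  C21 = 0.136, C22 = 0.4619, C23 = 0.5437, C24 = 0.1893, C25 = -0.8186,
  C26 = 0.264, C27 = 0.2148, CS = 0.08129,
  H1 = 0.123, H2 = -0.2677, H3 = 0.2142, H4 = 0.298, HS = 0.1125,
  N1 = -1.019, N2 = -0.7096, N3 = -1.027, N4 = -0.5188, N5 = 0.08387,
  N6 = 0.1836, N7 = -0.3187, N8 = -0.4458, N9 = 0.01508, N10 = -1.95,
  N11 = -0.3239, N12 = -1.119, N13 = -0.3396, N14 = 0.2887, NS = -0.4806,
  O1 = 0.1552, O2 = -0.2893, O3 = -0.0684, O4 = -0.4195, O5 = 0.0335,
  O6 = -0.3339, O7 = -1.189, O8 = 0.1788, O9 = -0.1526, O10 = 0.1129,
  O11 = 0.4833, O12 = -1.326, OS = -0.1188,
  F = 0.4202, Cl = 0.6895, Br = 0.8456, I = 0.8857, Hal = -2.996,
  P = 0.8612, S1 = 0.6482, S2 = -0.0024, S3 = 0.6237)

.crippen_hetero <- c("N", "O", "P", "S", "F", "Cl", "Br", "I")

#' Wildman-Crippen clogP
#'
#' Sum of the published atom-type contributions over heavy atoms and
#' hydrogens.  Deterministic; untypable atoms raise an error naming the
#' atom.
#'
#' @param mol A `lit_molecule` or SMILES string (aromaticity perceived at
#'   parse time).
#' @return The clogP estimate.
#' @export
crippen_clogp <- function(mol) {
  mol <- as_molecule(mol)
  types <- crippen_types(mol)
  sum(.crippen_logp[types$type])
}

# Typed contributions for every heavy atom and each implicit hydrogen.
crippen_types <- function(mol) {
  na <- nrow(mol$atoms)
  heavy <- vapply(seq_len(na), function(a) crippen_type_atom(mol, a),
                  character(1))
  hs <- character(0)
  for (a in seq_len(na)) {
    nh <- mol$atoms$implicit_h[a]
    if (nh > 0L) {
      hs <- c(hs, rep(crippen_type_hydrogen(mol, a), nh))
    }
  }
  data.frame(type = c(heavy, hs), stringsAsFactors = FALSE)
}

crippen_type_atom <- function(mol, a) {
  el <- mol$atoms$element[a]
  switch(el,
         C = crippen_type_C(mol, a),
         N = crippen_type_N(mol, a),
         O = crippen_type_O(mol, a),
         S = {
           at <- mol$atoms[a, ]
           nb <- atom_neighbors(mol, a)
           if (at$charge != 0) "S2"
           else if (any(nb$order == 2 &
                        mol$atoms$element[nb$nbr] %in%
                          c("N", "O", "P", "S"))) "S2"
           else if (at$aromatic) "S3"
           else "S1"
         },
         P = "P",
         F = if (mol$atoms$charge[a] == 0L) "F" else "Hal",
         Cl = if (mol$atoms$charge[a] == 0L) "Cl" else "Hal",
         Br = if (mol$atoms$charge[a] == 0L) "Br" else "Hal",
         I = if (mol$atoms$charge[a] == 0L) "I" else "Hal",
         stop("no Wildman-Crippen type for atom ", a, " (", el, ")"))
}

crippen_type_C <- function(mol, a) {
  at <- mol$atoms[a, ]
  nb <- atom_neighbors(mol, a)
  nH <- at$implicit_h
  deg <- nrow(nb)
  X <- deg + nH                                   # total connectivity
  nbr_el <- mol$atoms$element[nb$nbr]
  nbr_arom <- mol$atoms$aromatic[nb$nbr]
  if (!at$aromatic) {
    sp3 <- all(nb$order == 1 & !nb$aromatic)
    ali <- !nbr_arom                               # aliphatic neighbors
    ali_C <- ali & nbr_el == "C"
    het <- ali & nbr_el %in% .crippen_hetero
    # C1/C2: saturated carbons bound only to aliphatic carbon
    if (sp3 && X == 4L && all(ali_C)) {
      if (nH >= 2L) return("C1")
      return("C2")
    }
    # C3/C4: saturated carbons with an aliphatic heteroatom neighbor and
    # aliphatic remaining neighbors
    if (sp3 && X == 4L && any(het) && all(ali)) {
      if (nH >= 2L) return("C3")
      return("C4")
    }
    dbl <- nb$order == 2
    if (any(dbl & ali & nbr_el != "C")) return("C5")
    dbl_aliC <- dbl & ali_C
    if (any(dbl_aliC)) {
      # vinylic carbon: C6 with aliphatic substituents, C26 with aromatic
      if (sum(dbl_aliC) == 2L) return("C6")        # allene center
      others <- which(!dbl_aliC)
      if (length(others) == 0L) return("C6")       # terminal =CH2
      if (all(ali[others])) return("C6")
      if (any(nbr_arom[others])) return("C26")
      return("CS")
    }
    if (any(dbl & nbr_arom & nbr_el == "C")) return("C26")  # [C]=c
    if (nb_triple(nb) && X == 2L) return("C7")
    if (nH == 3L && deg == 1L) {
      if (nbr_arom[1] && nbr_el[1] == "C") return("C8")
      if (nbr_arom[1]) return("C9")
    }
    if (sp3 && X == 4L && any(nbr_arom)) {
      if (nH == 2L) return("C10")
      if (nH == 1L) return("C11")
      if (nH == 0L) return("C12")
    }
    return("CS")
  }
  # aromatic carbon
  exo <- !nb$aromatic                              # exocyclic bonds
  if (nH == 0L && any(exo & nb$order == 1 & !nbr_arom &
                      !(nbr_el %in% c("C", "N", "O", "S", "F", "Cl",
                                      "Br", "I")))) return("C13")
  if (any(nbr_el == "F")) return("C14")
  if (any(nbr_el == "Cl")) return("C15")
  if (any(nbr_el == "Br")) return("C16")
  if (any(nbr_el == "I")) return("C17")
  if (nH >= 1L) return("C18")
  if (sum(nb$aromatic) >= 3L) return("C19")
  exo_single <- exo & nb$order == 1
  if (any(exo_single & nbr_arom)) return("C20")
  if (any(exo_single & nbr_el == "C")) return("C21")
  if (any(exo_single & nbr_el == "N")) return("C22")
  if (any(exo_single & nbr_el == "O")) return("C23")
  if (any(exo_single & nbr_el == "S")) return("C24")
  if (any(exo & nb$order == 2 & nbr_el %in% c("C", "N", "O"))) return("C25")
  "CS"
}

nb_triple <- function(nb) any(nb$order == 3)

crippen_type_N <- function(mol, a) {
  at <- mol$atoms[a, ]
  nb <- atom_neighbors(mol, a)
  nH <- at$implicit_h
  nbr_arom <- mol$atoms$aromatic[nb$nbr]
  ali <- !nbr_arom
  n_dbl <- sum(nb$order == 2)
  n_trp <- sum(nb$order == 3)
  n_sng <- sum(nb$order == 1 & !nb$aromatic)
  if (at$charge == 0L) {
    if (at$aromatic) return("N11")
    if (nH >= 2L && n_sng == 1L) {
      return(if (ali[nb$order == 1][1]) "N1" else "N3")
    }
    if (nH == 1L && n_sng == 2L) {
      return(if (all(ali)) "N2" else "N4")
    }
    if (nH == 1L && n_dbl == 1L) return("N5")
    if (nH == 0L && n_dbl >= 1L && nrow(nb) >= 2L) return("N6")
    if (nH == 0L && n_sng == 3L) {
      return(if (all(ali)) "N7" else "N8")
    }
    if (n_trp == 1L) return("N9")
    return("NS")
  }
  if (at$charge > 0L) {
    if (at$aromatic) return("N12")
    if (nH >= 1L && nH + nrow(nb) <= 4L && n_dbl == 0L && n_trp == 0L) {
      return("N10")
    }
    if (nH == 0L && (n_sng == 4L || (n_dbl >= 1L && nrow(nb) >= 3L) ||
                     n_dbl == 2L)) return("N13")
    return("N14")
  }
  "N14"  # negatively charged nitrogen
}

crippen_type_O <- function(mol, a) {
  at <- mol$atoms[a, ]
  nb <- atom_neighbors(mol, a)
  nH <- at$implicit_h
  nbr_el <- mol$atoms$element[nb$nbr]
  nbr_arom <- mol$atoms$aromatic[nb$nbr]
  if (at$aromatic) return("O1")
  if (nH >= 1L) return("O2")
  n_sng <- sum(nb$order == 1)
  if (at$charge < 0L) {
    if (nrow(nb) == 1L) {
      nbr <- nb$nbr[1]
      if (nbr_el[1] == "C" && !nbr_arom[1]) {
        cnb <- atom_neighbors(mol, nbr)
        if (any(cnb$order == 2 & mol$atoms$element[cnb$nbr] == "O")) {
          return("O12")                            # carboxylate
        }
      }
      if (nbr_el[1] == "N") return("O5")
      if (nbr_el[1] == "S") return("O6")
    }
    return("O7")
  }
  dbl <- which(nb$order == 2)
  if (length(dbl) == 1L) {
    nbr <- nb$nbr[dbl]
    nel <- nbr_el[dbl]
    if (nel %in% c("N", "O")) return("O5")
    if (nel == "S") return("O6")
    if (nel == "C" && nbr_arom[dbl]) return("O8")
    if (nel == "C") {
      cnb <- atom_neighbors(mol, nbr)
      keep <- cnb$nbr != a
      oel <- mol$atoms$element[cnb$nbr[keep]]
      oarom <- mol$atoms$aromatic[cnb$nbr[keep]]
      cH <- mol$atoms$implicit_h[nbr]
      n_other <- sum(keep)
      # O9: aliphatic aldehydes/ketones/esters; O10 aryl carbonyls;
      # O11 carbonyl flanked by two non-carbons (ureas, carbamates)
      if (cH >= 1L && n_other == 1L && oel == "C" && !oarom) return("O9")
      if (n_other == 2L && any(oel == "C" & !oarom)) return("O9")
      if (cH >= 1L && n_other == 1L && oel %in% c("N", "O") && !oarom) {
        return("O9")
      }
      if (cH >= 2L && n_other == 0L) return("O9")  # formaldehyde
      if (n_other == 1L && any(cnb$order[keep] == 2 & oel == "O")) {
        return("O9")                                # ketene-type O=C=O
      }
      if (cH >= 1L && n_other == 1L && oel == "C" && oarom) return("O10")
      if (n_other == 2L && any(oel == "C") && any(oarom)) return("O10")
      if (n_other == 2L && all(oel != "C")) return("O11")
      return("OS")
    }
    return("OS")
  }
  if (n_sng == 2L) {
    return(if (any(nbr_arom)) "O4" else "O3")
  }
  "OS"
}

crippen_type_hydrogen <- function(mol, a) {
  el <- mol$atoms$element[a]
  if (el == "C") return("H1")
  if (el == "N") return("H3")
  if (el == "O") {
    nb <- atom_neighbors(mol, a)
    if (nrow(nb) == 0L) return("HS")               # water
    nbr <- nb$nbr[1]
    nel <- mol$atoms$element[nbr]
    narom <- mol$atoms$aromatic[nbr]
    if (nel == "C") {
      cnb <- atom_neighbors(mol, nbr)
      sp3 <- all(cnb$order == 1 & !cnb$aromatic)
      if ((sp3 && !narom) || narom) {
        if (narom) return("H2")                    # phenol
        return("H2")                               # alcohol on sp3 C
      }
      if (any(cnb$order == 2 &
              mol$atoms$element[cnb$nbr] %in% c("C", "N", "O", "S"))) {
        return("H4")                               # acid / enol
      }
      return("HS")
    }
    if (!(nel %in% c("C", "N", "O", "S"))) return("H2")
    if (nel == "N") return("H3")
    if (nel %in% c("O", "S")) return("H4")
    return("HS")
  }
  if (!(el %in% c("C", "N", "O"))) return("H2")    # thiols etc.
  "HS"
}
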