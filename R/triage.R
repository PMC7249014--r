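#' Lipinski rule-of-five configuration
#'
#' Bounds as used for oral-absorption triage: molecular weight strictly
#' below `mw_max`; hydrogen-bond donors, acceptors, topological polar
#' surface area and rotatable bonds at or below their maxima.  Accumulating
#' `violation_fail_count` violations (default 2) predicts poor oral
#' absorption.
#'
#' @param mw_max Molecular weight bound, strict `<` (default 500 Da).
#' @param hbd_max Donor bound, `<=` (default 5).
#' @param hba_max Acceptor bound, `<=` (default 10).
#' @param tpsa_max TPSA bound in square Angstroms, `<=` (default 140).
#' @param rotb_max Rotatable-bond bound, `<=` (default 10).
#' @param violation_fail_count Violations at which the poor-oral flag fires
#'   (default 2).
#' @return A `lipinski_config` list.
#' @export
lipinski_config <- function(mw_max = 500, hbd_max = 5, hba_max = 10,
                            tpsa_max = 140, rotb_max = 10,
                            violation_fail_count = 2L) {
  stopifnot(mw_max > 0, hbd_max > 0, hba_max > 0, tpsa_max > 0,
            rotb_max > 0, violation_fail_count >= 1L)
  structure(list(mw_max = mw_max, hbd_max = hbd_max, hba_max = hba_max,
                 tpsa_max = tpsa_max, rotb_max = rotb_max,
                 violation_fail_count = as.integer(violation_fail_count)),
            class = "lipinski_config")
}

#' Compute the descriptor set for one molecule
#'
#' @param mol A `lit_molecule` or SMILES string.
#' @return One-row data frame: `mw`, `hbd`, `hba`, `tpsa`, `rotb`, `clogp`.
#' @export
descriptor_set <- function(mol) {
  mol <- as_molecule(mol)
  data.frame(mw = molecular_weight(mol), hbd = count_hbd(mol),
             hba = count_hba(mol), tpsa = tpsa(mol),
             rotb = rotatable_bonds(mol), clogp = crippen_clogp(mol))
}

#' Count Lipinski violations for a descriptor set
#'
#' @param desc One-row data frame (or list) with `mw`, `hbd`, `hba`,
#'   `tpsa`, `rotb`.
#' @param rule A [lipinski_config()].
#' @return Integer violation count (0-5).
#' @export
lipinski_violations <- function(desc, rule = lipinski_config()) {
  as.integer((desc$mw >= rule$mw_max) + (desc$hbd > rule$hbd_max) +
             (desc$hba > rule$hba_max) + (desc$tpsa > rule$tpsa_max) +
             (desc$rotb > rule$rotb_max))
}

#' Triage compounds into a ranked verdict table
#'
#' For each compound: Lipinski descriptors and violation count, the
#' poor-oral flag (violations at or above the configured failure count),
#' the clogP band, and the blood-brain-barrier decision.  A compound is
#' `suitable` when it is not poor-oral, crosses the BBB, and sits in the
#' optimal clogP band.  Ranking is suitable-first, then fewer violations,
#' then higher BBB score, with the compound name as the final deterministic
#' tie-break.  Unparseable records are excluded with a warning naming the
#' record, never silently.
#'
#' @param records Data frame with columns `name` and `smiles`.
#' @param rule A [lipinski_config()].
#' @param bbb_model A trained `bbb_model`, or `NULL` to skip the BBB gate
#'   (then `bbb_score = NA` and `bbb_crossing = TRUE` so the gate is
#'   neutral).
#' @return Data frame of verdicts, ranked: `name`, `mw`, `hbd`, `hba`,
#'   `tpsa`, `rotb`, `clogp`, `violations`, `poor_oral`, `clogp_band`,
#'   `bbb_score`, `bbb_crossing`, `suitable`, `rank`.
#' @export
triage <- function(records, rule = lipinski_config(), bbb_model = NULL) {
  stopifnot(is.data.frame(records), all(c("name", "smiles") %in%
                                        names(records)))
  rows <- lapply(seq_len(nrow(records)), function(i) {
    nm <- records$name[i]
    mol <- tryCatch(parse_smiles(records$smiles[i]), error = function(e) e)
    if (inherits(mol, "error")) {
      warning("excluding unparseable compound '", nm, "': ",
              conditionMessage(mol))
      return(NULL)
    }
    d <- descriptor_set(mol)
    v <- lipinski_violations(d, rule)
    if (is.null(bbb_model)) {
      bscore <- NA_real_
      bcross <- TRUE
    } else {
      p <- predict_bbb(mol, bbb_model)
      bscore <- p$score
      bcross <- p$crossing
    }
    poor <- v >= rule$violation_fail_count
    band <- clogp_band(d$clogp)
    cbind(data.frame(name = nm, stringsAsFactors = FALSE), d,
          data.frame(violations = v, poor_oral = poor, clogp_band = band,
                     bbb_score = bscore, bbb_crossing = bcross,
                     suitable = !poor && bcross && band == "optimal",
                     stringsAsFactors = FALSE))
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) == 0L) {
    stop("no parseable compounds to triage")
  }
  ord <- order(-rows$suitable, rows$violations,
               -ifelse(is.na(rows$bbb_score), 0, rows$bbb_score),
               rows$name)
  rows <- rows[ord, , drop = FALSE]
  rows$rank <- seq_len(nrow(rows))
  rownames(rows) <- NULL
  rows
}

#' Read a compound table (CSV/TSV with columns name, smiles)
#'
#' @param path File path; the separator is inferred from the extension
#'   (`.tsv` = tab, otherwise comma).
#' @return Data frame with `name` and `smiles`.
#' @export
read_compound_table <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  if (!all(c("name", "smiles") %in% names(df))) {
    stop("compound table must have columns 'name' and 'smiles'")
  }
  df
}

#' Write a verdict table as TSV
#'
#' @param verdicts Data frame from [triage()].
#' @param path Output path.
#' @export
write_verdicts <- function(verdicts, path) {
  write.table(verdicts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
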