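pipeline_error <- function(class, msg) {
  stop(structure(class = c(class, "litriage_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Load a pipeline configuration from YAML
#'
#' Validates threshold and dimension constraints on load and re-checks that
#' referenced paths exist.  Recognized top-level keys: `question`,
#' `corpus`, `method`, `encoder` (fields of [encoder_config()]), `dcn_model`
#' (path), `threshold`, `compounds` (path), `bbb_model` (path or empty),
#' `lipinski` (fields of [lipinski_config()]), `out_dir`, `log_level`.
#'
#' @param path YAML file path.
#' @return A named list ready for [run_pipeline()].
#' @export
load_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    pipeline_error("litriage_config_error",
                   paste("config file not found:", path))
  }
  cfg <- yaml::read_yaml(path)
  for (key in c("question", "corpus")) {
    if (is.null(cfg[[key]])) {
      pipeline_error("litriage_config_error",
                     paste("config missing required key:", key))
    }
  }
  cfg$encoder <- do.call(encoder_config, as.list(cfg$encoder))
  cfg$lipinski <- do.call(lipinski_config, as.list(cfg$lipinski))
  if (is.null(cfg$method)) cfg$method <- "inner_product"
  for (key in c("corpus", "dcn_model", "compounds", "bbb_model")) {
    p <- cfg[[key]]
    if (is.character(p) && length(p) == 1L && !file.exists(p)) {
      pipeline_error("litriage_data_error",
                     paste("configured path does not exist:", p))
    }
  }
  cfg
}

#' Run the mining-filtering-triage pipeline end to end
#'
#' Stages: (1) mine the corpus for the top-scoring answer sentence per
#' document; (2) filter the answers with the DCN relevance threshold;
#' (3) match compound names from the compound table against the retained
#' sentences (dictionary matching, case-insensitive); (4) triage the
#' matched compounds; (5) assemble the candidate report.  Stage counts are
#' logged via `message()` unless `log_level = "quiet"`.  Reruns with an
#' identical configuration produce byte-identical reports.
#'
#' @param question Question string.
#' @param corp A `lit_corpus` or path to a corpus JSON.
#' @param dcn_model A trained `dcn_model` or path to a saved one; `NULL`
#'   skips relevance filtering.
#' @param compounds Data frame (`name`, `smiles`) or path to a CSV/TSV.
#' @param bbb_model A `bbb_model`, path, or `NULL` (BBB gate neutral).
#' @param method Similarity method for mining.
#' @param encoder An [encoder_config()].
#' @param lipinski A [lipinski_config()].
#' @param threshold Relevance threshold (default: the DCN model's).
#' @param out_dir If non-`NULL`, write `report.tsv` and `report.json` there.
#' @param log_level `"info"` or `"quiet"`.
#' @return Invisibly, a list with `report` (data frame), `answers`,
#'   `retained`, and stage `counts`.
#' @export
run_pipeline <- function(question, corp, dcn_model = NULL, compounds = NULL,
                         bbb_model = NULL,
                         method = c("inner_product", "hausdorff"),
                         encoder = encoder_config(),
                         lipinski = lipinski_config(),
                         threshold = NULL, out_dir = NULL,
                         log_level = c("info", "quiet")) {
  method <- match.arg(method)
  log_level <- match.arg(log_level)
  say <- function(...) if (log_level != "quiet") message("[litriage] ", ...)
  t0 <- Sys.time()
  if (is.character(corp)) {
    if (!file.exists(corp)) {
      pipeline_error("litriage_data_error",
                     paste("corpus file not found:", corp))
    }
    corp <- load_corpus(corp)
  }
  if (is.character(dcn_model)) {
    if (!file.exists(dcn_model)) {
      pipeline_error("litriage_model_error",
                     paste("dcn model file not found:", dcn_model))
    }
    dcn_model <- load_dcn(dcn_model)
  }
  if (is.character(bbb_model)) {
    if (!file.exists(bbb_model)) {
      pipeline_error("litriage_model_error",
                     paste("bbb model file not found:", bbb_model))
    }
    bbb_model <- load_bbb(bbb_model)
  }
  if (is.character(compounds)) compounds <- read_compound_table(compounds)
  if (is.null(compounds)) {
    pipeline_error("litriage_config_error", "no compound table supplied")
  }

  say("mining ", length(corp$documents), " documents (", method, ")")
  answers <- mine_answers(question, corp, method = method, config = encoder)
  say("stage mine: ", nrow(answers), " candidate answers")

  if (!is.null(dcn_model)) {
    thr <- if (is.null(threshold)) dcn_model$config$threshold else threshold
    retained <- filter_answers(answers, question, dcn_model,
                               config = encoder, threshold = thr)
    say("stage filter: ", nrow(retained), " of ", nrow(answers),
        " answers at relevance >= ", thr)
  } else {
    retained <- answers
    retained$relevance <- NA_real_
    say("stage filter: skipped (no DCN model)")
  }

  # dictionary matching of compound names in the retained sentences
  hits <- list()
  if (nrow(retained) > 0L) {
    low_text <- tolower(retained$text)
    for (i in seq_len(nrow(compounds))) {
      nm <- compounds$name[i]
      hit_rows <- which(grepl(tolower(nm), low_text, fixed = TRUE))
      for (r in hit_rows) {
        hits[[length(hits) + 1L]] <-
          cbind(data.frame(name = nm, stringsAsFactors = FALSE),
                retained[r, c("doc_id", "sent_id", "text", "score",
                              "relevance")])
      }
    }
  }
  matched <- if (length(hits)) do.call(rbind, hits) else NULL
  say("stage extract: ", if (is.null(matched)) 0L else nrow(matched),
      " compound mentions")

  if (is.null(matched)) {
    report <- data.frame()
    say("no compounds matched; empty report")
  } else {
    verdicts <- triage(compounds[compounds$name %in% matched$name,
                                 c("name", "smiles")],
                       rule = lipinski, bbb_model = bbb_model)
    say("stage triage: ", nrow(verdicts), " compounds, ",
        sum(verdicts$suitable), " suitable")
    report <- merge(matched, verdicts, by = "name", sort = FALSE)
    names(report)[names(report) == "text"] <- "answer_sentence"
    names(report)[names(report) == "score"] <- "similarity"
    report <- report[order(report$rank, report$doc_id), , drop = FALSE]
    cols <- c("name", "doc_id", "sent_id", "answer_sentence", "similarity",
              "relevance", "mw", "hbd", "hba", "tpsa", "rotb", "clogp",
              "violations", "poor_oral", "clogp_band", "bbb_score",
              "bbb_crossing", "suitable", "rank")
    report <- report[, cols]
    rownames(report) <- NULL
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(report, file.path(out_dir, "report.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    say("report written to ", out_dir)
  }
  say(sprintf("pipeline finished in %.2f s",
              as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(list(report = report, answers = answers, retained = retained,
                 counts = list(documents = length(corp$documents),
                               mined = nrow(answers),
                               retained = nrow(retained),
                               reported = nrow(report))))
}
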