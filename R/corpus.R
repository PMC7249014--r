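#' Extract raw text from a document file
#'
#' Plain-text files are read as-is.  PDF extraction is delegated to a
#' pluggable backend: any function taking a file path and returning a single
#' character string.  No backend is bundled, so the package builds and tests
#' with no binary dependencies; register one (e.g. an external tool wrapper)
#' when mining real PDF corpora.
#'
#' @param path Path to the file.
#' @param format Either `"plain"` or `"pdf"`.
#' @param pdf_backend A `function(path) -> character(1)` used when
#'   `format = "pdf"`.
#' @return A single non-empty character string; sentence punctuation is
#'   retained.
#' @export
extract_text <- function(path, format = c("plain", "pdf"), pdf_backend = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("file does not exist: ", path)
  }
  if (format == "plain") {
    txt <- paste(readLines(path, warn = FALSE, encoding = "UTF-8"),
                 collapse = "\n")
  } else {
    if (is.null(pdf_backend)) {
      stop("no pdf backend configured")
    }
    txt <- pdf_backend(path)
    if (!is.character(txt) || length(txt) != 1L) {
      stop("pdf backend must return a single character string")
    }
  }
  if (!nzchar(trimws(txt))) {
    stop("empty extraction result: ", path)
  }
  txt
}

#' Tokenize raw text into unique sentences with provenance offsets
#'
#' Sentences are split on terminal punctuation (`.`, `?`, `!`) followed by
#' whitespace or end of text.  A custom splitter (e.g. an abbreviation-aware
#' tokenizer) can be supplied; it must return 0-based half-open `[start, end)`
#' offsets into `raw_text`.  Exact duplicates (after trimming) are removed,
#' keeping the first occurrence; fragments shorter than `min_chars` are
#' discarded.
#'
#' @param raw_text A character string (may be empty).
#' @param min_chars Minimum sentence length in characters (default 3).
#' @param splitter Optional `function(raw_text) -> data.frame(start, end)`
#'   with 0-based half-open offsets, replacing the default rule.
#' @return A data frame with columns `sent_id` (integer, 1-based index after
#'   deduplication), `text`, `start`, `end` (0-based half-open offsets such
#'   that `substr(raw_text, start + 1, end)` equals `text`).
#' @export
tokenize_sentences <- function(raw_text, min_chars = 3L, splitter = NULL) {
  stopifnot(is.character(raw_text), length(raw_text) == 1L)
  empty <- data.frame(sent_id = integer(), text = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  if (!nzchar(raw_text)) {
    return(empty)
  }
  spans <- if (is.null(splitter)) {
    default_sentence_spans(raw_text)
  } else {
    splitter(raw_text)
  }
  if (nrow(spans) == 0L) {
    return(empty)
  }
  # trim whitespace by shrinking offsets, so text == raw_text[start:end]
  out <- lapply(seq_len(nrow(spans)), function(i) {
    s <- spans$start[i]
    e <- spans$end[i]
    txt <- substr(raw_text, s + 1L, e)
    lead <- nchar(txt) - nchar(sub("^\\s+", "", txt))
    trail <- nchar(txt) - nchar(sub("\\s+$", "", txt))
    s <- s + lead
    e <- e - trail
    if (e <= s) return(NULL)
    data.frame(text = substr(raw_text, s + 1L, e),
               start = as.integer(s), end = as.integer(e),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0L) {
    return(empty)
  }
  out <- out[nchar(out$text) >= min_chars, , drop = FALSE]
  out <- out[!duplicated(out$text), , drop = FALSE]
  if (nrow(out) == 0L) {
    return(empty)
  }
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  cbind(sent_id = seq_len(nrow(out)), out)
}

# Default splitting rule: break after runs of terminal punctuation followed by
# whitespace (or end of text).  Returns 0-based half-open spans.
default_sentence_spans <- function(raw_text) {
  m <- gregexpr("[.?!]+(\\s+|$)", raw_text, perl = TRUE)[[1]]
  n <- nchar(raw_text)
  if (m[1] == -1L) {
    return(data.frame(start = 0L, end = as.integer(n)))
  }
  punct_start <- as.integer(m)                      # 1-based
  punct_len <- attr(m, "match.length")
  # sentence ends just after the punctuation run (before trailing whitespace)
  full_end <- punct_start + punct_len - 1L          # 1-based inclusive
  starts <- c(0L, full_end)                         # 0-based starts
  ends <- c(full_end, if (full_end[length(full_end)] < n) n else NULL)
  k <- length(ends)
  data.frame(start = starts[seq_len(k)], end = as.integer(ends))
}

#' Build a document from raw text
#'
#' @param doc_id Unique identifier within a corpus.
#' @param raw_text Full extracted text.
#' @param source File path or label (defaults to `doc_id`).
#' @param ... Passed to [tokenize_sentences()].
#' @return A `lit_document`: list with `doc_id`, `source`, `raw_text` and a
#'   `sentences` data frame.
#' @export
document <- function(doc_id, raw_text, source = doc_id, ...) {
  stopifnot(is.character(doc_id), length(doc_id) == 1L, nzchar(doc_id))
  sent <- tokenize_sentences(raw_text, ...)
  structure(list(doc_id = doc_id, source = source,
                 raw_text = raw_text, sentences = sent),
            class = "lit_document")
}

#' Assemble documents into a corpus
#'
#' @param documents List of `lit_document` objects with unique `doc_id`s.
#' @param metadata Named list of creation parameters recorded alongside the
#'   documents (tokenizer settings, dedup policy, generator seeds ...).
#' @return A `lit_corpus` object.
#' @export
corpus <- function(documents, metadata = list()) {
  stopifnot(is.list(documents))
  ids <- vapply(documents, function(d) d$doc_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate doc_id in corpus: ", ids[duplicated(ids)][1])
  }
  names(documents) <- ids
  metadata$schema_version <- .litriage_schema_version
  structure(list(documents = documents, metadata = metadata),
            class = "lit_corpus")
}

#' @export
print.lit_corpus <- function(x, ...) {
  ns <- vapply(x$documents, function(d) nrow(d$sentences), integer(1))
  cat(sprintf("<lit_corpus> %d documents, %d unique sentences\n",
              length(x$documents), sum(ns)))
  invisible(x)
}

#' Persist a corpus to JSON / load it back
#'
#' The on-disk format is versioned JSON; loading a file written under a
#' different schema version fails explicitly rather than silently coercing.
#' `load_corpus(save_corpus(x, path))` is the identity on all fields.
#'
#' @param corp A `lit_corpus`.
#' @param path Output (or input) file path.
#' @return `save_corpus` invisibly returns `path`; `load_corpus` returns the
#'   `lit_corpus`.
#' @export
save_corpus <- function(corp, path) {
  stopifnot(inherits(corp, "lit_corpus"))
  docs <- lapply(unname(corp$documents), function(d) {
    list(doc_id = d$doc_id, source = d$source, raw_text = d$raw_text,
         sentences = d$sentences)
  })
  payload <- list(metadata = corp$metadata, documents = docs)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

#' @rdname save_corpus
#' @export
load_corpus <- function(path) {
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                      error = function(e) stop("malformed corpus file: ",
                                               conditionMessage(e)))
  if (is.null(payload$metadata) || is.null(payload$documents)) {
    stop("malformed corpus file: missing metadata or documents")
  }
  ver <- payload$metadata$schema_version
  if (is.null(ver) || !identical(as.character(ver), .litriage_schema_version)) {
    stop("corpus schema version mismatch: file has ",
         if (is.null(ver)) "<none>" else ver, ", expected ",
         .litriage_schema_version)
  }
  docs <- lapply(payload$documents, function(d) {
    sent <- d$sentences
    sdf <- if (length(sent) == 0L) {
      data.frame(sent_id = integer(), text = character(),
                 start = integer(), end = integer(), stringsAsFactors = FALSE)
    } else {
      do.call(rbind, lapply(sent, function(s) {
        data.frame(sent_id = as.integer(s$sent_id), text = s$text,
                   start = as.integer(s$start), end = as.integer(s$end),
                   stringsAsFactors = FALSE)
      }))
    }
    structure(list(doc_id = d$doc_id, source = d$source,
                   raw_text = d$raw_text, sentences = sdf),
              class = "lit_document")
  })
  meta <- payload$metadata
  meta$schema_version <- NULL
  corpus(docs, metadata = meta)
}

#' Question-answer benchmark items
#'
#' A benchmark item pairs a question with a target document and the set of
#' compound names any one of which makes a returned sentence correct; an
#' empty `gold_compounds` marks a document known to contain no answer.
#'
#' @param question Question string.
#' @param doc_id Target document identifier.
#' @param gold_compounds Character vector of acceptable compound names
#'   (possibly empty).
#' @return A `qa_benchmark_item`.
#' @export
benchmark_item <- function(question, doc_id, gold_compounds = character()) {
  structure(list(question = question, doc_id = doc_id,
                 gold_compounds = as.character(gold_compounds)),
            class = "qa_benchmark_item")
}

#' Read / write benchmark files (JSON list of items)
#'
#' @param items List of `qa_benchmark_item`.
#' @param path File path.
#' @return `read_benchmark` returns a list of `qa_benchmark_item`.
#' @export
write_benchmark <- function(items, path) {
  payload <- lapply(items, function(it) {
    list(question = it$question, doc_id = it$doc_id,
         gold_compounds = as.list(it$gold_compounds))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = FALSE)
  invisible(path)
}

#' @rdname write_benchmark
#' @export
read_benchmark <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(payload, function(it) {
    benchmark_item(it$question, it$doc_id,
                   unlist(it$gold_compounds, use.names = FALSE))
  })
}
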