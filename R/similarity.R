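#' Inner-product similarity between two embeddings
#'
#' @param q,s Numeric vectors of equal length.
#' @return Sum of elementwise products; lies in `[-1, 1]` when both inputs
#'   are L2-normalized.
#' @export
inner_product_score <- function(q, s) {
  if (length(q) != length(s)) {
    stop("dimension mismatch: ", length(q), " vs ", length(s))
  }
  sum(q * s)
}

#' Directed Hausdorff distance between two point sets
#'
#' `max` over rows of `A` of the Euclidean distance to the nearest row of
#' `B`.  Asymmetric: `directed_hausdorff(A, B)` is generally not
#' `directed_hausdorff(B, A)`.  For similarity ranking the negated distance
#' is used, so that higher is always more similar.
#'
#' @param A,B Numeric matrices (points in rows) of equal column dimension.
#' @return Non-negative scalar distance.
#' @export
directed_hausdorff <- function(A, B) {
  if (!is.matrix(A)) A <- matrix(A, nrow = 1)
  if (!is.matrix(B)) B <- matrix(B, nrow = 1)
  if (nrow(A) == 0L || nrow(B) == 0L) stop("empty point set")
  if (ncol(A) != ncol(B)) {
    stop("dimension mismatch: ", ncol(A), " vs ", ncol(B))
  }
  # ||a - b||^2 = ||a||^2 + ||b||^2 - 2 a.b, vectorized over both sets
  a2 <- rowSums(A^2)
  b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0  # numerical guard
  max(sqrt(apply(d2, 1, min)))
}

score_sentences <- function(question, document, method, config,
                            encoder = NULL) {
  sent <- document$sentences
  if (nrow(sent) == 0L) stop("empty document: ", document$doc_id)
  if (method == "inner_product") {
    qv <- embed_sentence(question, config, encoder = encoder)
    vapply(sent$text, function(tx) {
      inner_product_score(qv, embed_sentence(tx, config, encoder = encoder))
    }, numeric(1), USE.NAMES = FALSE)
  } else {
    qm <- embed_tokens(question, config)
    vapply(sent$text, function(tx) {
      -directed_hausdorff(qm, embed_tokens(tx, config))
    }, numeric(1), USE.NAMES = FALSE)
  }
}

#' Top-scoring answer sentence for one document
#'
#' Scores every sentence of the document against the question with the
#' chosen method and returns the argmax (ties broken by smallest sentence
#' id).  With the directed Hausdorff method the similarity is the negated
#' distance from the question's token set to the sentence's token set.
#'
#' @param question Question string.
#' @param document A `lit_document`.
#' @param method `"inner_product"` (default) or `"hausdorff"`.
#' @param config An [encoder_config()].
#' @param encoder Optional [external_encoder()] handle (inner product only).
#' @param floor Abstention floor: when the best score is strictly below it
#'   the document abstains (`abstained = TRUE`).  Default `-Inf`: always
#'   answer, as the top sentence is always returned in this workflow.
#' @param top_k Number of ranked sentences to return (default 1).
#' @return A data frame of `top_k` rows: `doc_id`, `sent_id`, `text`,
#'   `score`, `method`, `rank_within_document`, `abstained`.
#' @export
answer_for_document <- function(question, document,
                                method = c("inner_product", "hausdorff"),
                                config = encoder_config(), encoder = NULL,
                                floor = -Inf, top_k = 1L) {
  method <- match.arg(method)
  sc <- score_sentences(question, document, method, config, encoder)
  sent <- document$sentences
  ord <- order(-sc, sent$sent_id)
  keep <- head(ord, top_k)
  data.frame(doc_id = document$doc_id,
             sent_id = sent$sent_id[keep],
             text = sent$text[keep],
             score = sc[keep],
             method = method,
             rank_within_document = seq_along(keep),
             abstained = sc[keep[1]] < floor,
             stringsAsFactors = FALSE)
}

#' Mine a corpus: one ranked answer per document
#'
#' @inheritParams answer_for_document
#' @param corp A `lit_corpus`.
#' @return Data frame of ranked answers (rows = documents x `top_k`).
#' @export
mine_answers <- function(question, corp,
                         method = c("inner_product", "hausdorff"),
                         config = encoder_config(), encoder = NULL,
                         floor = -Inf, top_k = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(corp, "lit_corpus"))
  out <- lapply(corp$documents, function(d) {
    answer_for_document(question, d, method, config, encoder,
                        floor = floor, top_k = top_k)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Evaluate mined answers against a gold benchmark
#'
#' Per benchmark item: a true positive when the returned sentence contains
#' any gold compound name (case-insensitive substring); a false positive
#' when it contains none although `gold_compounds` is non-empty; a false
#' negative when the pipeline abstained on a document with a non-empty gold
#' set; a true negative when it abstained on a document with an empty gold
#' set.  An answered document with an empty gold set counts as a false
#' positive (the workflow asserted an answer where none exists).
#'
#' @param predictions Data frame from [mine_answers()] (rank-1 rows are
#'   used); the `abstained` column marks abstentions.
#' @param gold List of [benchmark_item()] objects.
#' @return A one-row data frame: `tp`, `fp`, `tn`, `fn`, `precision`,
#'   `recall`, `fscore` (0/0 conventions give 0).
#' @export
evaluate_answers <- function(predictions, gold) {
  preds <- predictions[predictions$rank_within_document == 1L, , drop = FALSE]
  unknown <- setdiff(preds$doc_id,
                     vapply(gold, function(g) g$doc_id, character(1)))
  if (length(unknown)) {
    stop("prediction for unknown doc_id: ", unknown[1])
  }
  tp <- fp <- tn <- fn <- 0L
  for (g in gold) {
    row <- preds[preds$doc_id == g$doc_id, , drop = FALSE]
    answered <- nrow(row) == 1L && !isTRUE(row$abstained)
    has_gold <- length(g$gold_compounds) > 0L
    if (answered) {
      hit <- has_gold && any(vapply(g$gold_compounds, function(nm) {
        grepl(tolower(nm), tolower(row$text), fixed = TRUE)
      }, logical(1)))
      if (hit) tp <- tp + 1L else fp <- fp + 1L
    } else {
      if (has_gold) fn <- fn + 1L else tn <- tn + 1L
    }
  }
  fscore_counts(tp, fp, tn, fn)
}

#' Precision / recall / f-score from confusion counts
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return One-row data frame with the counts and `precision`, `recall`,
#'   `fscore` (each 0 when its denominator is 0).
#' @export
fscore_counts <- function(tp, fp, tn = 0L, fn = 0L) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  fscore <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  data.frame(tp = tp, fp = fp, tn = tn, fn = fn,
             precision = precision, recall = recall, fscore = fscore)
}
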