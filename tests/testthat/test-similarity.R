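test_that("inner product matches hand-computed values", {
  expect_equal(inner_product_score(c(1, 0), c(1, 0)), 1)
  expect_equal(inner_product_score(c(1, 0), c(0, 1)), 0)
  expect_equal(inner_product_score(c(0.6, 0.8), c(0.8, 0.6)), 0.96)
  expect_error(inner_product_score(c(1, 0), c(1, 0, 0)), "dimension")
})

test_that("directed Hausdorff distance is exact on hand cases and asymmetric", {
  A <- matrix(c(0, 0), nrow = 1)
  expect_equal(directed_hausdorff(A, A), 0)
  expect_equal(directed_hausdorff(A, matrix(c(3, 4), nrow = 1)), 5)

  P <- matrix(c(0, 10), ncol = 1)        # points {0} and {10} on a line
  Q <- matrix(0, ncol = 1)
  expect_equal(directed_hausdorff(P, Q), 10)
  expect_equal(directed_hausdorff(Q, P), 0)

  expect_error(directed_hausdorff(matrix(0, 1, 2), matrix(0, 1, 3)),
               "dimension")
})

test_that("directed Hausdorff agrees with a brute-force double loop", {
  brute <- function(A, B) {
    best <- -Inf
    for (i in seq_len(nrow(A))) {
      mind <- Inf
      for (j in seq_len(nrow(B))) {
        mind <- min(mind, sqrt(sum((A[i, ] - B[j, ])^2)))
      }
      best <- max(best, mind)
    }
    best
  }
  set.seed(3)
  for (case in 1:50) {
    d <- sample(1:4, 1)
    A <- matrix(rnorm(sample(1:8, 1) * d), ncol = d)
    B <- matrix(rnorm(sample(1:8, 1) * d), ncol = d)
    expect_equal(directed_hausdorff(A, B), brute(A, B), tolerance = 1e-12)
  }
})

test_that("zero distance iff every row of A occurs in B", {
  set.seed(8)
  for (case in 1:30) {
    B <- unique(matrix(sample(0:3, 12, replace = TRUE), ncol = 2))
    A <- B[sample(nrow(B), sample(nrow(B), 1)), , drop = FALSE]
    expect_equal(directed_hausdorff(A, B), 0)
    # move one point of A off-grid: distance becomes positive
    A2 <- A
    A2[1, 1] <- A2[1, 1] + 0.5
    expect_gt(directed_hausdorff(A2, B), 0)
  }
})

test_that("answer selection returns the argmax with deterministic ties", {
  q <- "what are the drugs that affect oxidative stress in chronic diseases?"
  d <- document("d1", paste(q, ""))
  ans <- answer_for_document(q, d)
  expect_equal(ans$score, 1, tolerance = 1e-12)

  # identical sentences cannot survive dedup, so force a tie with two
  # sentences of entirely disjoint vocabulary (both score ~0 vs question)
  d2 <- document("d2", "Aaa bbb ccc ddd. Aaa bbb ccc ddd eee.")
  two <- answer_for_document("zzz yyy xxx", d2)
  expect_equal(two$sent_id, 1L)

  expect_error(answer_for_document(q, document("d3", "")), "empty document")
})

test_that("planted sentence wins over disjoint fillers (seed 7)", {
  cg <- make_corpus(corpus_spec(n_docs = 1L, filler_sentences_per_doc = 9L,
                                seed = 7L))
  doc <- cg$corpus$documents[[1]]
  gold_name <- cg$gold[[1]]$gold_compounds
  q <- default_question()
  # brute-force oracle: embed and score each sentence independently
  qv <- embed_sentence(q)
  scores <- vapply(doc$sentences$text,
                   function(tx) sum(qv * embed_sentence(tx)), numeric(1))
  best <- doc$sentences$sent_id[which.max(scores)]
  ans <- answer_for_document(q, doc)
  expect_equal(ans$sent_id, best)
  expect_true(grepl(gold_name, ans$text, fixed = TRUE))
})

test_that("evaluation implements the confusion-count formulas", {
  expect_equal(fscore_counts(10, 0, 0, 0)$fscore, 1)
  ev <- fscore_counts(1, 1, 0, 1)
  expect_equal(ev$precision, 0.5)
  expect_equal(ev$recall, 0.5)
  expect_equal(ev$fscore, 0.5)
  expect_equal(fscore_counts(0, 3, 0, 0)$fscore, 0)
})

test_that("evaluate_answers matches a brute-force confusion matrix", {
  set.seed(21)
  for (case in 1:100) {
    n <- sample(3:8, 1)
    gold <- lapply(seq_len(n), function(i) {
      benchmark_item("q?", sprintf("doc%d", i),
                     if (runif(1) < 0.7) sprintf("cmpd%d", i) else character())
    })
    preds <- do.call(rbind, lapply(seq_len(n), function(i) {
      hit <- runif(1) < 0.5
      data.frame(doc_id = sprintf("doc%d", i), sent_id = 1L,
                 text = if (hit) sprintf("Compound cmpd%d works.", i)
                        else "Nothing relevant.",
                 score = runif(1), method = "inner_product",
                 rank_within_document = 1L,
                 abstained = runif(1) < 0.2, stringsAsFactors = FALSE)
    }))
    got <- evaluate_answers(preds, gold)
    want <- brute_confusion(preds, gold)
    expect_equal(c(tp = got$tp, fp = got$fp, tn = got$tn, fn = got$fn), want)
  }
})

test_that("evaluation rejects predictions for unknown documents", {
  gold <- list(benchmark_item("q?", "doc1", "cmpd1"))
  preds <- data.frame(doc_id = "docX", sent_id = 1L, text = "x",
                      score = 0, method = "inner_product",
                      rank_within_document = 1L, abstained = FALSE)
  expect_error(evaluate_answers(preds, gold), "unknown doc_id")
})

test_that("inner-product retrieval beats Hausdorff on the planted benchmark", {
  cg <- fix_corpus42()
  q <- default_question()
  ev_ip <- evaluate_answers(mine_answers(q, cg$corpus), cg$gold)
  ev_h <- evaluate_answers(mine_answers(q, cg$corpus, method = "hausdorff"),
                           cg$gold)
  expect_gte(ev_ip$fscore, ev_h$fscore)
  expect_gt(ev_ip$fscore, 0.9)   # planted corpus is designed to be easy
})
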