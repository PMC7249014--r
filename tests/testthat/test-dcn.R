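rnorm_seeded <- function(n, seed) {
  set.seed(seed)
  rnorm(n)
}

tiny_cfg <- function(...) {
  dcn_config(input_dim = 12L, grid_shape = c(3L, 4L), kernel = c(2L, 2L),
             n_filters = 3L, dense_units = 4L, input_gain = 1, ...)
}

test_that("feature extraction reproduces a hand convolution", {
  cfg <- dcn_config(input_dim = 4L, grid_shape = c(1L, 4L),
                    kernel = c(1L, 3L), n_filters = 1L, dense_units = 1L,
                    input_gain = 1)
  model <- dcn_init(cfg)
  model$branch_q <- list(Wc = matrix(c(1, 0, -1), ncol = 1), bc = 0,
                         Wd = matrix(1, 1, 1), bd = 0)
  # input (1,2,3,4): windows (1,2,3) and (2,3,4) give -2 and -2; the
  # rectifier zeroes both, the max-pool and the unit dense map keep 0
  expect_equal(extract_features(c(1, 2, 3, 4), model), 0)

  # flipping the kernel sign makes the windows (2, 2) -> pooled 2
  model$branch_q$Wc <- matrix(c(-1, 0, 1), ncol = 1)
  expect_equal(extract_features(c(1, 2, 3, 4), model), 2)
})

test_that("zero embedding with zero biases maps to zero features", {
  cfg <- tiny_cfg(seed = 4L)
  model <- dcn_init(cfg)
  model$branch_q$bc[] <- 0
  model$branch_q$bd[] <- 0
  expect_equal(extract_features(rep(0, 12), model), rep(0, 4))
  f1 <- extract_features(rnorm_seeded(12, 1), model)
  expect_identical(f1, extract_features(rnorm_seeded(12, 1), model))
})

test_that("relevance score is 1 at identity, symmetric, and in (0, 1]", {
  model <- dcn_init(tiny_cfg(seed = 1L))
  x <- rnorm_seeded(12, 2)
  y <- rnorm_seeded(12, 3)
  expect_identical(relevance_score(x, x, model), 1)
  expect_equal(relevance_score(x, y, model), relevance_score(y, x, model))
  for (s in 4:8) {
    v <- relevance_score(x, rnorm_seeded(12, s), model)
    expect_gt(v, 0)
    expect_lte(v, 1)
  }
})

test_that("features differing by exactly 1 per component score exp(-1)", {
  cfg <- tiny_cfg(seed = 2L, siamese = FALSE)
  model <- dcn_init(cfg)
  model$branch_a <- model$branch_q
  model$branch_a$bd <- model$branch_q$bd + 1   # shift every feature by 1
  x <- rnorm_seeded(12, 9)
  expect_equal(relevance_score(x, x, model), exp(-1), tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences", {
  cfg <- tiny_cfg(seed = 6L)
  model <- dcn_init(cfg)
  set.seed(13)
  pairs <- list(q = matrix(rnorm(5 * 12), 5), a = matrix(rnorm(5 * 12), 5),
                label = c(1, 0, 1, 0, 1))
  lg <- litriage:::dcn_loss_grad(model, pairs)
  eps <- 1e-6
  for (field in c("Wc", "bc", "Wd", "bd")) {
    w <- model$branch_q[[field]]
    g <- lg$grad_q[[field]]
    idx <- seq_along(w)
    if (length(idx) > 6) idx <- idx[c(1, 2, 3, length(idx) - 1, length(idx))]
    for (i in idx) {
      up <- model; up$branch_q[[field]][i] <- w[i] + eps
      dn <- model; dn$branch_q[[field]][i] <- w[i] - eps
      fd <- (litriage:::dcn_loss_grad(up, pairs, want_grad = FALSE)$loss -
             litriage:::dcn_loss_grad(dn, pairs, want_grad = FALSE)$loss) /
            (2 * eps)
      denom <- max(abs(fd), abs(g[i]), 1e-8)
      expect_lt(abs(fd - g[i]) / denom, 1e-4)
    }
  }
})

test_that("training is deterministic and rejects degenerate inputs", {
  set.seed(31)
  pairs <- list(q = matrix(rnorm(8 * 12), 8), a = matrix(rnorm(8 * 12), 8),
                label = rep(c(1, 0), 4))
  cfg <- tiny_cfg(seed = 3L, epochs = 5L, batch_size = 4L)
  m1 <- train_dcn(pairs, cfg)
  m2 <- train_dcn(pairs, cfg)
  expect_identical(m1$branch_q, m2$branch_q)

  ones <- pairs; ones$label <- rep(1, 8)
  expect_error(train_dcn(ones, cfg), "both labels")
})

test_that("full-batch descent at a small learning rate never increases loss", {
  set.seed(17)
  pairs <- list(q = matrix(rnorm(10 * 12), 10),
                a = matrix(rnorm(10 * 12), 10),
                label = rep(c(1, 0), 5))
  cfg <- tiny_cfg(seed = 5L, learning_rate = 0.001, epochs = 40L,
                  batch_size = 10L)
  model <- train_dcn(pairs, cfg)
  hist <- attr(model, "loss_history")
  expect_true(all(diff(hist) <= 1e-6))
})

test_that("trained relevance separates planted pairs from fillers (seed 1)", {
  cg <- make_corpus(corpus_spec(n_docs = 100L, n_compounds = 100L,
                                seed = 1L))
  pairs <- make_relevance_pairs(cg$corpus, cg$gold, seed = 1L)
  tr <- seq_len(150L); te <- 151:200
  model <- train_dcn(list(q = pairs$q[tr, ], a = pairs$a[tr, ],
                          label = pairs$label[tr]),
                     dcn_config(seed = 1L))
  sc_tr <- vapply(tr, function(i) {
    relevance_score(pairs$q[i, ], pairs$a[i, ], model)
  }, numeric(1))
  cuts <- sort(unique(sc_tr))
  accs <- vapply(cuts, function(th) {
    mean((sc_tr >= th) == (pairs$label[tr] == 1))
  }, numeric(1))
  best <- cuts[which.max(accs)]
  sc_te <- vapply(te, function(i) {
    relevance_score(pairs$q[i, ], pairs$a[i, ], model)
  }, numeric(1))
  acc <- mean((sc_te >= best) == (pairs$label[te] == 1))
  expect_gte(acc, 0.9)
})

test_that("answer filtering honors the threshold and preserves order", {
  cg <- fix_corpus42()
  model <- fix_dcn42()
  q <- default_question()
  answers <- mine_answers(q, cg$corpus)
  kept <- filter_answers(answers, q, model)
  expect_true(all(kept$relevance >= model$config$threshold))
  expect_equal(kept$doc_id, answers$doc_id[answers$doc_id %in% kept$doc_id])

  empty <- answers[0, ]
  expect_equal(nrow(filter_answers(empty, q, model)), 0L)

  expect_warning(out <- filter_answers(answers, q, model, threshold = 1),
                 "below the relevance threshold")
  expect_equal(nrow(out), 0L)
})

test_that("the converged filter drops fillers but keeps every planted answer", {
  cg <- fix_corpus42()
  model <- fix_dcn42()
  q <- default_question()
  # candidate set: top-2 sentences per document, so each document
  # contributes its planted answer plus its best filler
  cands <- mine_answers(q, cg$corpus, top_k = 2L)
  kept <- filter_answers(cands, q, model)
  expect_lt(nrow(kept), nrow(cands))
  gold_names <- unlist(lapply(cg$gold, `[[`, "gold_compounds"))
  for (nm in gold_names) {
    expect_true(any(grepl(nm, kept$text, fixed = TRUE)))
  }
  # the filter rejects the clear majority of the filler candidates
  fillers <- cands[!grepl("cmpd_", cands$text), ]
  kept_fillers <- kept[!grepl("cmpd_", kept$text), ]
  expect_gt(1 - nrow(kept_fillers) / nrow(fillers), 0.5)
})

test_that("DCN models round-trip through the JSON manifest exactly", {
  model <- fix_dcn42()
  path <- withr::local_tempfile(fileext = ".json")
  save_dcn(model, path)
  back <- load_dcn(path)
  expect_equal(back$branch_q, model$branch_q)
  expect_equal(unclass(back$config), unclass(model$config))
  x <- rnorm_seeded(512, 77)
  y <- rnorm_seeded(512, 78)
  expect_equal(relevance_score(x, y, back), relevance_score(x, y, model))
})
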