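#' Differential convolution network configuration
#'
#' The relevance scorer is a siamese pair of convolutional feature
#' extractors: a sentence embedding is reshaped row-major onto a 2-D grid,
#' convolved (valid padding) with `n_filters` kernels, rectified, global
#' max-pooled per filter, and mapped affinely to `dense_units` features.
#' The relevance of a question-answer pair is `exp(-MSE)` of the two
#' branches' feature vectors, so identical inputs score exactly 1 and the
#' acceptance threshold (default 0.98) lives on a calibrated (0, 1] scale.
#'
#' @param input_dim Embedding dimension (default 512).
#' @param grid_shape `(rows, cols)` with `rows * cols == input_dim`
#'   (default `c(16, 32)`).
#' @param kernel Convolution kernel shape (default `c(3, 3)`).
#' @param n_filters Number of convolution filters (default 16; enough that
#'   every input keeps at least one active rectifier unit).
#' @param dense_units Feature dimension after the dense layer (default 32).
#' @param seed Seed for weight initialization and batch shuffling.
#' @param learning_rate Gradient-descent step size (default 0.2).
#' @param epochs Training epochs (default 50).
#' @param batch_size Minibatch size (default 16).
#' @param threshold Relevance acceptance threshold in `(0, 1]`
#'   (default 0.98).
#' @param input_gain Fixed gain applied to the embedding before the
#'   convolution (default 20).  Unit-norm sentence embeddings have entries
#'   of magnitude well below 1, which would leave both branches' features
#'   nearly identical at the small random initialization and stall training
#'   in the `exp(-MSE) = 1` saturation region; the gain puts the feature
#'   difference on an O(1) scale where gradients are informative.
#' @param siamese Share weights between the two branches (default `TRUE`).
#'   Sharing makes `relevance_score(x, x) == 1` exactly; the unshared
#'   variant is available for comparison.
#' @return A `dcn_config` list.
#' @export
dcn_config <- function(input_dim = 512L, grid_shape = c(16L, 32L),
                       kernel = c(3L, 3L), n_filters = 16L,
                       dense_units = 32L, seed = 0L,
                       learning_rate = 0.2, epochs = 50L,
                       batch_size = 16L, threshold = 0.98,
                       input_gain = 20, siamese = TRUE) {
  input_dim <- as.integer(input_dim)
  grid_shape <- as.integer(grid_shape)
  kernel <- as.integer(kernel)
  stopifnot(length(grid_shape) == 2L, prod(grid_shape) == input_dim,
            length(kernel) == 2L, all(kernel >= 1L),
            all(kernel <= grid_shape),
            n_filters >= 1L, dense_units >= 1L,
            threshold > 0, threshold <= 1)
  structure(list(input_dim = input_dim, grid_shape = grid_shape,
                 kernel = kernel, n_filters = as.integer(n_filters),
                 dense_units = as.integer(dense_units),
                 seed = as.integer(seed),
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 threshold = threshold, input_gain = input_gain,
                 siamese = isTRUE(siamese)),
            class = "dcn_config")
}

# Linear indices (into the column-major grid matrix) of every valid kernel
# patch, one patch per row.  Computed once per config.
dcn_patch_index <- function(config) {
  rows <- config$grid_shape[1]; cols <- config$grid_shape[2]
  kh <- config$kernel[1]; kw <- config$kernel[2]
  orow <- rows - kh + 1L; ocol <- cols - kw + 1L
  # patch-internal offsets, row-major within the kernel window
  off <- as.vector(t(outer(seq_len(kh) - 1L, (seq_len(kw) - 1L) * rows, "+")))
  origins <- as.vector(outer(seq_len(orow), (seq_len(ocol) - 1L) * rows, "+"))
  idx <- outer(origins, off, "+")
  storage.mode(idx) <- "integer"
  idx
}

# Embedding -> patch matrix (n_patches x kernel_size), row-major grid.
dcn_patches <- function(embedding, config, idx = dcn_patch_index(config)) {
  if (length(embedding) != config$input_dim) {
    stop("dimension mismatch: embedding has ", length(embedding),
         " values, model expects ", config$input_dim)
  }
  g <- matrix(embedding * config$input_gain, nrow = config$grid_shape[1],
              ncol = config$grid_shape[2], byrow = TRUE)
  matrix(g[idx], nrow = nrow(idx))
}

dcn_init_branch <- function(config) {
  k <- prod(config$kernel)
  list(Wc = matrix(runif(k * config$n_filters, -0.1, 0.1), nrow = k),
       bc = runif(config$n_filters, -0.1, 0.1),
       Wd = matrix(runif(config$n_filters * config$dense_units, -0.1, 0.1),
                   nrow = config$n_filters),
       bd = runif(config$dense_units, -0.1, 0.1))
}

#' Initialize an untrained DCN model
#'
#' Weights are drawn from a seeded uniform(-0.1, 0.1); with `siamese = TRUE`
#' one branch parameter set is shared.
#'
#' @param config A [dcn_config()].
#' @return A `dcn_model`.
#' @export
dcn_init <- function(config = dcn_config()) {
  model <- local_seed(config$seed, {
    if (config$siamese) {
      list(branch_q = dcn_init_branch(config), branch_a = NULL)
    } else {
      list(branch_q = dcn_init_branch(config),
           branch_a = dcn_init_branch(config))
    }
  })
  model$config <- config
  class(model) <- "dcn_model"
  model
}

dcn_branch <- function(model, which) {
  if (model$config$siamese || which == "q") model$branch_q else model$branch_a
}

# Forward pass of one branch.  Returns feature vector and the cache needed
# for backprop (patches, pre-pool activations, argmax locations).
dcn_forward_branch <- function(P, br) {
  Z <- sweep(P %*% br$Wc, 2, br$bc, "+")   # n_patches x n_filters
  A <- Z * (Z > 0)
  pool <- apply(A, 2, max)
  amax <- max.col(t(A), ties.method = "first")  # row index of max per filter
  f <- drop(pool %*% br$Wd) + br$bd
  list(f = f, pool = pool, amax = amax)
}

#' Extract DCN features for one embedding
#'
#' Reshape to the configured grid (row-major), valid-padding 2-D
#' convolution, rectifier, global max-pool per filter, affine map to the
#' dense feature space.  Deterministic given the model.
#'
#' @param embedding Numeric vector of length `config$input_dim`.
#' @param model A `dcn_model`.
#' @param branch `"q"` or `"a"` (identical when the model is siamese).
#' @return Numeric feature vector of length `dense_units`.
#' @export
extract_features <- function(embedding, model, branch = "q") {
  config <- model$config
  P <- dcn_patches(embedding, config)
  dcn_forward_branch(P, dcn_branch(model, branch))$f
}

#' Relevance score of a question-answer embedding pair
#'
#' `exp(-MSE)` of the two branch feature vectors; in `(0, 1]`, exactly 1 for
#' identical inputs under a siamese model.
#'
#' @param q_emb,a_emb Numeric embeddings of length `input_dim`.
#' @param model A `dcn_model`.
#' @return Scalar relevance in `(0, 1]`.
#' @export
relevance_score <- function(q_emb, a_emb, model) {
  fq <- extract_features(q_emb, model, "q")
  fa <- extract_features(a_emb, model, "a")
  exp(-mean((fq - fa)^2))
}

# Loss and analytic gradient over a set of pairs.
# pairs: list(q = n x d matrix, a = n x d matrix, label = numeric n)
# Pq, Pa: optional precomputed patch lists.
dcn_loss_grad <- function(model, pairs, Pq = NULL, Pa = NULL,
                          subset = NULL, want_grad = TRUE) {
  config <- model$config
  idx <- dcn_patch_index(config)
  n_all <- length(pairs$label)
  if (is.null(subset)) subset <- seq_len(n_all)
  n <- length(subset)
  brq <- dcn_branch(model, "q")
  bra <- dcn_branch(model, "a")
  zero_grad <- function(br) {
    list(Wc = br$Wc * 0, bc = br$bc * 0, Wd = br$Wd * 0, bd = br$bd * 0)
  }
  gq <- zero_grad(brq)
  ga <- if (config$siamese) NULL else zero_grad(bra)
  du <- config$dense_units
  loss <- 0
  for (i in subset) {
    P1 <- if (is.null(Pq)) dcn_patches(pairs$q[i, ], config, idx) else Pq[[i]]
    P2 <- if (is.null(Pa)) dcn_patches(pairs$a[i, ], config, idx) else Pa[[i]]
    o1 <- dcn_forward_branch(P1, brq)
    o2 <- dcn_forward_branch(P2, bra)
    diff <- o1$f - o2$f
    mse <- mean(diff^2)
    s <- exp(-mse)
    r <- s - pairs$label[i]
    loss <- loss + r^2
    if (!want_grad) next
    ds <- 2 * r / n
    dmse <- -s * ds
    df1 <- dmse * 2 * diff / du
    df2 <- -df1
    # branch q
    dm1 <- drop(brq$Wd %*% df1)
    for (j in seq_len(config$n_filters)) {
      if (o1$pool[j] > 0) {
        r1 <- o1$amax[j]
        gq$Wc[, j] <- gq$Wc[, j] + dm1[j] * P1[r1, ]
        gq$bc[j] <- gq$bc[j] + dm1[j]
      }
    }
    gq$Wd <- gq$Wd + outer(o1$pool, df1)
    gq$bd <- gq$bd + df1
    # branch a (accumulates into the shared gradient when siamese)
    dm2 <- drop(bra$Wd %*% df2)
    g2 <- if (config$siamese) gq else ga
    for (j in seq_len(config$n_filters)) {
      if (o2$pool[j] > 0) {
        r2 <- o2$amax[j]
        g2$Wc[, j] <- g2$Wc[, j] + dm2[j] * P2[r2, ]
        g2$bc[j] <- g2$bc[j] + dm2[j]
      }
    }
    g2$Wd <- g2$Wd + outer(o2$pool, df2)
    g2$bd <- g2$bd + df2
    if (config$siamese) gq <- g2 else ga <- g2
  }
  list(loss = loss / n, grad_q = gq, grad_a = ga)
}

#' Train the DCN relevance scorer
#'
#' Minimizes the mean of `(relevance_score - label)^2` over labeled
#' question-answer embedding pairs by minibatch gradient descent with a
#' seeded uniform(-0.1, 0.1) initialization and seeded shuffling, so
#' retraining with the same data and config reproduces the weights exactly.
#'
#' @param pairs A `relevance_pairs` object (see [make_relevance_pairs()]) or
#'   a list with elements `q` (n x input_dim matrix), `a` (matching matrix)
#'   and `label` (0/1 vector).
#' @param config A [dcn_config()].
#' @param track_history Record the full-data loss after every epoch
#'   (default `TRUE`; disable to halve the cost of long training runs, the
#'   initial and final loss are always recorded).
#' @return A trained `dcn_model` with attributes `final_loss` and
#'   `loss_history` (full-data loss after each tracked epoch, first entry =
#'   before training).
#' @export
train_dcn <- function(pairs, config = dcn_config(), track_history = TRUE) {
  stopifnot(is.matrix(pairs$q), is.matrix(pairs$a),
            nrow(pairs$q) == nrow(pairs$a),
            nrow(pairs$q) == length(pairs$label))
  n <- length(pairs$label)
  if (n < 2L || length(unique(pairs$label)) < 2L) {
    stop("training needs at least two pairs with both labels present")
  }
  model <- dcn_init(config)
  idx <- dcn_patch_index(config)
  Pq <- lapply(seq_len(n), function(i) dcn_patches(pairs$q[i, ], config, idx))
  Pa <- lapply(seq_len(n), function(i) dcn_patches(pairs$a[i, ], config, idx))
  history <- dcn_loss_grad(model, pairs, Pq, Pa, want_grad = FALSE)$loss
  local_seed(config$seed + 1L, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      for (s in starts) {
        batch <- ord[s:min(s + config$batch_size - 1L, n)]
        lg <- dcn_loss_grad(model, pairs, Pq, Pa, subset = batch)
        if (!is.finite(lg$loss)) {
          stop("non-finite training loss at epoch ", ep)
        }
        lr <- config$learning_rate
        upd <- function(br, g) {
          br$Wc <- br$Wc - lr * g$Wc; br$bc <- br$bc - lr * g$bc
          br$Wd <- br$Wd - lr * g$Wd; br$bd <- br$bd - lr * g$bd
          br
        }
        model$branch_q <- upd(model$branch_q, lg$grad_q)
        if (!config$siamese) {
          model$branch_a <- upd(model$branch_a, lg$grad_a)
        }
      }
      if (track_history || ep == config$epochs) {
        history <- c(history,
                     dcn_loss_grad(model, pairs, Pq, Pa,
                                   want_grad = FALSE)$loss)
      }
    }
  })
  attr(model, "loss_history") <- history
  attr(model, "final_loss") <- history[length(history)]
  model
}

#' Filter mined answers by DCN relevance
#'
#' Scores each answer sentence against the question with the trained model
#' and retains those with relevance at or above the threshold, preserving
#' input order.
#'
#' @param answers Data frame from [mine_answers()] (needs `text`).
#' @param question Question string.
#' @param model Trained `dcn_model`.
#' @param config Encoder config used to embed question and answers.
#' @param encoder Optional external encoder handle.
#' @param threshold Relevance threshold; defaults to the model's configured
#'   value (0.98).
#' @return The retained rows of `answers` with a `relevance` column added.
#' @export
filter_answers <- function(answers, question, model,
                           config = encoder_config(), encoder = NULL,
                           threshold = model$config$threshold) {
  if (nrow(answers) == 0L) {
    answers$relevance <- numeric(0)
    return(answers)
  }
  qv <- embed_sentence(question, config, encoder = encoder)
  rel <- vapply(answers$text, function(tx) {
    relevance_score(qv, embed_sentence(tx, config, encoder = encoder), model)
  }, numeric(1), USE.NAMES = FALSE)
  answers$relevance <- rel
  keep <- rel >= threshold
  if (!any(keep)) {
    warning("all answers fall below the relevance threshold ", threshold)
  }
  answers[keep, , drop = FALSE]
}

#' Serialize / restore a DCN model (JSON weight manifest)
#'
#' @param model A `dcn_model`.
#' @param path File path.
#' @return `load_dcn` returns the model; round-trip is exact.
#' @export
save_dcn <- function(model, path) {
  ser_branch <- function(br) {
    if (is.null(br)) return(NULL)
    list(Wc = as.vector(br$Wc), bc = br$bc,
         Wd = as.vector(br$Wd), bd = br$bd)
  }
  payload <- list(schema_version = .litriage_schema_version,
                  config = unclass(model$config),
                  branch_q = ser_branch(model$branch_q),
                  branch_a = ser_branch(model$branch_a))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_dcn
#' @export
load_dcn <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(as.character(payload$schema_version),
                 .litriage_schema_version)) {
    stop("dcn model schema version mismatch")
  }
  cfgl <- payload$config
  config <- dcn_config(input_dim = cfgl$input_dim,
                       grid_shape = cfgl$grid_shape, kernel = cfgl$kernel,
                       n_filters = cfgl$n_filters,
                       dense_units = cfgl$dense_units, seed = cfgl$seed,
                       learning_rate = cfgl$learning_rate,
                       epochs = cfgl$epochs, batch_size = cfgl$batch_size,
                       threshold = cfgl$threshold,
                       input_gain = cfgl$input_gain, siamese = cfgl$siamese)
  de_branch <- function(br) {
    if (is.null(br) || length(br) == 0L) return(NULL)
    k <- prod(config$kernel)
    list(Wc = matrix(br$Wc, nrow = k), bc = br$bc,
         Wd = matrix(br$Wd, nrow = config$n_filters), bd = br$bd)
  }
  model <- list(branch_q = de_branch(payload$branch_q),
                branch_a = de_branch(payload$branch_a),
                config = config)
  class(model) <- "dcn_model"
  model
}
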