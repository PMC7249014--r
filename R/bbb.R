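#' Train the blood-brain-barrier permeability classifier
#'
#' A linear soft-margin support-vector machine over molecular fingerprint
#' bits (hinge loss + L2 penalty, fitted with the deterministic libsvm
#' solver via \pkg{e1071}).  The decision function is reduced to an explicit
#' weight vector and bias so that prediction is a plain dot product.
#'
#' @param X Numeric/integer matrix, rows = compounds, columns = fingerprint
#'   bits.
#' @param y Labels in `{-1, +1}` (or coercible logicals; `+1` = crosses).
#' @param cost Soft-margin cost parameter; `NULL` (the default) selects it
#'   from `cost_grid` by seeded 5-fold cross-validation on the training
#'   data, which is what keeps the classifier calibrated under label noise.
#' @param cost_grid Candidate costs for the internal cross-validation.
#' @param cv_seed Seed for the cross-validation folds.
#' @param fp_bits Fingerprint length recorded in the model (default
#'   `ncol(X)`).
#' @param fp_radius Fingerprint radius recorded in the model (default 2).
#' @return A `bbb_model`: list with `weights`, `bias`, `n_bits`, `radius`.
#' @export
train_bbb_svm <- function(X, y, cost = NULL,
                          cost_grid = c(0.03, 0.1, 0.3, 1, 3),
                          cv_seed = 1L, fp_bits = ncol(X),
                          fp_radius = 2L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  y[y == 0] <- -1
  if (length(unique(y)) < 2L) {
    stop("single-class training set: both BBB classes must be present")
  }
  if (is.null(cost)) {
    cost <- if (nrow(X) >= 20L) {
      select_svm_cost(X, y, cost_grid, cv_seed)
    } else 1
  }
  fit <- e1071::svm(x = X, y = factor(y, levels = c(-1, 1)),
                    kernel = "linear", cost = cost, scale = FALSE)
  w <- drop(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  # libsvm orients the decision value toward whichever class it saw first;
  # re-orient against the model's own class predictions so that a positive
  # score always means the +1 class
  pred <- as.numeric(as.character(predict(fit, X)))
  dec <- drop(X %*% w + b)
  agree <- mean(sign(dec)[pred != 0] == pred[pred != 0])
  if (!is.nan(agree) && agree < 0.5) {
    w <- -w
    b <- -b
  }
  structure(list(weights = as.numeric(w), bias = as.numeric(b),
                 n_bits = as.integer(fp_bits),
                 radius = as.integer(fp_radius), cost = cost),
            class = "bbb_model")
}

#' Predict blood-brain-barrier crossing
#'
#' @param mol A `lit_molecule`, SMILES string, or a precomputed fingerprint
#'   bit vector of length `model$n_bits`.
#' @param model A `bbb_model`.
#' @return A list with `score` (signed margin, `weights . fp + bias`) and
#'   `crossing` (`score > 0`).
#' @export
predict_bbb <- function(mol, model) {
  fp <- if (is.numeric(mol) && !inherits(mol, "lit_molecule")) {
    mol
  } else {
    fingerprint(as_molecule(mol), n_bits = model$n_bits,
                radius = model$radius)
  }
  if (length(fp) != model$n_bits) {
    stop("fingerprint size mismatch: ", length(fp), " vs model ",
         model$n_bits)
  }
  score <- sum(model$weights * fp) + model$bias
  list(score = score, crossing = score > 0)
}

#' Serialize / restore a BBB model (JSON weight manifest)
#'
#' @param model A `bbb_model`.
#' @param path File path.
#' @return `load_bbb` returns the model.
#' @export
save_bbb <- function(model, path) {
  payload <- c(list(schema_version = .litriage_schema_version),
               unclass(model))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_bbb
#' @export
load_bbb <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(as.character(p$schema_version), .litriage_schema_version)) {
    stop("bbb model schema version mismatch")
  }
  structure(list(weights = p$weights, bias = p$bias,
                 n_bits = as.integer(p$n_bits),
                 radius = as.integer(p$radius), cost = p$cost),
            class = "bbb_model")
}

# Seeded 5-fold cross-validation over the cost grid; ties go to the
# smallest (most regularized) cost.
select_svm_cost <- function(X, y, cost_grid, cv_seed) {
  n <- nrow(X)
  folds <- local_seed(cv_seed, sample(rep(1:5, length.out = n)))
  accs <- vapply(cost_grid, function(cc) {
    mean(vapply(1:5, function(f) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2L) return(NA_real_)
      fit <- e1071::svm(x = X[tr, , drop = FALSE],
                        y = factor(y[tr], levels = c(-1, 1)),
                        kernel = "linear", cost = cc, scale = FALSE)
      mean(as.numeric(as.character(
        predict(fit, X[!tr, , drop = FALSE]))) == y[!tr])
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  cost_grid[which.max(accs)]
}
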