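#' Encoder configuration
#'
#' The default encoder is a deterministic hashed bag-of-ngrams deep-averaging
#' scheme: each word and adjacent bigram is mapped by signed feature hashing
#' (64-bit FNV-1a, salted by `hash_seed`; index = hash mod `dimension`, sign
#' from bit 63) to a signed unit basis vector; a sentence embedding is the
#' mean of its unit vectors, optionally L2-normalized.  It shares the
#' interface and dimensionality of pretrained deep-averaging-network sentence
#' encoders, which can be plugged in via [external_encoder()].
#'
#' @param kind `"hashing_dan"` (default) or `"external_adapter"`.
#' @param dimension Embedding dimension (default 512, minimum 2).
#' @param ngram_orders Integer set within `{1, 2, 3}` (default `c(1, 2)`).
#' @param hash_seed Integer salt for the hash (default 0).
#' @param normalize L2-normalize sentence embeddings (default `TRUE`).
#' @return An `encoder_config` list.
#' @export
encoder_config <- function(kind = c("hashing_dan", "external_adapter"),
                           dimension = 512L, ngram_orders = c(1L, 2L),
                           hash_seed = 0L, normalize = TRUE) {
  kind <- match.arg(kind)
  dimension <- as.integer(dimension)
  ngram_orders <- sort(unique(as.integer(ngram_orders)))
  stopifnot(dimension >= 2L, all(ngram_orders %in% 1:3),
            length(ngram_orders) >= 1L)
  structure(list(kind = kind, dimension = dimension,
                 ngram_orders = ngram_orders,
                 hash_seed = as.integer(hash_seed),
                 normalize = isTRUE(normalize)),
            class = "encoder_config")
}

# Lowercase and split on non-alphanumeric runs.  This is the embedding
# tokenizer only (the corpus sentence tokenizer is separate); words keep
# digits so compound codes like "cmpd_07" survive as two tokens.
embed_tokenize <- function(text) {
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
  toks[nzchar(toks)]
}

ngram_units <- function(tokens, orders) {
  units <- character(0)
  for (k in orders) {
    if (length(tokens) >= k) {
      if (k == 1L) {
        units <- c(units, tokens)
      } else {
        idx <- seq_len(length(tokens) - k + 1L)
        grams <- vapply(idx, function(i) {
          paste(tokens[i:(i + k - 1L)], collapse = " ")
        }, character(1))
        units <- c(units, grams)
      }
    }
  }
  units
}

#' Per-token embedding matrix
#'
#' One row per word / n-gram unit in text order; each row is the signed unit
#' basis vector assigned by the hashing encoder (exactly one nonzero entry of
#' magnitude 1).
#'
#' @param sentence_text Non-empty sentence string.
#' @param config An [encoder_config()].
#' @return A numeric matrix (`units x dimension`) with `rownames` giving the
#'   unit labels.
#' @export
embed_tokens <- function(sentence_text, config = encoder_config()) {
  toks <- embed_tokenize(sentence_text)
  if (length(toks) == 0L) {
    stop("empty sentence")
  }
  units <- ngram_units(toks, config$ngram_orders)
  idx <- fnv_index(units, config$dimension, config$hash_seed)
  sgn <- fnv_sign(units, config$hash_seed)
  m <- matrix(0, nrow = length(units), ncol = config$dimension)
  m[cbind(seq_along(units), idx)] <- sgn
  rownames(m) <- units
  m
}

#' Sentence embedding
#'
#' Mean of the token rows of [embed_tokens()]; L2-normalized when the config
#' says so.  The learned feedforward stage of pretrained deep-averaging
#' encoders is the identity here: the default encoder is a test-surface
#' encoder with the same contract, and a real pretrained model enters through
#' [external_encoder()].
#'
#' @inheritParams embed_tokens
#' @param encoder Optional external encoder handle (from
#'   [external_encoder()]); when supplied it replaces the default path.
#' @return Numeric vector of length `config$dimension`.
#' @export
embed_sentence <- function(sentence_text, config = encoder_config(),
                           encoder = NULL) {
  if (!is.null(encoder)) {
    stopifnot(inherits(encoder, "external_encoder"))
    v <- encoder$fn(sentence_text)
    if (length(v) != encoder$dimension) {
      stop("external encoder returned ", length(v), " values, declared ",
           encoder$dimension)
    }
    return(as.numeric(v))
  }
  m <- embed_tokens(sentence_text, config)
  v <- colMeans(m)
  if (config$normalize) {
    n <- sqrt(sum(v^2))
    if (n == 0) stop("zero-norm embedding cannot be normalized")
    v <- v / n
  }
  v
}

#' Register an external sentence encoder
#'
#' Adapter contract for pretrained encoders: a function taking one sentence
#' string and returning a numeric vector of the declared dimension,
#' deterministically.  Both the dimension and determinism are checked at
#' registration by a double-embedding probe.
#'
#' @param fn `function(sentence) -> numeric(dimension)`.
#' @param dimension Declared output dimension.
#' @param probe Sentence used for the registration checks.
#' @return An `external_encoder` handle usable in [embed_sentence()].
#' @export
external_encoder <- function(fn, dimension,
                             probe = "registration probe sentence") {
  stopifnot(is.function(fn), dimension >= 2)
  v1 <- fn(probe)
  if (!is.numeric(v1) || length(v1) != dimension) {
    stop("external encoder returned ", length(v1), " values, declared ",
         dimension)
  }
  v2 <- fn(probe)
  if (!isTRUE(all.equal(as.numeric(v1), as.numeric(v2), tolerance = 0))) {
    stop("external encoder is not deterministic")
  }
  structure(list(fn = fn, dimension = as.integer(dimension)),
            class = "external_encoder")
}
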