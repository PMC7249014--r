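#' Canonical mining question
#'
#' The default question driving the drug-mining pipeline and the synthetic
#' corpus generator.
#'
#' @return A character string.
#' @export
default_question <- function() {
  "what are the drugs that affect oxidative stress in chronic diseases?"
}

# content words of the default question, in injection order
question_content_words <- function() {
  c("oxidative", "stress", "chronic", "diseases", "drugs", "affect")
}

#' Synthetic-corpus specification
#'
#' Describes a corpus of background-noise documents with planted
#' compound-answer sentences.  Fillers draw from a synthetic background
#' vocabulary (`tok_###`) disjoint from the question's content words by
#' construction, so retrieval hits and misses are unambiguous; compound
#' names are synthetic (`cmpd_##`) to avoid accidental substring collisions.
#'
#' @param n_docs Number of documents (default 20).
#' @param n_compounds Number of distinct plantable compound names
#'   (default 20).
#' @param filler_sentences_per_doc Background sentences per document
#'   (default 9).
#' @param plant_probability Probability that a document receives a planted
#'   answer sentence (default 1).
#' @param background_vocab Background vocabulary size (default 200).
#' @param overlap_tokens Number of question content words injected into each
#'   planted sentence (default 4, minimum 1).
#' @param words_per_filler Words per filler sentence (default 8).
#' @param seed RNG seed; generation is a pure function of the spec.
#' @return A `corpus_spec` list.
#' @export
corpus_spec <- function(n_docs = 20L, n_compounds = 20L,
                        filler_sentences_per_doc = 9L,
                        plant_probability = 1.0, background_vocab = 200L,
                        overlap_tokens = 4L, words_per_filler = 8L,
                        seed = 42L) {
  stopifnot(plant_probability >= 0, plant_probability <= 1,
            overlap_tokens >= 1L,
            overlap_tokens <= length(question_content_words()))
  structure(list(n_docs = as.integer(n_docs),
                 n_compounds = as.integer(n_compounds),
                 filler_sentences_per_doc =
                   as.integer(filler_sentences_per_doc),
                 plant_probability = plant_probability,
                 background_vocab = as.integer(background_vocab),
                 overlap_tokens = as.integer(overlap_tokens),
                 words_per_filler = as.integer(words_per_filler),
                 seed = as.integer(seed)),
            class = "corpus_spec")
}

#' Generate a synthetic planted corpus with its gold benchmark
#'
#' Each document gets `filler_sentences_per_doc` background sentences; with
#' `plant_probability` one planted sentence
#' `"Compound <name> attenuates <question words>."` is inserted at a random
#' position.  The gold benchmark records the planted compound (or an empty
#' set for unplanted documents).  Fully reproducible given the spec.
#'
#' @param spec A [corpus_spec()].
#' @param question Question string (default [default_question()]).
#' @return List with `corpus` (a `lit_corpus`) and `gold` (list of
#'   [benchmark_item()]).
#' @export
make_corpus <- function(spec = corpus_spec(), question = default_question()) {
  stopifnot(inherits(spec, "corpus_spec"))
  vocab <- sprintf("tok%03d", seq_len(spec$background_vocab))
  names_pool <- sprintf("cmpd_%02d", seq_len(spec$n_compounds))
  inject <- head(question_content_words(), spec$overlap_tokens)
  local_seed(spec$seed, {
    docs <- vector("list", spec$n_docs)
    gold <- vector("list", spec$n_docs)
    for (d in seq_len(spec$n_docs)) {
      doc_id <- sprintf("doc_%03d", d)
      fillers <- vapply(seq_len(spec$filler_sentences_per_doc), function(i) {
        paste0(paste(sample(vocab, spec$words_per_filler, replace = TRUE),
                     collapse = " "), ".")
      }, character(1))
      planted <- runif(1) < spec$plant_probability
      if (planted) {
        name <- names_pool[((d - 1L) %% spec$n_compounds) + 1L]
        sentence <- paste0("Compound ", name, " attenuates ",
                           paste(inject, collapse = " "), ".")
        pos <- sample.int(length(fillers) + 1L, 1L)
        sentences <- append(fillers, sentence, after = pos - 1L)
        gold[[d]] <- benchmark_item(question, doc_id, name)
      } else {
        sentences <- fillers
        gold[[d]] <- benchmark_item(question, doc_id, character())
      }
      docs[[d]] <- document(doc_id, paste(sentences, collapse = " "),
                            source = "synthetic")
    }
    list(corpus = corpus(docs, metadata = list(
           generator = "litriage::make_corpus",
           rng = "R Mersenne-Twister", seed = spec$seed,
           spec = unclass(spec))),
         gold = gold)
  })
}

#' Build labeled question-answer relevance pairs from a planted corpus
#'
#' Label-1 pairs embed (question, planted sentence); label-0 pairs embed
#' (question, random filler sentence), `n_irrelevant_per_doc` per planted
#' document, so classes are balanced at the default of 1.
#'
#' @param corp `lit_corpus` from [make_corpus()].
#' @param gold Matching gold list.
#' @param n_irrelevant_per_doc Fillers sampled per planted document
#'   (default 1).
#' @param config Encoder configuration used for the embeddings.
#' @param seed Seed for filler sampling.
#' @return A `relevance_pairs` list: `q` and `a` embedding matrices,
#'   `label` (1/0) and a `meta` data frame (doc_id, sent_id).
#' @export
make_relevance_pairs <- function(corp, gold, n_irrelevant_per_doc = 1L,
                                 config = encoder_config(), seed = 42L) {
  planted <- Filter(function(g) length(g$gold_compounds) > 0L, gold)
  if (length(planted) == 0L) {
    stop("corpus has no planted sentences")
  }
  qs <- unique(vapply(planted, `[[`, character(1), "question"))
  stopifnot(length(qs) == 1L)
  qv <- embed_sentence(qs, config)
  rows_q <- list(); rows_a <- list(); labels <- integer(0)
  meta <- list()
  local_seed(seed, {
    for (g in planted) {
      doc <- corp$documents[[g$doc_id]]
      sent <- doc$sentences
      is_planted <- grepl(tolower(g$gold_compounds[1]), tolower(sent$text),
                          fixed = TRUE)
      if (!any(is_planted)) {
        stop("no planted sentence found in ", g$doc_id)
      }
      p <- which(is_planted)[1]
      k <- length(rows_q)
      rows_q[[k + 1L]] <- qv
      rows_a[[k + 1L]] <- embed_sentence(sent$text[p], config)
      labels <- c(labels, 1L)
      meta[[k + 1L]] <- data.frame(doc_id = g$doc_id,
                                   sent_id = sent$sent_id[p])
      fillers <- which(!is_planted)
      take <- sample(fillers, min(n_irrelevant_per_doc, length(fillers)))
      for (f in take) {
        k <- length(rows_q)
        rows_q[[k + 1L]] <- qv
        rows_a[[k + 1L]] <- embed_sentence(sent$text[f], config)
        labels <- c(labels, 0L)
        meta[[k + 1L]] <- data.frame(doc_id = g$doc_id,
                                     sent_id = sent$sent_id[f])
      }
    }
  })
  structure(list(q = do.call(rbind, rows_q), a = do.call(rbind, rows_a),
                 label = labels, meta = do.call(rbind, meta)),
            class = "relevance_pairs")
}

#' Synthetic BBB dataset specification
#'
#' A planted-hyperplane fingerprint/label generator: bits are
#' Bernoulli(`bit_density`), the label is the side of a seeded
#' standard-normal weight vector, points closer to the hyperplane than
#' `margin` (in units of the weight norm) are rejected so the classes are
#' genuinely linearly separable, and labels are then flipped at `flip_rate`
#' as noise.
#'
#' @param n_samples Number of samples (default 400).
#' @param n_bits Fingerprint length (default 256).
#' @param bit_density Probability a bit is set (default 0.1).
#' @param flip_rate Label-noise rate in `[0, 0.5)` (default 0.05).
#' @param margin Minimum distance to the hyperplane, in units of the weight
#'   norm (default 0.5).
#' @param seed RNG seed.
#' @return A `bbb_spec` list.
#' @export
bbb_spec <- function(n_samples = 400L, n_bits = 256L, bit_density = 0.1,
                     flip_rate = 0.05, margin = 0.5, seed = 3L) {
  stopifnot(flip_rate >= 0, flip_rate < 0.5, bit_density > 0,
            bit_density < 1, margin >= 0)
  structure(list(n_samples = as.integer(n_samples),
                 n_bits = as.integer(n_bits), bit_density = bit_density,
                 flip_rate = flip_rate, margin = margin,
                 seed = as.integer(seed)),
            class = "bbb_spec")
}

#' Generate the synthetic BBB training set
#'
#' @param spec A [bbb_spec()].
#' @return List with `X` (n x n_bits 0/1 matrix), `y` (noisy labels, -1/+1),
#'   `y_clean` (noiseless labels), `true_weights` (the generating
#'   hyperplane) and `flipped` (logical noise mask).
#' @export
make_bbb_dataset <- function(spec = bbb_spec()) {
  stopifnot(inherits(spec, "bbb_spec"))
  local_seed(spec$seed, {
    w <- rnorm(spec$n_bits)
    wn <- sqrt(sum(w^2))
    X <- matrix(0L, nrow = 0L, ncol = spec$n_bits)
    while (nrow(X) < spec$n_samples) {
      batch <- matrix(as.integer(runif(spec$n_samples * spec$n_bits) <
                                   spec$bit_density),
                      nrow = spec$n_samples)
      keep <- abs(batch %*% w) / wn >= spec$margin
      X <- rbind(X, batch[keep, , drop = FALSE])
    }
    X <- X[seq_len(spec$n_samples), , drop = FALSE]
    y_clean <- ifelse(drop(X %*% w) > 0, 1L, -1L)
    flipped <- runif(spec$n_samples) < spec$flip_rate
    y <- ifelse(flipped, -y_clean, y_clean)
    list(X = X, y = y, y_clean = y_clean, true_weights = w,
         flipped = flipped)
  })
}

#' Built-in compound panel (synthetic stand-in training labels)
#'
#' A small panel of well-known molecules with SMILES and approximate
#' blood-brain-barrier permeability labels (`+1` = crosses).  The labels
#' are synthetic stand-ins good enough to exercise the classifier and the
#' end-to-end pipeline offline; they are not a curated pharmacokinetic
#' dataset.
#'
#' @return Data frame with `name`, `smiles`, `bbb_label`.
#' @export
synthetic_compound_panel <- function() {
  data.frame(
    name = c("zileuton", "caffeic acid", "caffeine", "ibuprofen",
             "nicotine", "aspirin", "TCDD", "sulforaphane",
             "salicylic acid", "atenolol", "sucrose", "glucose",
             "lisinopril", "urea"),
    smiles = c(
      "CC(c1cc2ccccc2s1)N(O)C(N)=O",
      "O=C(O)C=Cc1ccc(O)c(O)c1",
      "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
      "CC(C)Cc1ccc(cc1)C(C)C(=O)O",
      "CN1CCCC1c1cccnc1",
      "CC(=O)Oc1ccccc1C(=O)O",
      "Clc1cc2Oc3cc(Cl)c(Cl)cc3Oc2cc1Cl",
      "CS(=O)CCCCN=C=S",
      "O=C(O)c1ccccc1O",
      "CC(C)NCC(O)COc1ccc(CC(N)=O)cc1",
      "OCC1OC(CO)(OC2OC(CO)C(O)C(O)C2O)C(O)C1O",
      "OCC1OC(O)C(O)C(O)C1O",
      "NCCCCC(NC(CCc1ccccc1)C(=O)O)C(=O)N1CCCC1C(=O)O",
      "NC(N)=O"),
    bbb_label = c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L,
                  1L, -1L, -1L, -1L, -1L, -1L),
    stringsAsFactors = FALSE)
}

#' Map synthetic compound names onto panel structures
#'
#' Assigns each planted compound name a SMILES from
#' [synthetic_compound_panel()], cycling in order, so the end-to-end
#' pipeline has a compound table with known triage outcomes.
#'
#' @param names Character vector of compound names (e.g. the gold set).
#' @return Data frame with `name`, `smiles`, `bbb_label`.
#' @export
make_compound_table <- function(names) {
  panel <- synthetic_compound_panel()
  idx <- ((seq_along(names) - 1L) %% nrow(panel)) + 1L
  data.frame(name = names, smiles = panel$smiles[idx],
             bbb_label = panel$bbb_label[idx], stringsAsFactors = FALSE)
}
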