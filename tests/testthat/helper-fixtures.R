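# Shared fixtures, built once per test run and memoized: the seed-42 planted
# corpus, its relevance pairs, a converged DCN, and the compound table with
# its BBB model.  Building the converged DCN dominates the suite's runtime,
# so every test that needs it shares one instance.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache, inherits = FALSE)
}

fix_corpus42 <- function() {
  fixture("corpus42", function() make_corpus(corpus_spec(seed = 42L)))
}

fix_pairs42 <- function() {
  fixture("pairs42", function() {
    cg <- fix_corpus42()
    make_relevance_pairs(cg$corpus, cg$gold, seed = 42L)
  })
}

# DCN trained to convergence on the seed-42 fixture (full-batch descent).
fix_dcn42 <- function() {
  fixture("dcn42", function() {
    train_dcn(fix_pairs42(),
              dcn_config(seed = 0L, learning_rate = 1, epochs = 2000L,
                         batch_size = 40L),
              track_history = FALSE)
  })
}

fix_compounds42 <- function() {
  fixture("compounds42", function() {
    cg <- fix_corpus42()
    make_compound_table(unlist(lapply(cg$gold, `[[`, "gold_compounds")))
  })
}

fix_bbb42 <- function() {
  fixture("bbb42", function() {
    ctab <- fix_compounds42()
    X <- t(vapply(ctab$smiles, function(s) fingerprint(s),
                  integer(1024L)))
    train_bbb_svm(X, ctab$bbb_label)
  })
}

# brute-force confusion-matrix oracle used by the evaluation tests
brute_confusion <- function(preds, gold) {
  tp <- fp <- tn <- fn <- 0L
  for (g in gold) {
    row <- preds[preds$doc_id == g$doc_id & preds$rank_within_document == 1L, ]
    answered <- nrow(row) == 1L && !isTRUE(row$abstained)
    has_gold <- length(g$gold_compounds) > 0L
    hit <- answered && has_gold &&
      any(vapply(g$gold_compounds,
                 function(nm) grepl(tolower(nm), tolower(row$text),
                                    fixed = TRUE), logical(1)))
    if (answered && hit) tp <- tp + 1L
    if (answered && !hit) fp <- fp + 1L
    if (!answered && has_gold) fn <- fn + 1L
    if (!answered && !has_gold) tn <- tn + 1L
  }
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}
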