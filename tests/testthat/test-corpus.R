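test_that("plain-text extraction is identity and errors are explicit", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines("Zileuton works.", f)
  expect_equal(extract_text(f), "Zileuton works.")

  empty <- withr::local_tempfile(fileext = ".txt")
  file.create(empty)
  expect_error(extract_text(empty), "empty extraction result")

  expect_error(extract_text(f, format = "pdf"), "no pdf backend")
  expect_error(extract_text(file.path(tempdir(), "nope.txt")),
               "does not exist")

  backend <- function(path) "From a pdf."
  expect_equal(extract_text(f, format = "pdf", pdf_backend = backend),
               "From a pdf.")
})

test_that("sentence tokenization splits, deduplicates and records offsets", {
  expect_equal(nrow(tokenize_sentences("")), 0L)

  s <- tokenize_sentences("Zileuton inhibits 5-LO. It is approved.")
  expect_equal(nrow(s), 2L)
  expect_equal(s$text, c("Zileuton inhibits 5-LO.", "It is approved."))

  # dedup keeps first occurrence
  d <- tokenize_sentences("A drug works. A drug works. B fails.")
  expect_equal(d$text, c("A drug works.", "B fails."))
  expect_equal(d$sent_id, c(1L, 2L))

  # offsets are 0-based half-open and recover the exact substring
  raw <- "One sentence here. And a second?  Third!"
  toks <- tokenize_sentences(raw)
  for (i in seq_len(nrow(toks))) {
    expect_identical(substr(raw, toks$start[i] + 1L, toks$end[i]),
                     toks$text[i])
  }
  expect_true(all(diff(toks$start) > 0))

  # fragments below the 3-character minimum are dropped ("Hi." is kept)
  expect_equal(nrow(tokenize_sentences("A. A real sentence follows.")), 1L)
  expect_equal(nrow(tokenize_sentences("Hi. A real sentence follows.")), 2L)
})

test_that("sentence spans never overlap and dedup is idempotent", {
  set.seed(11)
  vocab <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta")
  for (case in 1:25) {
    n_sent <- sample(1:8, 1)
    text <- paste(vapply(seq_len(n_sent), function(i) {
      paste0(paste(sample(vocab, sample(3:6, 1), replace = TRUE),
                   collapse = " "), sample(c(".", "?", "!"), 1))
    }, character(1)), collapse = " ")
    toks <- tokenize_sentences(text)
    if (nrow(toks) > 1L) {
      expect_true(all(toks$start[-1] >= toks$end[-nrow(toks)]))
      expect_true(all(toks$end > toks$start))
    }
    doubled <- tokenize_sentences(paste(text, text))
    expect_setequal(doubled$text, toks$text)
  }
})

test_that("corpus persistence round-trips field-for-field", {
  docs <- list(document("d1", "First fact here. Second fact there."),
               document("d2", "Only one sentence."))
  corp <- corpus(docs, metadata = list(tokenizer = "default"))
  path <- withr::local_tempfile(fileext = ".json")
  save_corpus(corp, path)
  back <- load_corpus(path)
  expect_equal(back$documents, corp$documents)
  expect_equal(back$metadata$tokenizer, "default")
})

test_that("random corpora survive persistence round-trips", {
  set.seed(7)
  vocab <- sprintf("w%02d", 1:40)
  for (case in 1:100) {
    n_docs <- sample(1:4, 1)
    docs <- lapply(seq_len(n_docs), function(d) {
      n_sent <- sample(1:6, 1)
      text <- paste(vapply(seq_len(n_sent), function(i) {
        paste0(paste(sample(vocab, sample(3:7, 1)), collapse = " "), ".")
      }, character(1)), collapse = " ")
      document(sprintf("doc%d", d), text)
    })
    corp <- corpus(docs, metadata = list(case = case))
    path <- tempfile(fileext = ".json")
    save_corpus(corp, path)
    expect_equal(load_corpus(path)$documents, corp$documents)
    unlink(path)
  }
})

test_that("malformed and version-mismatched corpus files fail loudly", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines("{\"documents\": []}", path)
  expect_error(load_corpus(path), "malformed")

  writeLines("{\"metadata\": {\"schema_version\": \"99\"}, \"documents\": []}",
             path)
  expect_error(load_corpus(path), "version mismatch")

  writeLines("{\"metadata\": {", path)  # truncated
  expect_error(load_corpus(path), "malformed")

  expect_error(corpus(list(document("a", "Hello there."),
                           document("a", "Hello again."))),
               "duplicate doc_id")
})

test_that("benchmark items round-trip through JSON", {
  items <- list(benchmark_item("q?", "d1", c("zileuton", "caffeic acid")),
                benchmark_item("q?", "d2", character()))
  path <- withr::local_tempfile(fileext = ".json")
  write_benchmark(items, path)
  back <- read_benchmark(path)
  expect_equal(back, items)
})
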