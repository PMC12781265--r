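gold_of <- function(docs) vapply(docs, `[[`, integer(1), "gold_label")

test_that("corpus specs validate their fields", {
  expect_error(corpus_spec(-1, 0.5, 1), "non-negative")
  expect_error(corpus_spec(10, 1.5, 1), "fractions")
  expect_error(corpus_spec(10, 0.5, 1, noise_fraction = -0.1), "fractions")
  expect_s3_class(corpus_spec(0, 0, 1), "corpus_spec")
})

test_that("positive counts are exact for every generated corpus", {
  cases <- list(c(440, 0.17, 75), c(115, 0.43, 49), c(99, 0.43, 43),
                c(10, 0.5, 5), c(7, 0.5, 4), c(200, 0.213, 43))
  for (cs in cases) {
    corp <- generate_corpus(corpus_spec(cs[1], cs[2], seed = 3))
    expect_length(corp, cs[1])
    expect_equal(sum(gold_of(corp)), cs[3],
                 info = paste(cs[1], "x", cs[2]))
  }
  expect_length(generate_corpus(corpus_spec(0, 0.5, 1)), 0)
})

test_that("corpora are a pure function of their spec, byte for byte", {
  spec <- corpus_spec(40, 0.3, seed = 99, full_report_fraction = 0.5)
  a <- generate_corpus(spec)
  b <- generate_corpus(spec)
  expect_identical(a, b)
  f1 <- withr::local_tempfile(fileext = ".jsonl")
  f2 <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus_jsonl(a, f1)
  write_corpus_jsonl(b, f2)
  expect_identical(readLines(f1), readLines(f2))
  # a different seed changes documents but not the structure
  c2 <- generate_corpus(corpus_spec(40, 0.3, seed = 100,
                                    full_report_fraction = 0.5))
  expect_false(identical(a, c2))
  expect_equal(sum(gold_of(c2)), sum(gold_of(a)))
})

test_that("noise-free corpora are perfectly recoverable by the classifier", {
  corp <- generate_corpus(corpus_spec(250, 0.35, seed = 5, noise_fraction = 0))
  res <- classify_corpus(corp)
  expect_equal(res$summary$n_errored, 0)
  preds <- vapply(res$results, `[[`, integer(1), "ischemia")
  expect_identical(preds, gold_of(corp))
})

test_that("noise introduces both false negatives and false positives", {
  corp <- generate_corpus(corpus_spec(300, 0.5, seed = 8,
                                      noise_fraction = 0.4))
  res <- classify_corpus(corp)
  preds <- vapply(res$results, `[[`, integer(1), "ischemia")
  cm <- build_confusion(preds, gold_of(corp))
  expect_gt(cm$c, 0)  # uncovered positives are missed
  expect_gt(cm$b, 0)  # uncovered negatives (e.g. historical mentions) alert
})

test_that("positive reports survive distractors and sites add boilerplate", {
  set.seed(21)
  spec <- corpus_spec(1, 0.5, 1, site_count = 5)
  for (i in 1:30) {
    d <- generate_report(1L, spec, report_id = paste0("g", i))
    expect_equal(classify_document(d)$ischemia, 1L)
    expect_match(d$site_id, "^site-[1-5]$")
  }
})

test_that("full reports wrap the impression in a sectioned document", {
  corp <- generate_corpus(corpus_spec(60, 0.4, seed = 13,
                                      full_report_fraction = 1))
  rules <- default_ischemia_rulebook()$sections
  for (d in corp[1:10]) {
    expect_true(nzchar(d$full_report_text))
    secs <- detect_sections(d$full_report_text, rules)
    expect_true(all(c("INDICATION", "TECHNIQUE", "FINDINGS", "IMPRESSION")
                    %in% secs$section_category))
    imp <- secs$body[secs$section_category == "IMPRESSION"]
    expect_identical(imp, d$impression_text)
  }
})

test_that("benchmark splits have the reference sizes, prevalences, unique ids", {
  splits <- generate_benchmark_splits(7)
  expect_equal(lengths(splits), c(train = 440, validation = 115, test = 99))
  expect_equal(sum(lengths(splits)), 654)
  expect_equal(sum(gold_of(splits$train)), 75)       # round(440 * 0.17)
  expect_equal(sum(gold_of(splits$validation)), 49)  # round(115 * 0.43)
  expect_equal(sum(gold_of(splits$test)), 43)        # round(99 * 0.43)
  ids <- unlist(lapply(splits, function(s)
    vapply(s, `[[`, character(1), "report_id")))
  expect_false(anyDuplicated(ids) > 0)
  # training share of the pooled corpus rounds to 67%
  expect_equal(round(100 * 440 / 654), 67)
  # different seeds: same structure, different documents
  splits2 <- generate_benchmark_splits(8)
  expect_equal(lengths(splits2), lengths(splits))
  expect_false(identical(splits, splits2))
  expect_identical(generate_benchmark_splits(7), splits)
})

test_that("JSONL and CSV corpus files round-trip", {
  corp <- generate_corpus(corpus_spec(25, 0.4, seed = 17,
                                      full_report_fraction = 0.5))
  fj <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus_jsonl(corp, fj)
  back <- read_corpus_jsonl(fj)
  expect_equal(length(back), length(corp))
  for (i in seq_along(corp)) expect_identical(back[[i]], corp[[i]])

  fc <- withr::local_tempfile(fileext = ".csv")
  write_corpus_csv(corp, fc)
  backc <- read_corpus_csv(fc)
  for (i in seq_along(corp)) expect_identical(backc[[i]], corp[[i]])
})

test_that("malformed rows can be skipped with a record of why", {
  fc <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("report_id,impression_text,gold_label",
               "r1,Likely ischemia,1",
               ",missing id,0",
               "r3,No ischemia,0"), fc)
  expect_error(read_corpus_csv(fc), "row 2")
  docs <- read_corpus_csv(fc, row_errors = "skip")
  expect_length(docs, 2)
  skipped <- attr(docs, "skipped")
  expect_equal(skipped$row, 2)
  expect_match(skipped$message, "report_id")
})

test_that("template coverage flags are honest, one template at a time", {
  set.seed(29)
  tpl <- phrase_templates()
  for (i in seq_len(nrow(tpl))) {
    txt <- tpl$text[i]
    txt <- gsub("{territory}", "anterior", txt, fixed = TRUE)
    txt <- gsub("{size}", "small", txt, fixed = TRUE)
    pred <- classify_document(report_document("t", txt))$ischemia
    want <- if (tpl$label_contribution[i] == "POSITIVE" &&
                tpl$in_rulebook_coverage[i]) 1L
            else if (tpl$label_contribution[i] == "POSITIVE") 0L
            else if (tpl$in_rulebook_coverage[i]) 0L else 1L
    expect_equal(pred, want, info = txt)
  }
})
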