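test_that("mention polarity follows the decision table", {
  mk <- function(category, ...) {
    m <- list(category = category,
              attributes = list(is_negated = FALSE, is_fixed = FALSE,
                                is_artifact = FALSE, is_uncertain = FALSE,
                                has_reversible_modifier = FALSE))
    flags <- list(...)
    for (f in names(flags)) m$attributes[[f]] <- flags[[f]]
    m
  }
  cases <- list(
    list(mk("ISCHEMIA_TERM"), "POSITIVE"),
    list(mk("ISCHEMIA_TERM", is_uncertain = TRUE), "POSITIVE"),
    list(mk("ISCHEMIA_TERM", is_fixed = TRUE), "NOT_POSITIVE"),
    list(mk("ISCHEMIA_TERM", is_negated = TRUE), "NOT_POSITIVE"),
    list(mk("ISCHEMIA_TERM", is_artifact = TRUE), "NOT_POSITIVE"),
    list(mk("REVERSIBILITY_TERM"), "POSITIVE"),
    list(mk("REVERSIBILITY_TERM", is_negated = TRUE), "NOT_POSITIVE"),
    list(mk("PERFUSION_FINDING"), "NOT_POSITIVE"),
    list(mk("PERFUSION_FINDING", has_reversible_modifier = TRUE), "POSITIVE"),
    list(mk("PERFUSION_FINDING", has_reversible_modifier = TRUE,
            is_fixed = TRUE), "NOT_POSITIVE"),
    list(mk("PERFUSION_FINDING", is_uncertain = TRUE), "NOT_POSITIVE"))
  for (cs in cases)
    expect_identical(mention_polarity(cs[[1]]), cs[[2]])
})

test_that("all thirteen reference phrases classify to their printed labels", {
  gold <- reference_phrases()
  preds <- vapply(seq_len(nrow(gold)), function(i)
    classify_document(report_document(paste0("p", i),
                                      gold$phrase[i]))$ischemia,
    integer(1))
  expect_identical(preds, gold$label)
  expect_equal(sum(preds), 5)
})

test_that("classification output carries evidence and provenance", {
  r <- classify_document(report_document("r1", "Likely ischemia"))
  expect_equal(r$ischemia, 1L)
  expect_match(r$evidence, "ischemia \\[ISCHEMIA_TERM")
  expect_match(r$evidence, "c-likely")
  expect_equal(r$source_text_provenance, "impression")

  r <- classify_document(report_document("r2", "Negative for reversible ischemia"))
  expect_equal(r$ischemia, 0L)
  expect_match(r$evidence, "c-negative-for")

  # no mentions at all: evidence empty
  r <- classify_document(report_document("r3", "Normal study"))
  expect_equal(r$ischemia, 0L)
  expect_identical(r$evidence, "")

  expect_error(classify_document(report_document("r4", "", "")), "r4")
})

test_that("classification is deterministic including evidence text", {
  doc <- report_document("r1",
    "Small, primarily fixed defect and a mild, reversible defect.\nNo ischemia elsewhere.")
  a <- classify_document(doc)
  b <- classify_document(doc)
  expect_identical(a, b)
})

test_that("any positive sentence dominates any number of negative ones", {
  positive_docs <- list(
    report_document("a", "Likely ischemia"),
    report_document("b", "Moderate area of reversibility"))
  negative_docs <- list(
    report_document("c", "Negative myocardial perfusion study"),
    report_document("d", "No evidence of ischemia. Fixed perfusion defects are seen."))
  for (d in c(positive_docs, negative_docs)) {
    appended <- report_document(d$report_id,
      paste0(d$impression_text, "\nModerate area of reversibility."))
    expect_equal(classify_document(appended)$ischemia, 1L, info = d$report_id)
  }
  for (d in positive_docs) {
    appended <- report_document(d$report_id,
      paste0(d$impression_text, "\nNegative myocardial perfusion study."))
    expect_equal(classify_document(appended)$ischemia, 1L, info = d$report_id)
  }
})

test_that("multi-territory reports classify positive on one positive territory", {
  doc <- report_document("mt", paste(
    "Fixed perfusion defect in the inferior wall.",
    "No reversible defect in the lateral wall.",
    "Small reversible defect in the anterior wall.",
    "Normal apical perfusion.", sep = "\n"))
  expect_equal(classify_document(doc)$ischemia, 1L)
})

test_that("corpus classification preserves order, isolates errors, reports prevalence", {
  docs <- gold_docs_from_phrases()
  res <- classify_corpus(docs)
  expect_length(res$results, 13)
  expect_identical(vapply(res$results, `[[`, character(1), "report_id"),
                   vapply(docs, `[[`, character(1), "report_id"))
  expect_equal(res$summary$n_positive, 5)
  expect_equal(res$summary$prevalence, 5 / 13)

  empty <- classify_corpus(list())
  expect_length(empty$results, 0)
  expect_true(is.na(empty$summary$prevalence))

  mixed <- classify_corpus(list(report_document("ok", "Likely ischemia"),
                                report_document("bad", "", "")))
  expect_equal(mixed$summary$n_classified, 1)
  expect_equal(mixed$summary$n_errored, 1)
  expect_equal(mixed$errors$report_id, "bad")
})

test_that("classification falls back to the full-report impression section", {
  doc <- report_document("fb", "", paste0(
    "INDICATION: chest pain\nFINDINGS: reduced uptake\n",
    "IMPRESSION: Moderate area of reversibility"))
  r <- classify_document(doc)
  expect_equal(r$ischemia, 1L)
  expect_equal(r$source_text_provenance, "full_report_impression_section")
  expect_error(classify_document(doc, policy = "IMPRESSION_ONLY"), "fb")
})
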