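# Synthetic stress test report corpus. Templates emulate the sub-language of
# nuclear perfusion impressions: perfusion findings with reversibility or
# fixed qualifiers, artifact attributions, negations, hedges, multi-territory
# sentences, and site-specific boilerplate. Out-of-coverage paraphrase
# templates (noise) express the same clinical facts in wording the default
# rulebook does not recognize, emulating the error modes of a real deployment.

TERRITORIES <- c("anterior", "inferior", "lateral", "septal", "apical",
                 "anterolateral", "inferolateral")
SIZES <- c("small", "moderate", "large", "medium size")

#' The thirteen reference example phrases and their ischemia labels
#'
#' Short impression phrases, each with the label a cardiologist assigns
#' (1 = ischemia, 0 = no ischemia). They cover the hard cases: hedged
#' positives, negated and fixed findings, artifact attributions, and a mixed
#' fixed-plus-reversible sentence. They ship both as the behavioral contract
#' of the default rulebook and as fixed generator templates.
#'
#' @return A data frame with columns `phrase` and `label`.
#' @export
reference_phrases <- function() {
  data.frame(
    phrase = c(
      "Defect resolves on prone imaging, consistent with attenuation artifact",
      "Fixed area of mildly reduced counts",
      "Fixed perfusion defects are seen",
      "Large perfusion defect without evidence of reversibility",
      "Likely ischemia",
      "Moderate area of reversibility",
      "Moderate size, mildly reduced counts in anterior wall which is reversible",
      "Negative for reversible ischemia",
      "Negative myocardial perfusion study",
      "Small perfusion abnormality is favored to be artifactual",
      "Small, primarily fixed defect and a mild, reversible defect",
      "There is a medium size, partially reversible defect",
      "There is a small area of fixed ischemia"),
    label = c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 0L, 0L, 0L, 1L, 1L, 0L),
    stringsAsFactors = FALSE)
}

#' Phrase templates used by the generator
#'
#' Each template has `text` (with optional `{territory}` and `{size}` slots),
#' a `label_contribution` (`POSITIVE`, `NEGATIVE`, or `NEUTRAL`), and an
#' `in_rulebook_coverage` flag: covered templates are guaranteed to be
#' handled correctly by the default rulebook; uncovered ones paraphrase the
#' same finding in wording the rulebook does not recognize, so they generate
#' realistic false negatives (uncovered positives) and false positives
#' (uncovered negatives, e.g. an unrefuted historical mention of ischemia).
#'
#' @return A data frame with columns `text`, `label_contribution`,
#'   `in_rulebook_coverage`.
#' @export
phrase_templates <- function() {
  t13 <- reference_phrases()
  fixed <- data.frame(
    text = t13$phrase,
    label_contribution = ifelse(t13$label == 1L, "POSITIVE", "NEGATIVE"),
    in_rulebook_coverage = TRUE, stringsAsFactors = FALSE)
  tpl <- function(text, contrib, covered = TRUE)
    data.frame(text = text, label_contribution = contrib,
               in_rulebook_coverage = covered, stringsAsFactors = FALSE)
  rbind(
    fixed,
    tpl("{size} reversible defect in the {territory} wall", "POSITIVE"),
    tpl("{size} area of reversibility in the {territory} territory", "POSITIVE"),
    tpl("Stress images demonstrate a {size} reversible perfusion defect in the {territory} wall", "POSITIVE"),
    tpl("{size} area of ischemia involving the {territory} wall", "POSITIVE"),
    tpl("Mildly reduced counts in the {territory} wall which is reversible", "POSITIVE"),
    tpl("No evidence of ischemia", "NEGATIVE"),
    tpl("Negative for ischemia", "NEGATIVE"),
    tpl("{size} fixed perfusion defect in the {territory} wall", "NEGATIVE"),
    tpl("Fixed defect in the {territory} territory, consistent with scar", "NEGATIVE"),
    tpl("{size} perfusion defect consistent with attenuation artifact", "NEGATIVE"),
    tpl("No reversible perfusion abnormality identified", "NEGATIVE"),
    tpl("Normal myocardial perfusion study", "NEUTRAL"),
    tpl("Normal wall motion and thickening", "NEUTRAL"),
    tpl("Left ventricular ejection fraction estimated at 55 percent", "NEUTRAL"),
    tpl("No prior studies available for comparison", "NEUTRAL"),
    tpl("Gated images show normal left ventricular systolic function", "NEUTRAL"),
    tpl("Stress induced hypoperfusion of the {territory} wall, suggestive of flow limitation", "POSITIVE", covered = FALSE),
    tpl("Findings compatible with inducible flow abnormality in the {territory} territory", "POSITIVE", covered = FALSE),
    tpl("History of prior ischemia on outside imaging, currently stable appearance", "NEGATIVE", covered = FALSE))
}

SITE_BOILERPLATE <- c(
  "Myocardial perfusion SPECT study at rest and during stress.",
  "Gated SPECT myocardial perfusion imaging was performed.",
  "Pharmacologic nuclear stress study.",
  "Exercise myocardial perfusion study, standard protocol.",
  "Rest and stress perfusion imaging obtained per site protocol.")

#' Specification of a synthetic corpus
#'
#' @param n Document count.
#' @param prevalence Target positive fraction in `[0, 1]`; the positive count
#'   is exactly `n * prevalence` rounded half-up, not a per-document coin
#'   flip, so split prevalences are testable as equalities.
#' @param seed Integer seed; corpora are a pure function of their spec.
#' @param site_count Number of synthetic sites with distinct boilerplate
#'   (default 3; capped at the available boilerplate variants).
#' @param noise_fraction Fraction of documents drawn from out-of-coverage
#'   paraphrase templates (default 0: every generated label is recoverable by
#'   the default rulebook).
#' @param full_report_fraction Fraction of documents additionally given a
#'   sectioned full report whose IMPRESSION section equals the impression
#'   text (default 0.3).
#' @return An object of class `"corpus_spec"`.
#' @export
corpus_spec <- function(n, prevalence, seed, site_count = 3,
                        noise_fraction = 0, full_report_fraction = 0.3) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0 || n != round(n))
    stop("n must be a non-negative integer", call. = FALSE)
  for (f in c(prevalence, noise_fraction, full_report_fraction))
    if (!is.numeric(f) || is.na(f) || f < 0 || f > 1)
      stop("fractions must lie in [0, 1]", call. = FALSE)
  if (site_count < 1) stop("site_count must be >= 1", call. = FALSE)
  structure(list(n = as.integer(n), prevalence = prevalence,
                 seed = as.integer(seed),
                 site_count = min(as.integer(site_count),
                                  length(SITE_BOILERPLATE)),
                 noise_fraction = noise_fraction,
                 full_report_fraction = full_report_fraction),
            class = "corpus_spec")
}

instantiate_template <- function(text) {
  if (grepl("{territory}", text, fixed = TRUE))
    text <- sub("{territory}", sample(TERRITORIES, 1L), text, fixed = TRUE)
  if (grepl("{size}", text, fixed = TRUE)) {
    size <- sample(SIZES, 1L)
    text <- sub("{size}", size, text, fixed = TRUE)
    # sentence-initial slot: capitalize
    text <- paste0(toupper(substring(text, 1, 1)), substring(text, 2))
  }
  text
}

draw_sentence <- function(templates, contribution, covered) {
  pool <- templates[templates$label_contribution %in% contribution &
                      templates$in_rulebook_coverage == covered, , drop = FALSE]
  instantiate_template(pool$text[sample.int(nrow(pool), 1L)])
}

#' Generate one synthetic stress test report
#'
#' A positive report contains at least one positive sentence plus 0–3
#' negative/neutral distractor sentences (exercising any-positive,
#' multi-territory aggregation); a negative report contains only
#' negative/neutral sentences. Site boilerplate is prepended according to the
#' drawn site, and a fraction of reports also carry a sectioned full report
#' (INDICATION/TECHNIQUE/FINDINGS/IMPRESSION) wrapping the impression.
#' Consumes the R random number stream; callers seed it (as
#' [generate_corpus()] does).
#'
#' @param label Gold label to realize (1 = ischemia).
#' @param spec A [corpus_spec()].
#' @param report_id Identifier for the document.
#' @param noisy Draw the decisive sentence from out-of-coverage templates.
#' @return A [report_document()] with `gold_label` set.
#' @export
generate_report <- function(label, spec, report_id, noisy = FALSE) {
  templates <- phrase_templates()
  site <- sample.int(spec$site_count, 1L)
  n_distract <- sample(0:3, 1L)
  distractors <- character(n_distract)
  for (i in seq_len(n_distract))
    distractors[i] <- draw_sentence(templates, c("NEGATIVE", "NEUTRAL"), TRUE)
  decisive <- if (label == 1L) {
    draw_sentence(templates, "POSITIVE", covered = !noisy)
  } else if (noisy) {
    draw_sentence(templates, "NEGATIVE", covered = FALSE)
  } else {
    character(0)
  }
  body <- c(decisive, distractors)
  if (length(body) > 1L) body <- body[sample.int(length(body))]
  if (!length(body)) body <- draw_sentence(templates, c("NEGATIVE", "NEUTRAL"), TRUE)
  sentences <- paste0(sub("([^.!?])$", "\\1.", body), collapse = "\n")
  impression <- paste0(SITE_BOILERPLATE[site], "\n", sentences)
  full <- ""
  if (stats::runif(1) < spec$full_report_fraction) {
    full <- paste0(
      "INDICATION: ", sample(c("Chest pain.", "Dyspnea on exertion.",
                               "Preoperative evaluation.", "Abnormal ECG."), 1L),
      "\nTECHNIQUE: ", SITE_BOILERPLATE[site],
      "\nFINDINGS: Tracer uptake assessed in all territories.",
      "\nIMPRESSION: ", impression)
  }
  report_document(report_id, impression_text = impression,
                  full_report_text = full,
                  site_id = paste0("site-", site), gold_label = label)
}

#' Generate a gold-labeled synthetic corpus
#'
#' Produces exactly `round(n * prevalence)` positive documents (half-up
#' rounding), shuffled by the spec's seed. The same spec always yields an
#' identical corpus.
#'
#' @param spec A [corpus_spec()].
#' @param id_prefix Prefix for generated report ids.
#' @return A list of [report_document()]s with gold labels.
#' @examples
#' corp <- generate_corpus(corpus_spec(10, 0.5, seed = 1))
#' sum(vapply(corp, function(d) d$gold_label, integer(1)))  # 5
#' @export
generate_corpus <- function(spec, id_prefix = "doc") {
  stopifnot(inherits(spec, "corpus_spec"))
  if (spec$n == 0L) return(list())
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)
  n_pos <- as.integer(round_half_up(spec$n * spec$prevalence))
  n_noise <- as.integer(round_half_up(spec$n * spec$noise_fraction))
  labels <- sample(c(rep(1L, n_pos), rep(0L, spec$n - n_pos)))
  noisy <- seq_len(spec$n) %in% sample.int(spec$n, n_noise)
  lapply(seq_len(spec$n), function(i)
    generate_report(labels[i], spec,
                    report_id = sprintf("%s-%05d", id_prefix, i),
                    noisy = noisy[i]))
}

#' Generate the benchmark train/validation/test splits
#'
#' Three disjoint corpora with the reference split structure: 440 training
#' documents at 17% prevalence, and 115 validation plus 99 test documents at
#' 43% prevalence (the validation/test pool was enriched for suspected
#' positives, hence its higher prevalence). Report ids are globally unique
#' across splits; total 654 documents, of which the training split is 67%.
#'
#' @param seed Integer seed.
#' @param noise_fraction Passed to each split's [corpus_spec()] (default 0).
#' @return A named list of document lists: `train`, `validation`, `test`.
#' @export
generate_benchmark_splits <- function(seed, noise_fraction = 0) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sub <- sample.int(2147483606L, 3L)
  list(
    train = generate_corpus(
      corpus_spec(440, 0.17, sub[1], noise_fraction = noise_fraction),
      id_prefix = "train"),
    validation = generate_corpus(
      corpus_spec(115, 0.43, sub[2], noise_fraction = noise_fraction),
      id_prefix = "val"),
    test = generate_corpus(
      corpus_spec(99, 0.43, sub[3], noise_fraction = noise_fraction),
      id_prefix = "test"))
}

CORPUS_COLUMNS <- c("report_id", "impression_text", "full_report_text",
                    "site_id", "gold_label")

docs_as_data_frame <- function(docs) {
  data.frame(
    report_id = vapply(docs, `[[`, character(1), "report_id"),
    impression_text = vapply(docs, `[[`, character(1), "impression_text"),
    full_report_text = vapply(docs, `[[`, character(1), "full_report_text"),
    site_id = vapply(docs, `[[`, character(1), "site_id"),
    gold_label = vapply(docs, `[[`, integer(1), "gold_label"),
    stringsAsFactors = FALSE)
}

# row_errors = "skip" isolates malformed rows: each is reported (row number +
# reason) in the "skipped" attribute instead of aborting the whole read.
df_as_docs <- function(df, row_errors = c("stop", "skip")) {
  row_errors <- match.arg(row_errors)
  skipped <- list()
  docs <- list()
  for (i in seq_len(nrow(df))) {
    d <- tryCatch(
      report_document(df$report_id[i],
                      impression_text = df$impression_text[i],
                      full_report_text = if ("full_report_text" %in% names(df))
                        df$full_report_text[i] else "",
                      site_id = if ("site_id" %in% names(df))
                        df$site_id[i] else NA_character_,
                      gold_label = if ("gold_label" %in% names(df))
                        df$gold_label[i] else NA_integer_),
      error = function(e) e)
    if (inherits(d, "error")) {
      if (row_errors == "stop") stop("row ", i, ": ", conditionMessage(d),
                                     call. = FALSE)
      skipped[[length(skipped) + 1L]] <- data.frame(
        row = i, message = conditionMessage(d), stringsAsFactors = FALSE)
    } else {
      docs[[length(docs) + 1L]] <- d
    }
  }
  attr(docs, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(row = integer(), message = character(), stringsAsFactors = FALSE)
  docs
}

#' Read and write report corpora
#'
#' Corpora are stored as JSONL (one JSON object per line — the canonical,
#' streaming-friendly format) or CSV, with columns/keys `report_id`,
#' `impression_text`, `full_report_text`, `site_id`, `gold_label`.
#'
#' @param docs List of [report_document()]s.
#' @param path File path.
#' @return Readers return a list of documents; writers return `path`
#'   invisibly.
#' @export
write_corpus_jsonl <- function(docs, path) {
  df <- docs_as_data_frame(docs)
  lines <- vapply(seq_len(nrow(df)), function(i)
    as.character(jsonlite::toJSON(as.list(df[i, , drop = FALSE]),
                                  auto_unbox = TRUE, na = "null")),
    character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_corpus_jsonl
#' @param row_errors `"stop"` (default) to fail on a malformed row, `"skip"`
#'   to drop it and record it in the result's `"skipped"` attribute (a data
#'   frame of row numbers and messages).
#' @export
read_corpus_jsonl <- function(path, row_errors = c("stop", "skip")) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(lines, function(l) {
    r <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    data.frame(
      report_id = as.character(r$report_id %||% NA_character_),
      impression_text = as.character(r$impression_text %||% ""),
      full_report_text = as.character(r$full_report_text %||% ""),
      site_id = as.character(r$site_id %||% NA_character_),
      gold_label = as.integer(r$gold_label %||% NA_integer_),
      stringsAsFactors = FALSE)
  })
  if (!length(rows)) return(df_as_docs(docs_as_data_frame(list()), row_errors))
  df_as_docs(do.call(rbind, rows), row_errors)
}

#' @rdname write_corpus_jsonl
#' @export
write_corpus_csv <- function(docs, path) {
  utils::write.csv(docs_as_data_frame(docs), path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' @rdname write_corpus_jsonl
#' @export
read_corpus_csv <- function(path, row_errors = c("stop", "skip")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!"report_id" %in% names(df))
    stop("corpus CSV lacks a report_id column", call. = FALSE)
  if ("gold_label" %in% names(df))
    df$gold_label <- suppressWarnings(as.integer(df$gold_label))
  df_as_docs(df, row_errors)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a
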