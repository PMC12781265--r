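#' Polarity of a single target mention
#'
#' A mention is `POSITIVE` when it carries direct positive evidence of
#' ischemia — its category is an ischemia or reversibility term, or it is a
#' perfusion finding bound to a reversibility modifier — and no refuting
#' attribute is set. Negation, fixed-defect, and artifact attributions each
#' refute; hedges (`is_uncertain`) never change the outcome, so "likely
#' ischemia" stays positive. A bare perfusion finding with no reversibility
#' cue is `NOT_POSITIVE`: a defect alone is not documentation of ischemia.
#'
#' @param m A target mention with context applied.
#' @return `"POSITIVE"` or `"NOT_POSITIVE"`.
#' @export
mention_polarity <- function(m) {
  a <- m$attributes
  positive_evidence <- m$category %in% c("ISCHEMIA_TERM", "REVERSIBILITY_TERM") ||
    isTRUE(a$has_reversible_modifier)
  refuted <- isTRUE(a$is_negated) || isTRUE(a$is_fixed) || isTRUE(a$is_artifact)
  if (positive_evidence && !refuted) "POSITIVE" else "NOT_POSITIVE"
}

#' Classify one stress test report for myocardial ischemia
#'
#' Runs the full pipeline on the document's analysis text: sentence
#' segmentation, tokenization, target and modifier matching, directional
#' scope resolution, context application, and per-mention polarity. The
#' document is positive (`ischemia = 1`) if and only if at least one mention
#' is positive — ischemia in any myocardial territory makes the report
#' positive regardless of how many territories are negative, which is how
#' reports are read clinically. The result carries an evidence excerpt of the
#' decisive targets and the modifiers that touched them.
#'
#' @param doc A [report_document()].
#' @param rb A [rulebook()]; default the built-in ischemia rulebook.
#' @param policy Text-selection policy, see [select_analysis_text()].
#' @return A `document_classification` with fields `report_id`, `ischemia`
#'   (0/1), `evidence`, `mentions`, and `source_text_provenance`.
#' @examples
#' classify_document(report_document("r1", "Likely ischemia"))$ischemia      # 1
#' classify_document(report_document("r2", "Negative for reversible ischemia"))$ischemia  # 0
#' @export
classify_document <- function(doc, rb = default_ischemia_rulebook(),
    policy = c("IMPRESSION_THEN_FULL_IMPRESSION_SECTION", "IMPRESSION_ONLY",
               "FULL")) {
  policy <- match.arg(policy)
  sel <- select_analysis_text(doc, policy, section_rules = rb$sections)
  text <- sel$text
  sentences <- segment_sentences(text)
  mentions <- list()
  for (si in seq_len(nrow(sentences))) {
    tokens <- tokenize(sentences$text[si], offset = sentences$start[si])
    if (!nrow(tokens)) next
    targets <- match_targets(tokens, si, rb$targets, source = text)
    if (!length(targets)) next
    modifiers <- match_modifiers(tokens, rb$contexts, source = text)
    modifiers <- resolve_scopes(modifiers, tokens, source = text)
    targets <- apply_context(targets, modifiers)
    mentions <- c(mentions, targets)
  }
  polarity <- vapply(mentions, mention_polarity, character(1))
  ischemia <- as.integer(any(polarity == "POSITIVE"))
  if (isTRUE(getOption("stressnlp.verbose", FALSE))) {
    conflicted <- vapply(mentions, function(m)
      isTRUE(m$attributes$has_reversible_modifier) &&
        isTRUE(m$attributes$is_fixed), logical(1))
    if (any(conflicted))
      message("report ", doc$report_id, ": ", sum(conflicted),
              " mention(s) carry both fixed and reversible cues; refutation wins")
  }
  decisive <- if (ischemia == 1L) mentions[polarity == "POSITIVE"] else mentions
  evidence <- paste(vapply(decisive, format_evidence_fragment, character(1)),
                    collapse = " | ")
  new_document_classification(doc$report_id, ischemia, evidence, mentions,
                              sel$provenance)
}

format_evidence_fragment <- function(m) {
  mods <- if (length(m$modifier_rule_ids)) {
    paste0("; modifiers: ", paste(m$modifier_rule_ids, collapse = ", "))
  } else ""
  sprintf("%s [%s%s]", m$span$text, m$category, mods)
}

#' Classify a corpus of reports
#'
#' Order-preserving batch classification with per-document error isolation:
#' a document that cannot be classified (no usable text) is reported in the
#' summary, never silently dropped and never aborting the batch.
#'
#' @param docs List of [report_document()] objects.
#' @param rb A [rulebook()].
#' @param policy Text-selection policy.
#' @return An object of class `"corpus_classification"`: a list with
#'   `results` (the classifications, in input order), `errors` (a data frame
#'   of `report_id` and `message`), and `summary` (`n_classified`,
#'   `n_errored`, `prevalence` = positives / classified, `NA` when nothing
#'   classified).
#' @export
classify_corpus <- function(docs, rb = default_ischemia_rulebook(),
    policy = c("IMPRESSION_THEN_FULL_IMPRESSION_SECTION", "IMPRESSION_ONLY",
               "FULL")) {
  policy <- match.arg(policy)
  results <- list()
  errors <- list()
  for (doc in docs) {
    res <- tryCatch(classify_document(doc, rb, policy), error = function(e) e)
    if (inherits(res, "error")) {
      errors[[length(errors) + 1L]] <- data.frame(
        report_id = doc$report_id, message = conditionMessage(res),
        stringsAsFactors = FALSE)
    } else {
      results[[length(results) + 1L]] <- res
    }
  }
  errdf <- if (length(errors)) do.call(rbind, errors) else
    data.frame(report_id = character(), message = character(),
               stringsAsFactors = FALSE)
  n_classified <- length(results)
  n_pos <- sum(vapply(results, `[[`, integer(1), "ischemia"))
  structure(list(
    results = results, errors = errdf,
    summary = list(n_classified = n_classified, n_errored = nrow(errdf),
                   n_positive = n_pos,
                   prevalence = if (n_classified) n_pos / n_classified else NA_real_)),
    class = "corpus_classification")
}

#' @export
print.corpus_classification <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<corpus classification: %d classified, %d errored, prevalence %s>\n",
              s$n_classified, s$n_errored,
              if (is.na(s$prevalence)) "NA" else sprintf("%.1f%%", 100 * s$prevalence)))
  invisible(x)
}

#' @export
summary.corpus_classification <- function(object, ...) {
  print(object)
  if (nrow(object$errors)) {
    cat("errored report_ids:", paste(object$errors$report_id, collapse = ", "), "\n")
  }
  invisible(object$summary)
}

#' @export
as.data.frame.corpus_classification <- function(x, ...) {
  data.frame(
    report_id = vapply(x$results, `[[`, character(1), "report_id"),
    ischemia = vapply(x$results, `[[`, integer(1), "ischemia"),
    evidence = vapply(x$results, `[[`, character(1), "evidence"),
    source_text_provenance = vapply(x$results, `[[`, character(1),
                                    "source_text_provenance"),
    stringsAsFactors = FALSE)
}
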