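#' @details
#' All character offsets in stressnlp are 0-based and half-open: a span
#' `[start, end)` covers `end - start` characters, and `substring(text,
#' start + 1, end)` recovers its text. This is the dominant convention of
#' text-annotation tooling and keeps span arithmetic off-by-one-safe.
#'
#' @keywords internal
"_PACKAGE"

TARGET_CATEGORIES <- c("ISCHEMIA_TERM", "REVERSIBILITY_TERM", "PERFUSION_FINDING")
MODIFIER_CATEGORIES <- c("NEGATED_EXISTENCE", "FIXED", "ARTIFACT", "REVERSIBLE",
                         "UNCERTAIN", "TERMINATE")
MODIFIER_DIRECTIONS <- c("FORWARD", "BACKWARD", "BIDIRECTIONAL")
ATTRIBUTE_FLAGS <- c("is_negated", "is_fixed", "is_artifact", "is_uncertain",
                     "has_reversible_modifier")

#' Character span within a source text
#'
#' A span is a 0-based, half-open interval `[start, end)` over a source text,
#' carrying the covered substring.
#'
#' @param start Integer, 0-based inclusive start offset.
#' @param end Integer, 0-based exclusive end offset; must satisfy
#'   `0 <= start <= end <= nchar(source)`.
#' @param source The source text the offsets refer to.
#' @return An object of class `"stressnlp_span"`: a list with elements
#'   `start`, `end` and `text`.
#' @examples
#' span(0, 5, "Likely ischemia")$text  # "Likel"
#' @export
span <- function(start, end, source) {
  start <- as.integer(start)
  end <- as.integer(end)
  stopifnot(length(start) == 1L, length(end) == 1L, !is.na(start), !is.na(end))
  if (start < 0L || end < start || end > nchar(source))
    stop("invalid span [", start, ", ", end, ") for text of length ",
         nchar(source), call. = FALSE)
  structure(list(start = start, end = end,
                 text = substring(source, start + 1L, end)),
            class = "stressnlp_span")
}

#' @export
print.stressnlp_span <- function(x, ...) {
  cat(sprintf("<span [%d,%d) %s>\n", x$start, x$end, deparse(x$text)))
  invisible(x)
}

#' Span predicates
#'
#' `span_overlaps()` tests whether two half-open spans intersect;
#' `span_contains()` tests whether `outer` fully contains `inner`. Both spans
#' must refer to the same source text.
#'
#' @param a,b,outer,inner Spans created with [span()], or any list with
#'   numeric `start` and `end` elements.
#' @return Logical scalar.
#' @examples
#' s <- "no ischemia"
#' span_overlaps(span(0, 5, s), span(3, 8, s))  # TRUE
#' span_overlaps(span(0, 5, s), span(5, 8, s))  # FALSE (half-open)
#' @export
span_overlaps <- function(a, b) {
  a$start < b$end && b$start < a$end
}

#' @rdname span_overlaps
#' @export
span_contains <- function(outer, inner) {
  outer$start <= inner$start && inner$end <= outer$end
}

#' Construct a stress test report document
#'
#' The unit record of the pipeline: one nuclear cardiac stress test report.
#' The impression (the report's summarizing section) is the text the
#' classifier prefers; the full report text is an optional fallback from
#' which an IMPRESSION section can be extracted.
#'
#' @param report_id Non-empty string, unique within a corpus.
#' @param impression_text Free text of the impression section; may be empty.
#' @param full_report_text Optional full report free text.
#' @param site_id Optional site identifier (medical centers differ in
#'   boilerplate and lexicon).
#' @param gold_label Optional reference label: 1 = ischemia present, 0 = absent.
#' @return An object of class `"report_document"`.
#' @export
report_document <- function(report_id, impression_text = "",
                            full_report_text = "", site_id = NA_character_,
                            gold_label = NA_integer_) {
  report_id <- as.character(report_id)
  if (length(report_id) != 1L || is.na(report_id) || !nzchar(report_id))
    stop("report_id must be a non-empty string", call. = FALSE)
  if (!is.na(gold_label) && !gold_label %in% c(0L, 1L))
    stop("gold_label must be 0, 1 or NA", call. = FALSE)
  structure(list(report_id = report_id,
                 impression_text = as_scalar_text(impression_text),
                 full_report_text = as_scalar_text(full_report_text),
                 site_id = as.character(site_id),
                 gold_label = as.integer(gold_label)),
            class = "report_document")
}

as_scalar_text <- function(x) {
  if (is.null(x) || length(x) == 0L || is.na(x[1L])) "" else as.character(x[1L])
}

#' @export
print.report_document <- function(x, ...) {
  cat(sprintf("<report %s%s: %d impression chars, %d full-report chars>\n",
              x$report_id,
              if (!is.na(x$gold_label)) paste0(" [gold=", x$gold_label, "]") else "",
              nchar(x$impression_text), nchar(x$full_report_text)))
  invisible(x)
}

# A target mention: a matched clinical concept span plus the attribute flags
# the context engine later sets. Flags are always FALSE at match time.
new_target_mention <- function(span, category, rule_id, sentence_index) {
  stopifnot(category %in% TARGET_CATEGORIES)
  attrs <- stats::setNames(as.list(rep(FALSE, length(ATTRIBUTE_FLAGS))),
                           ATTRIBUTE_FLAGS)
  structure(list(span = span, category = category, rule_id = rule_id,
                 sentence_index = as.integer(sentence_index),
                 attributes = attrs),
            class = "target_mention")
}

#' @export
print.target_mention <- function(x, ...) {
  on <- names(Filter(isTRUE, x$attributes))
  cat(sprintf("<target %s %s [%d,%d)%s>\n", deparse(x$span$text), x$category,
              x$span$start, x$span$end,
              if (length(on)) paste0(" ", paste(on, collapse = ",")) else ""))
  invisible(x)
}

# A modifier mention: a context cue span, its direction, and (once resolved)
# the scope span it governs. TERMINATE mentions have no direction or scope;
# they cut the scopes of other modifiers.
new_modifier_mention <- function(span, category, direction, rule_id,
                                 max_scope_tokens = Inf,
                                 token_start = NA_integer_,
                                 token_end = NA_integer_) {
  stopifnot(category %in% MODIFIER_CATEGORIES)
  if (category != "TERMINATE") stopifnot(direction %in% MODIFIER_DIRECTIONS)
  structure(list(span = span, category = category,
                 direction = if (category == "TERMINATE") NA_character_ else direction,
                 scope = NULL, rule_id = rule_id,
                 max_scope_tokens = max_scope_tokens,
                 token_start = as.integer(token_start),
                 token_end = as.integer(token_end)),
            class = "modifier_mention")
}

#' Document classification result
#'
#' The output record of [classify_document()]: the binary ischemia indicator
#' together with a text excerpt of the target and modifier mentions the
#' determination used.
#'
#' @name document_classification
#' @keywords internal
new_document_classification <- function(report_id, ischemia, evidence,
                                        mentions, provenance) {
  structure(list(report_id = report_id, ischemia = as.integer(ischemia),
                 evidence = evidence, mentions = mentions,
                 source_text_provenance = provenance),
            class = "document_classification")
}

#' @export
print.document_classification <- function(x, ...) {
  cat(sprintf("<classification %s: ischemia=%d (%s)>\n", x$report_id,
              x$ischemia, x$source_text_provenance))
  if (nzchar(x$evidence)) cat("  evidence: ", x$evidence, "\n", sep = "")
  invisible(x)
}
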