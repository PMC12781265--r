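#' Split text into sentences
#'
#' Deterministic, rule-based segmentation suited to short, telegraphic,
#' list-structured impressions. Boundaries fall at newline runs and after a
#' period, question mark, or exclamation mark that is followed by whitespace
#' and an uppercase letter or digit. Enumerated-list markers ("1.", "2.") do
#' not end sentences, so numbered impressions stay intact.
#'
#' @param text Free text; may be empty.
#' @return A data frame with one row per sentence and columns `index`
#'   (ordinal, 1-based), `start`, `end` (0-based half-open character offsets
#'   into `text`) and `text`. Sentences are non-overlapping and ordered.
#' @examples
#' segment_sentences("No ischemia. Normal study.")
#' @export
segment_sentences <- function(text) {
  empty <- data.frame(index = integer(), start = integer(), end = integer(),
                      text = character(), stringsAsFactors = FALSE)
  if (is.null(text) || is.na(text) || !nzchar(text)) return(empty)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  # boundary after position i means a sentence ends at i (1-based, inclusive)
  breaks <- integer(0)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "\n") {
      breaks <- c(breaks, i - 1L)  # sentence ends before the newline
    } else if (ch %in% c(".", "?", "!") && i < n && grepl("\\s", chars[i + 1L])) {
      # look ahead past whitespace for an uppercase letter or digit
      j <- i + 1L
      while (j <= n && grepl("\\s", chars[j])) j <- j + 1L
      if (j <= n && grepl("[A-Z0-9]", chars[j]) &&
          !is_list_marker(chars, i)) {
        breaks <- c(breaks, i)
      }
    }
    i <- i + 1L
  }
  bounds <- unique(c(0L, breaks, n))
  bounds <- sort(bounds[bounds >= 0L & bounds <= n])
  out <- list()
  for (k in seq_len(length(bounds) - 1L)) {
    s <- bounds[k]; e <- bounds[k + 1L]
    seg <- substring(text, s + 1L, e)
    # trim whitespace but keep offsets honest
    lead <- nchar(seg) - nchar(sub("^\\s+", "", seg))
    trail <- nchar(seg) - nchar(sub("\\s+$", "", seg))
    s2 <- s + lead; e2 <- e - trail
    if (e2 > s2)
      out[[length(out) + 1L]] <- data.frame(
        start = s2, end = e2, text = substring(text, s2 + 1L, e2),
        stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- cbind(index = seq_len(nrow(res)), res)
  res
}

# TRUE when the '.' at 1-based position i terminates an enumerated-list
# marker: the maximal word before it consists only of digits.
is_list_marker <- function(chars, i) {
  j <- i - 1L
  saw_digit <- FALSE
  while (j >= 1L && grepl("[0-9]", chars[j])) { saw_digit <- TRUE; j <- j - 1L }
  saw_digit && (j < 1L || grepl("\\s", chars[j]))
}

#' Tokenize a sentence with character offsets
#'
#' Splits on whitespace and detaches the punctuation characters
#' `, . ; : ( ) /` as their own tokens. Offsets are 0-based half-open into the
#' text the sentence came from (`offset` shifts them, so tokens of a sentence
#' can carry document-level offsets). Tokenization is lossless: the substrings
#' between consecutive tokens are pure whitespace.
#'
#' @param sentence_text The sentence text.
#' @param offset Character offset of the sentence within its document
#'   (default 0).
#' @return A data frame with columns `start`, `end`, `text`, and `norm`
#'   (the lower-cased surface form).
#' @examples
#' tokenize("Negative for reversible ischemia")
#' @export
tokenize <- function(sentence_text, offset = 0L) {
  empty <- data.frame(start = integer(), end = integer(), text = character(),
                      norm = character(), stringsAsFactors = FALSE)
  if (is.null(sentence_text) || is.na(sentence_text) || !nzchar(sentence_text))
    return(empty)
  m <- gregexpr("[,.;:()/]|[^[:space:],.;:()/]+", sentence_text)[[1]]
  if (m[1] == -1) return(empty)
  starts <- as.integer(m) - 1L + as.integer(offset)
  lens <- attr(m, "match.length")
  texts <- regmatches(sentence_text, gregexpr("[,.;:()/]|[^[:space:],.;:()/]+",
                                              sentence_text))[[1]]
  data.frame(start = starts, end = starts + lens, text = texts,
             norm = tolower(texts), stringsAsFactors = FALSE)
}

#' Detect report sections by header rules
#'
#' A header matches when a section rule's `header_pattern` occurs at line
#' start, case-insensitively, optionally followed by a colon or dash. Each
#' section runs from its header to the next header (or end of text); text
#' before the first header forms an implicit `PREAMBLE` section. Section
#' spans therefore partition all text from the first header onward.
#'
#' @param text Full report text.
#' @param rules List of [section_rule()] objects.
#' @return A data frame with columns `section_category`, `start`, `end`
#'   (span of the whole section including its header), `header_start`,
#'   `header_end`, `body_start`, `body_end` (content after the header and any
#'   colon/dash), and `body` (the trimmed body text).
#' @export
detect_sections <- function(text, rules) {
  empty <- data.frame(section_category = character(), start = integer(),
                      end = integer(), header_start = integer(),
                      header_end = integer(), body_start = integer(),
                      body_end = integer(), body = character(),
                      stringsAsFactors = FALSE)
  if (is.null(text) || is.na(text) || !nzchar(text)) return(empty)
  n <- nchar(text)
  hits <- list()
  for (r in rules) {
    pat <- paste0("(?mi)^[ \\t]*(", escape_regex(r$header_pattern),
                  ")[ \\t]*(:|-)?[ \\t]*")
    m <- gregexpr(pat, text, perl = TRUE)[[1]]
    if (m[1] == -1) next
    for (k in seq_along(m)) {
      hits[[length(hits) + 1L]] <- data.frame(
        section_category = r$section_category,
        header_start = as.integer(m[k]) - 1L,
        body_start = as.integer(m[k]) - 1L + attr(m, "match.length")[k],
        header_end = as.integer(m[k]) - 1L +
          attr(m, "capture.start")[k, 1] - m[k] +
          attr(m, "capture.length")[k, 1],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) {
    body <- trimws(text)
    return(data.frame(section_category = "PREAMBLE", start = 0L, end = n,
                      header_start = NA_integer_, header_end = NA_integer_,
                      body_start = 0L, body_end = n, body = body,
                      stringsAsFactors = FALSE))
  }
  h <- do.call(rbind, hits)
  h <- h[order(h$header_start), , drop = FALSE]
  # overlapping header matches (two rules on one line): keep the earliest
  keep <- !duplicated(h$header_start)
  h <- h[keep, , drop = FALSE]
  h$start <- h$header_start
  h$end <- c(h$header_start[-1L], n)
  h$body_end <- h$end
  h$body <- trimws(substring(text, h$body_start + 1L, h$body_end))
  out <- h
  if (h$start[1L] > 0L) {
    pre <- data.frame(section_category = "PREAMBLE", start = 0L,
                      end = h$start[1L], header_start = NA_integer_,
                      header_end = NA_integer_, body_start = 0L,
                      body_end = h$start[1L],
                      body = trimws(substring(text, 1L, h$start[1L])),
                      stringsAsFactors = FALSE)
    out <- rbind(pre, h[, names(pre)])
  } else {
    out <- h[, c("section_category", "start", "end", "header_start",
                 "header_end", "body_start", "body_end", "body")]
  }
  rownames(out) <- NULL
  out
}

escape_regex <- function(x) gsub("([][{}()*+?.^$|\\\\])", "\\\\\\1", x)

#' Select the text a document is classified on
#'
#' Impressions are preferred: they are succinct and less prone to false
#' positives than full reports. Three policies are supported:
#' \describe{
#'   \item{IMPRESSION_ONLY}{use `impression_text` only (reproduces the
#'     reference configuration exactly).}
#'   \item{IMPRESSION_THEN_FULL_IMPRESSION_SECTION}{the default: fall back to
#'     the IMPRESSION section extracted from `full_report_text` when the
#'     impression field is empty. Useful for warehouse extracts with missing
#'     impression fields; the fallback is recorded in the provenance tag.}
#'   \item{FULL}{use the entire `full_report_text`.}
#' }
#'
#' @param doc A [report_document()].
#' @param policy One of the three policy names above.
#' @param section_rules Section rules used for the fallback extraction
#'   (default: the built-in rulebook's).
#' @return A list with elements `text` and `provenance` (one of
#'   `"impression"`, `"full_report_impression_section"`, `"full_report"`).
#' @export
select_analysis_text <- function(doc,
    policy = c("IMPRESSION_THEN_FULL_IMPRESSION_SECTION", "IMPRESSION_ONLY",
               "FULL"),
    section_rules = default_ischemia_rulebook()$sections) {
  policy <- match.arg(policy)
  fail <- function() stop("document '", doc$report_id,
                          "' has no usable text under policy ", policy,
                          call. = FALSE)
  if (policy == "FULL") {
    if (!nzchar(doc$full_report_text)) fail()
    return(list(text = doc$full_report_text, provenance = "full_report"))
  }
  if (nzchar(trimws(doc$impression_text)))
    return(list(text = doc$impression_text, provenance = "impression"))
  if (policy == "IMPRESSION_ONLY") fail()
  if (nzchar(doc$full_report_text)) {
    secs <- detect_sections(doc$full_report_text, section_rules)
    imp <- secs[secs$section_category == "IMPRESSION", , drop = FALSE]
    if (nrow(imp) && nzchar(imp$body[1L]))
      return(list(text = imp$body[1L],
                  provenance = "full_report_impression_section"))
  }
  fail()
}
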