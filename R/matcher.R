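# Token-sequence matching with longest/leftmost overlap resolution.
#
# A pattern is a whitespace-separated sequence of lower-case tokens; "*"
# matches any single token. Matching compares against token norms, so it is
# case-insensitive and immune to substring artifacts ("ischemiaX" never
# matches "ischemia"). When candidate matches overlap, the longest (most
# tokens) wins; ties go to the leftmost start, then to the earlier-listed
# rule. Selected matches never overlap.

pattern_tokens <- function(pattern) strsplit(tolower(trimws(pattern)), "\\s+")[[1]]

# Enumerate every (rule, position) candidate, then greedily select
# non-overlapping matches in (length desc, start asc, rule order asc) order.
# Returns a data frame of token ranges (1-based, inclusive).
match_token_sequences <- function(norms, patterns) {
  n <- length(norms)
  cand <- list()
  for (ri in seq_along(patterns)) {
    pt <- pattern_tokens(patterns[[ri]])
    k <- length(pt)
    if (k == 0L || k > n) next
    for (s in seq_len(n - k + 1L)) {
      seg <- norms[s:(s + k - 1L)]
      if (all(pt == "*" | pt == seg))
        cand[[length(cand) + 1L]] <- c(rule = ri, from = s, to = s + k - 1L,
                                       len = k)
    }
  }
  if (!length(cand))
    return(data.frame(rule = integer(), from = integer(), to = integer()))
  cd <- as.data.frame(do.call(rbind, cand))
  cd <- cd[order(-cd$len, cd$from, cd$rule), , drop = FALSE]
  taken <- rep(FALSE, n)
  keep <- logical(nrow(cd))
  for (i in seq_len(nrow(cd))) {
    rng <- cd$from[i]:cd$to[i]
    if (!any(taken[rng])) {
      keep[i] <- TRUE
      taken[rng] <- TRUE
    }
  }
  sel <- cd[keep, c("rule", "from", "to"), drop = FALSE]
  sel <- sel[order(sel$from), , drop = FALSE]
  rownames(sel) <- NULL
  sel
}

token_range_span <- function(tokens, from, to, source) {
  span(tokens$start[from], tokens$end[to], source)
}

#' Find target-concept mentions in a tokenized sentence
#'
#' Applies the rulebook's target rules to one sentence's tokens. Matching is
#' case-insensitive on token norms; overlapping candidates are resolved
#' longest-match-first (so "reversible ischemia" shadows "ischemia"), with
#' ties broken leftmost then by rule order. Returned mentions are
#' non-overlapping and ordered by start offset, with all attribute flags
#' `FALSE` — only the context engine sets them.
#'
#' @param tokens Token data frame from [tokenize()] (one sentence).
#' @param sentence_index Ordinal index of the sentence within its document.
#' @param rules List of [target_rule()] objects.
#' @param source Source text the token offsets refer to.
#' @return List of target mentions.
#' @export
match_targets <- function(tokens, sentence_index, rules,
                          source = paste(tokens$text, collapse = " ")) {
  if (!nrow(tokens) || !length(rules)) return(list())
  sel <- match_token_sequences(tokens$norm,
                               lapply(rules, `[[`, "pattern"))
  lapply(seq_len(nrow(sel)), function(i) {
    r <- rules[[sel$rule[i]]]
    m <- new_target_mention(token_range_span(tokens, sel$from[i], sel$to[i],
                                             source),
                            r$category, r$rule_id, sentence_index)
    m$token_start <- sel$from[i]
    m$token_end <- sel$to[i]
    m
  })
}

#' Find context-modifier mentions in a tokenized sentence
#'
#' Same matching semantics as [match_targets()]. `TERMINATE` matches are
#' returned as scope-cutting markers; scopes are not yet assigned — use
#' [resolve_scopes()].
#'
#' @inheritParams match_targets
#' @param rules List of [context_rule()] objects.
#' @return List of modifier mentions (scope unset).
#' @export
match_modifiers <- function(tokens, rules,
                            source = paste(tokens$text, collapse = " ")) {
  if (!nrow(tokens) || !length(rules)) return(list())
  sel <- match_token_sequences(tokens$norm,
                               lapply(rules, `[[`, "pattern"))
  lapply(seq_len(nrow(sel)), function(i) {
    r <- rules[[sel$rule[i]]]
    new_modifier_mention(token_range_span(tokens, sel$from[i], sel$to[i],
                                          source),
                         r$category, r$direction, r$rule_id,
                         max_scope_tokens = r$max_scope_tokens,
                         token_start = sel$from[i], token_end = sel$to[i])
  })
}
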