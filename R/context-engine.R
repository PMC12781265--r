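# ConText-style directional scoping. A modifier governs a token window on
# one or both sides of its own span; the window is cut by the sentence
# boundary, by the nearest TERMINATE marker in that direction, and by the
# rule's max_scope_tokens limit. Targets whose tokens fall inside a
# modifier's window receive the attribute the modifier's category maps to.

#' Resolve one modifier's scope within its sentence
#'
#' Computes the token window a modifier governs. A `FORWARD` scope runs from
#' the token after the modifier to the earliest of: the sentence end, the
#' token before the nearest following `TERMINATE` marker, and
#' `max_scope_tokens` tokens past the modifier. `BACKWARD` is symmetric
#' toward the sentence start; `BIDIRECTIONAL` is the union of both windows.
#' `TERMINATE` mentions themselves carry no scope.
#'
#' @param modifier A modifier mention from [match_modifiers()].
#' @param tokens The sentence's token data frame.
#' @param terminators Modifier mentions of category `TERMINATE` in the same
#'   sentence.
#' @param source Source text for span construction.
#' @return The modifier with `scope` (a character span) and `scope_tokens`
#'   (the governed token indices, possibly empty) set.
#' @export
resolve_scope <- function(modifier, tokens, terminators = list(),
                          source = paste(tokens$text, collapse = " ")) {
  n <- nrow(tokens)
  if (modifier$category == "TERMINATE") {
    modifier$scope_tokens <- integer(0)
    modifier$scope <- span(modifier$span$end, modifier$span$end, source)
    return(modifier)
  }
  term_starts <- vapply(terminators, `[[`, integer(1), "token_start")
  term_ends <- vapply(terminators, `[[`, integer(1), "token_end")
  fwd <- integer(0)
  bwd <- integer(0)
  if (modifier$direction %in% c("FORWARD", "BIDIRECTIONAL")) {
    from <- modifier$token_end + 1L
    to <- min(n, modifier$token_end + modifier$max_scope_tokens)
    cut <- term_starts[term_starts > modifier$token_end]
    if (length(cut)) to <- min(to, min(cut) - 1L)
    if (from <= to) fwd <- from:to
  }
  if (modifier$direction %in% c("BACKWARD", "BIDIRECTIONAL")) {
    to <- modifier$token_start - 1L
    from <- max(1L, modifier$token_start - modifier$max_scope_tokens)
    cut <- term_ends[term_ends < modifier$token_start]
    if (length(cut)) from <- max(from, max(cut) + 1L)
    if (from <= to) bwd <- from:to
  }
  sc <- sort(unique(c(bwd, fwd)))
  modifier$scope_tokens <- sc
  modifier$scope <- if (length(sc)) {
    span(tokens$start[min(sc)], tokens$end[max(sc)], source)
  } else if (modifier$direction == "BACKWARD") {
    span(modifier$span$start, modifier$span$start, source)
  } else {
    span(modifier$span$end, modifier$span$end, source)
  }
  modifier
}

#' Resolve scopes for all modifiers in a sentence
#'
#' @param modifiers List of modifier mentions from [match_modifiers()].
#' @inheritParams resolve_scope
#' @return The list with every non-`TERMINATE` modifier's scope set.
#' @export
resolve_scopes <- function(modifiers, tokens,
                           source = paste(tokens$text, collapse = " ")) {
  terminators <- Filter(function(m) m$category == "TERMINATE", modifiers)
  lapply(modifiers, resolve_scope, tokens = tokens,
         terminators = terminators, source = source)
}

MODIFIER_ATTRIBUTE <- c(NEGATED_EXISTENCE = "is_negated",
                        FIXED = "is_fixed",
                        ARTIFACT = "is_artifact",
                        UNCERTAIN = "is_uncertain",
                        REVERSIBLE = "has_reversible_modifier")

#' Apply modifier scopes to target mentions
#'
#' Sets each target's attribute flags from the modifiers whose resolved
#' scopes intersect it: negation sets `is_negated`, fixed-defect cues set
#' `is_fixed`, artifact attributions set `is_artifact`, hedges set
#' `is_uncertain`, and reversibility cues set `has_reversible_modifier`.
#' Additionally, a `REVERSIBLE` modifier immediately adjacent to a
#' `PERFUSION_FINDING` ("reversible defect") binds to it even when scope
#' arithmetic would not reach it. Attributes accumulate independently — a
#' target may be both fixed and uncertain; precedence between positivity and
#' refutation is decided later by [mention_polarity()].
#'
#' @param targets List of target mentions (same sentence).
#' @param modifiers List of scope-resolved modifier mentions.
#' @return The targets with attribute flags set and, on each target, a
#'   `modifier_rule_ids` vector naming the modifiers that touched it.
#' @export
apply_context <- function(targets, modifiers) {
  mods <- Filter(function(m) m$category != "TERMINATE", modifiers)
  lapply(targets, function(tg) {
    touching <- character(0)
    touching_cat <- character(0)
    for (m in mods) {
      hit <- length(m$scope_tokens) &&
        any(m$scope_tokens >= tg$token_start & m$scope_tokens <= tg$token_end)
      adjacent <- m$category == "REVERSIBLE" &&
        tg$category == "PERFUSION_FINDING" &&
        (m$token_end + 1L == tg$token_start ||
         tg$token_end + 1L == m$token_start)
      if (hit || adjacent) {
        tg$attributes[[MODIFIER_ATTRIBUTE[[m$category]]]] <- TRUE
        touching <- c(touching, m$rule_id)
        touching_cat <- c(touching_cat, m$category)
      }
    }
    tg$modifier_rule_ids <- touching
    tg$modifier_categories <- touching_cat
    tg
  })
}
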