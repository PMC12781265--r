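# Independent brute-force oracles and randomized fixtures. These deliberately
# re-derive expected behavior by direct enumeration, not by calling the
# implementation's internals.

# --- matcher oracle -----------------------------------------------------
# Enumerate every (rule, position) candidate by hand, then select
# non-overlapping matches by repeatedly taking the single best remaining
# candidate (longest, then leftmost, then earliest rule) and discarding
# everything that overlaps it.
oracle_match <- function(norms, patterns) {
  cands <- list()
  for (ri in seq_along(patterns)) {
    pt <- strsplit(tolower(patterns[[ri]]), "\\s+")[[1]]
    k <- length(pt)
    if (k == 0 || k > length(norms)) next
    for (s in seq_len(length(norms) - k + 1)) {
      ok <- TRUE
      for (j in seq_len(k)) {
        if (pt[j] != "*" && pt[j] != norms[s + j - 1]) { ok <- FALSE; break }
      }
      if (ok) cands[[length(cands) + 1]] <- list(rule = ri, from = s,
                                                 to = s + k - 1)
    }
  }
  chosen <- list()
  while (length(cands)) {
    best <- 1
    for (i in seq_along(cands)) {
      a <- cands[[i]]; b <- cands[[best]]
      la <- a$to - a$from; lb <- b$to - b$from
      if (la > lb || (la == lb && (a$from < b$from ||
          (a$from == b$from && a$rule < b$rule)))) best <- i
    }
    pick <- cands[[best]]
    chosen[[length(chosen) + 1]] <- pick
    cands <- Filter(function(c) c$to < pick$from || c$from > pick$to, cands)
  }
  chosen <- chosen[order(vapply(chosen, `[[`, numeric(1), "from"))]
  chosen
}

# --- context oracle -----------------------------------------------------
# Token k is governed by modifier m iff it lies within max_scope_tokens on an
# allowed side and no TERMINATE marker sits between the modifier and k.
oracle_governs <- function(m, k, terminators) {
  term_starts <- vapply(terminators, `[[`, integer(1), "token_start")
  term_ends <- vapply(terminators, `[[`, integer(1), "token_end")
  fwd <- m$direction %in% c("FORWARD", "BIDIRECTIONAL") &&
    k > m$token_end && k - m$token_end <= m$max_scope_tokens &&
    !any(term_starts > m$token_end & term_starts <= k)
  bwd <- m$direction %in% c("BACKWARD", "BIDIRECTIONAL") &&
    k < m$token_start && m$token_start - k <= m$max_scope_tokens &&
    !any(term_ends < m$token_start & term_ends >= k)
  fwd || bwd
}

# Expected attribute flags for one target, by direct enumeration of every
# (modifier, target-token) pair plus the reversible-adjacency rule.
oracle_attributes <- function(target, modifiers) {
  flag_of <- c(NEGATED_EXISTENCE = "is_negated", FIXED = "is_fixed",
               ARTIFACT = "is_artifact", UNCERTAIN = "is_uncertain",
               REVERSIBLE = "has_reversible_modifier")
  terminators <- Filter(function(m) m$category == "TERMINATE", modifiers)
  flags <- list(is_negated = FALSE, is_fixed = FALSE, is_artifact = FALSE,
                is_uncertain = FALSE, has_reversible_modifier = FALSE)
  for (m in modifiers) {
    if (m$category == "TERMINATE") next
    hit <- FALSE
    for (k in target$token_start:target$token_end)
      if (oracle_governs(m, k, terminators)) { hit <- TRUE; break }
    if (!hit && m$category == "REVERSIBLE" &&
        target$category == "PERFUSION_FINDING" &&
        (m$token_end + 1 == target$token_start ||
         target$token_end + 1 == m$token_start)) hit <- TRUE
    if (hit) flags[[flag_of[[m$category]]]] <- TRUE
  }
  flags
}

# --- randomized fixtures ------------------------------------------------
# A compact rulebook with varied directions and tight scope limits, so that
# random sentences exercise termination, limits, and adjacency.
property_rulebook <- function() {
  rulebook(
    targets = list(
      target_rule("pt-isch", "ischemia", "ISCHEMIA_TERM"),
      target_rule("pt-rev", "reversibility", "REVERSIBILITY_TERM"),
      target_rule("pt-def", "defect", "PERFUSION_FINDING"),
      target_rule("pt-pdef", "perfusion defect", "PERFUSION_FINDING")),
    contexts = list(
      context_rule("pc-no", "no", "NEGATED_EXISTENCE", "FORWARD", 3),
      context_rule("pc-fixed", "fixed", "FIXED", "FORWARD", 2),
      context_rule("pc-revmod", "reversible", "REVERSIBLE", "FORWARD", 4),
      context_rule("pc-whichrev", "which is reversible", "REVERSIBLE",
                   "BACKWARD", 5),
      context_rule("pc-likely", "likely", "UNCERTAIN", "BIDIRECTIONAL", 3),
      context_rule("pc-artifact", "artifact", "ARTIFACT", "BACKWARD", 4),
      context_rule("pc-and", "and", "TERMINATE"),
      context_rule("pc-but", "but", "TERMINATE")),
    name = "property", version = "1")
}

property_vocab <- c("ischemia", "defect", "reversibility", "perfusion",
                    "no", "fixed", "reversible", "which", "is", "likely",
                    "artifact", "and", "but", "mild", "wall", "area", "of",
                    "the", "seen")

random_sentence <- function(max_tokens = 12) {
  n <- sample.int(max_tokens, 1)
  paste(sample(property_vocab, n, replace = TRUE), collapse = " ")
}

# Run implementation and oracle on one sentence; return TRUE when every
# target's attribute flags agree.
context_case_agrees <- function(text, rb) {
  tokens <- tokenize(text)
  targets <- match_targets(tokens, 1L, rb$targets, source = text)
  if (!length(targets)) return(TRUE)
  modifiers <- match_modifiers(tokens, rb$contexts, source = text)
  resolved <- resolve_scopes(modifiers, tokens, source = text)
  got <- apply_context(targets, resolved)
  for (i in seq_along(targets)) {
    want <- oracle_attributes(targets[[i]], resolved)
    if (!identical(got[[i]]$attributes[names(want)], want)) return(FALSE)
  }
  TRUE
}

# --- frozen printed reference values ------------------------------------
# Confusion-matrix cells and the percentages printed for the five evaluated
# models on the 99-report test set.
reference_model_table <- function() {
  data.frame(
    model = c("rules-based", "bio-clinical-bert", "clinical-bert",
              "distilbert-cased", "distilbert-uncased"),
    a = c(37, 33, 38, 30, 35),
    b = c(5, 6, 6, 5, 5),
    c = c(1, 5, 0, 8, 3),
    d = c(56, 55, 55, 56, 56),
    sensitivity_recall = c(97.4, 86.8, 100, 78.9, 92.1),
    specificity = c(91.8, 90.2, 90.2, 91.8, 91.8),
    precision_ppv = c(88.1, 84.6, 86.4, 85.7, 87.5),
    npv = c(98.2, 91.7, 100, 87.5, 94.9),
    f1 = c(92.5, 85.7, 92.7, 82.2, 89.7),
    stringsAsFactors = FALSE)
}

gold_docs_from_phrases <- function() {
  g <- reference_phrases()
  lapply(seq_len(nrow(g)), function(i)
    report_document(paste0("t1-", i), impression_text = g$phrase[i],
                    gold_label = g$label[i]))
}
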