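rb_default <- default_ischemia_rulebook()

resolve_all <- function(txt, rb = rb_default) {
  tk <- tokenize(txt)
  mods <- match_modifiers(tk, rb$contexts, source = txt)
  list(tokens = tk,
       modifiers = resolve_scopes(mods, tk, source = txt))
}

mod_by_cat <- function(mods, cat)
  Filter(function(m) m$category == cat, mods)

test_that("modifier matching finds cues and terminators", {
  r <- resolve_all("Negative for reversible ischemia")
  neg <- mod_by_cat(r$modifiers, "NEGATED_EXISTENCE")
  expect_length(neg, 1)
  expect_equal(neg[[1]]$span$text, "Negative for")
  expect_equal(neg[[1]]$direction, "FORWARD")

  r <- resolve_all("Small, primarily fixed defect and a mild, reversible defect")
  cats <- vapply(r$modifiers, `[[`, character(1), "category")
  expect_true("FIXED" %in% cats)
  expect_true("TERMINATE" %in% cats)
  expect_true("REVERSIBLE" %in% cats)
  fx <- mod_by_cat(r$modifiers, "FIXED")[[1]]
  expect_equal(fx$span$text, "primarily fixed")

  expect_length(resolve_all("Normal perfusion")$modifiers, 0)
})

test_that("forward scopes stop at terminators, limits, and sentence end", {
  txt <- "Small, primarily fixed defect and a mild, reversible defect"
  r <- resolve_all(txt)
  fx <- mod_by_cat(r$modifiers, "FIXED")[[1]]
  and_tok <- which(r$tokens$norm == "and")
  expect_true(all(fx$scope_tokens < and_tok))
  # the first "defect" is governed, the second escapes
  defects <- which(r$tokens$norm == "defect")
  expect_true(defects[1] %in% fx$scope_tokens)
  expect_false(defects[2] %in% fx$scope_tokens)

  txt <- "Large perfusion defect without evidence of reversibility"
  r <- resolve_all(txt)
  neg <- mod_by_cat(r$modifiers, "NEGATED_EXISTENCE")[[1]]
  expect_true(which(r$tokens$norm == "reversibility") %in% neg$scope_tokens)

  # sentence-final forward modifier has an empty scope
  tk <- tokenize("defect is fixed")
  mods <- resolve_scopes(match_modifiers(tk, rb_default$contexts),
                         tk)
  fx <- mod_by_cat(mods, "FIXED")[[1]]
  expect_length(fx$scope_tokens, 0)
  expect_equal(fx$scope$start, fx$scope$end)

  # max_scope_tokens truncates
  rb <- rulebook(contexts = list(
    context_rule("c", "no", "NEGATED_EXISTENCE", "FORWARD",
                 max_scope_tokens = 2)))
  tk <- tokenize("no a b c d")
  mods <- resolve_scopes(match_modifiers(tk, rb$contexts), tk)
  expect_equal(mods[[1]]$scope_tokens, 2:3)
})

test_that("backward and bidirectional scopes are symmetric", {
  txt <- "Moderate size, mildly reduced counts in anterior wall which is reversible"
  r <- resolve_all(txt)
  rev <- mod_by_cat(r$modifiers, "REVERSIBLE")[[1]]
  expect_equal(rev$span$text, "which is reversible")
  expect_true(all(rev$scope_tokens < rev$token_start))
  expect_true(all(which(r$tokens$norm %in% c("reduced", "counts")) %in%
                    rev$scope_tokens))

  rb <- rulebook(contexts = list(
    context_rule("c", "likely", "UNCERTAIN", "BIDIRECTIONAL", 2),
    context_rule("t", "and", "TERMINATE")))
  tk <- tokenize("a b likely c d")
  mods <- resolve_scopes(match_modifiers(tk, rb$contexts), tk)
  expect_equal(mods[[1]]$scope_tokens, c(1, 2, 4, 5))
})

test_that("scope containment invariants hold on resolved modifiers", {
  txts <- c(reference_phrases()$phrase, replicate(50, random_sentence()))
  for (txt in txts) {
    r <- resolve_all(txt)
    n <- nrow(r$tokens)
    for (m in r$modifiers) {
      if (m$category == "TERMINATE") next
      expect_true(all(m$scope_tokens >= 1 & m$scope_tokens <= n))
      if (m$direction == "FORWARD" && length(m$scope_tokens))
        expect_gte(m$scope$start, m$span$end)
      if (m$direction == "BACKWARD" && length(m$scope_tokens))
        expect_lte(m$scope$end, m$span$start)
    }
  }
})

test_that("context application sets the documented attributes", {
  run <- function(txt) {
    tk <- tokenize(txt)
    targets <- match_targets(tk, 1L, rb_default$targets, source = txt)
    mods <- resolve_scopes(match_modifiers(tk, rb_default$contexts,
                                           source = txt), tk, source = txt)
    apply_context(targets, mods)
  }
  m <- run("There is a small area of fixed ischemia")
  expect_true(m[[1]]$attributes$is_fixed)
  expect_false(m[[1]]$attributes$is_negated)

  m <- run("Moderate size, mildly reduced counts in anterior wall which is reversible")
  expect_true(m[[1]]$attributes$has_reversible_modifier)

  m <- run("Small perfusion abnormality is favored to be artifactual")
  expect_true(m[[1]]$attributes$is_artifact)
  expect_true(m[[1]]$attributes$is_uncertain)

  # no modifiers: identity
  m <- run("Moderate area of reversibility")
  expect_false(any(unlist(m[[1]]$attributes)))
})

test_that("a reversible cue binds an adjacent perfusion finding without scope", {
  rb <- rulebook(
    targets = list(target_rule("t", "defect", "PERFUSION_FINDING")),
    contexts = list(context_rule("c", "reversible", "REVERSIBLE", "BACKWARD",
                                 max_scope_tokens = 1)))
  tk <- tokenize("reversible defect")
  targets <- match_targets(tk, 1L, rb$targets)
  mods <- resolve_scopes(match_modifiers(tk, rb$contexts), tk)
  # BACKWARD scope cannot reach the following token, adjacency still binds
  got <- apply_context(targets, mods)
  expect_true(got[[1]]$attributes$has_reversible_modifier)
})

test_that("inserting a terminator between modifier and target removes its effect", {
  set.seed(47)
  rb <- property_rulebook()
  for (case in 1:100) {
    gap <- paste(sample(c("mild", "wall", "area"), sample(0:2, 1),
                        replace = TRUE), collapse = " ")
    plain <- trimws(paste("no", gap, "ischemia"))
    cut <- trimws(paste("no", gap, "but ischemia"))
    eval_flags <- function(txt) {
      tk <- tokenize(txt)
      tg <- match_targets(tk, 1L, rb$targets, source = txt)
      md <- resolve_scopes(match_modifiers(tk, rb$contexts, source = txt),
                           tk, source = txt)
      isch <- Filter(function(m) m$category == "ISCHEMIA_TERM",
                     apply_context(tg, md))
      vapply(isch, function(m) m$attributes$is_negated, logical(1))
    }
    base <- eval_flags(plain)
    if (length(base) && any(base))
      expect_false(any(eval_flags(cut)), info = cut)
  }
})

test_that("attribute assignment matches the brute-force oracle on random sentences", {
  set.seed(53)
  rb <- property_rulebook()
  for (case in 1:1500)
    expect_true(context_case_agrees(random_sentence(), rb))
})
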