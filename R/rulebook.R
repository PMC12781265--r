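#' Rule constructors
#'
#' Rules are the auditable unit of the pipeline. Patterns are case-insensitive
#' token-sequence literals — a pattern like `"negative for"` matches the two
#' consecutive tokens `negative`, `for` regardless of case or surrounding
#' punctuation — with `"*"` available as a single-token wildcard. Full regular
#' expressions are deliberately not supported so that rule files remain
#' readable by clinicians.
#'
#' Three rule classes exist:
#' \describe{
#'   \item{target}{identifies a clinical concept mention (an ischemia term, a
#'     reversibility term, or a perfusion finding).}
#'   \item{context}{a modifier cue (negation, fixed, artifact, reversible,
#'     hedge, or scope terminator) with a direction and a token-scope limit.}
#'   \item{section}{a report header (IMPRESSION, FINDINGS, ...) matched at
#'     line start, tolerant of case and a trailing colon or dash.}
#' }
#'
#' @param rule_id Unique identifier string.
#' @param pattern Non-empty token-sequence pattern.
#' @param category Closed-set category (see Details above).
#' @param direction One of `"FORWARD"`, `"BACKWARD"`, `"BIDIRECTIONAL"`;
#'   ignored (and stored as `NA`) for `TERMINATE` rules, which cut scopes
#'   rather than carry one.
#' @param max_scope_tokens Positive integer limit on how many tokens the
#'   modifier's scope may extend in each direction, or `Inf` for
#'   unlimited-within-sentence. Default 10: impressions are telegraphic, and a
#'   bounded scope prevents a cue early in a run-on sentence from governing
#'   findings in a different clause.
#' @param header_pattern Literal line-initial header text.
#' @param section_category Section label, e.g. `"IMPRESSION"`.
#' @return A rule object (a classed list).
#' @seealso [rulebook()], [default_ischemia_rulebook()]
#' @export
target_rule <- function(rule_id, pattern, category) {
  validate_rule_common(rule_id, pattern)
  if (!category %in% TARGET_CATEGORIES)
    stop("target rule '", rule_id, "': unknown category '", category,
         "' (must be one of ", paste(TARGET_CATEGORIES, collapse = ", "), ")",
         call. = FALSE)
  structure(list(rule_id = rule_id, pattern = pattern, category = category),
            class = "target_rule")
}

#' @rdname target_rule
#' @export
context_rule <- function(rule_id, pattern, category, direction = NULL,
                         max_scope_tokens = 10) {
  validate_rule_common(rule_id, pattern)
  if (!category %in% MODIFIER_CATEGORIES)
    stop("context rule '", rule_id, "': unknown category '", category,
         "' (must be one of ", paste(MODIFIER_CATEGORIES, collapse = ", "), ")",
         call. = FALSE)
  if (category == "TERMINATE") {
    direction <- NA_character_
  } else {
    if (is.null(direction) || !direction %in% MODIFIER_DIRECTIONS)
      stop("context rule '", rule_id, "': direction must be one of ",
           paste(MODIFIER_DIRECTIONS, collapse = ", "), call. = FALSE)
  }
  if (!is.infinite(max_scope_tokens) &&
      (!is.numeric(max_scope_tokens) || max_scope_tokens < 1))
    stop("context rule '", rule_id,
         "': max_scope_tokens must be a positive integer or Inf", call. = FALSE)
  structure(list(rule_id = rule_id, pattern = pattern, category = category,
                 direction = direction,
                 max_scope_tokens = as.numeric(max_scope_tokens)),
            class = "context_rule")
}

#' @rdname target_rule
#' @export
section_rule <- function(rule_id, header_pattern, section_category) {
  validate_rule_common(rule_id, header_pattern, field = "header_pattern")
  if (!nzchar(section_category))
    stop("section rule '", rule_id, "': empty section_category", call. = FALSE)
  structure(list(rule_id = rule_id, header_pattern = header_pattern,
                 section_category = section_category),
            class = "section_rule")
}

validate_rule_common <- function(rule_id, pattern, field = "pattern") {
  if (!is.character(rule_id) || length(rule_id) != 1L || !nzchar(rule_id))
    stop("rule_id must be a non-empty string", call. = FALSE)
  if (!is.character(pattern) || length(pattern) != 1L || !nzchar(trimws(pattern)))
    stop("rule '", rule_id, "': empty ", field, call. = FALSE)
}

#' Assemble a rulebook
#'
#' A rulebook bundles target, context and section rules with name/version
#' metadata. All `rule_id`s must be globally unique across the three lists.
#'
#' @param targets List of [target_rule()] objects.
#' @param contexts List of [context_rule()] objects.
#' @param sections List of [section_rule()] objects.
#' @param name,version Metadata strings.
#' @return An object of class `"rulebook"`.
#' @export
rulebook <- function(targets = list(), contexts = list(), sections = list(),
                     name = "unnamed", version = "0") {
  stopifnot(all(vapply(targets, inherits, logical(1), "target_rule")),
            all(vapply(contexts, inherits, logical(1), "context_rule")),
            all(vapply(sections, inherits, logical(1), "section_rule")))
  ids <- c(vapply(targets, `[[`, character(1), "rule_id"),
           vapply(contexts, `[[`, character(1), "rule_id"),
           vapply(sections, `[[`, character(1), "rule_id"))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate rule_id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  structure(list(name = name, version = version, targets = targets,
                 contexts = contexts, sections = sections),
            class = "rulebook")
}

#' @export
print.rulebook <- function(x, ...) {
  cat(sprintf("<rulebook '%s' v%s: %d target, %d context, %d section rules>\n",
              x$name, x$version, length(x$targets), length(x$contexts),
              length(x$sections)))
  invisible(x)
}

#' @export
summary.rulebook <- function(object, ...) {
  tc <- table(vapply(object$targets, `[[`, character(1), "category"))
  cc <- table(vapply(object$contexts, `[[`, character(1), "category"))
  print(object)
  cat("target categories: ", paste(names(tc), tc, sep = "=", collapse = ", "), "\n")
  cat("context categories:", paste(names(cc), cc, sep = "=", collapse = ", "), "\n")
  invisible(object)
}

KNOWN_RULE_FIELDS <- list(
  targets = c("rule_id", "pattern", "category"),
  contexts = c("rule_id", "pattern", "category", "direction", "max_scope_tokens"),
  sections = c("rule_id", "header_pattern", "section_category"))

#' Load a rulebook from a JSON file
#'
#' The file format is a single JSON object with keys `"targets"`, `"contexts"`
#' and `"sections"` (each a list of rule objects) plus optional `"name"` and
#' `"version"`. A context rule's `max_scope_tokens` may be a positive integer
#' or the string `"unlimited"`. Unknown fields on a rule are ignored with a
#' warning, so rule files from richer ecosystems remain loadable; schema
#' violations (unknown category or direction, empty pattern, duplicate ids)
#' are errors naming the offending rule.
#'
#' @param path Path to a JSON rule file.
#' @return A validated [rulebook()].
#' @examples
#' rb <- default_ischemia_rulebook()
#' f <- tempfile(fileext = ".json")
#' save_rulebook(rb, f)
#' identical(load_rulebook(f), rb)
#' @export
load_rulebook <- function(path) {
  if (!file.exists(path)) stop("rule file not found: ", path, call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.list(raw)) stop("rule file is not a JSON object: ", path, call. = FALSE)
  get_field <- function(rule, field, id) {
    if (is.null(rule[[field]]))
      stop("rule '", id, "': missing required field '", field, "'",
           call. = FALSE)
    rule[[field]]
  }
  parse_rules <- function(kind, build) {
    lapply(raw[[kind]], function(r) {
      id <- if (is.null(r$rule_id)) "<missing rule_id>" else r$rule_id
      extra <- setdiff(names(r), KNOWN_RULE_FIELDS[[kind]])
      if (length(extra))
        warning("rule '", id, "': ignoring unknown field(s) ",
                paste(extra, collapse = ", "), call. = FALSE)
      build(r, get_field(r, "rule_id", id))
    })
  }
  targets <- parse_rules("targets", function(r, id)
    target_rule(id, get_field(r, "pattern", id), get_field(r, "category", id)))
  contexts <- parse_rules("contexts", function(r, id) {
    mst <- r$max_scope_tokens
    mst <- if (is.null(mst)) 10 else if (identical(mst, "unlimited")) Inf else mst
    context_rule(id, get_field(r, "pattern", id), get_field(r, "category", id),
                 direction = r$direction, max_scope_tokens = mst)
  })
  sections <- parse_rules("sections", function(r, id)
    section_rule(id, get_field(r, "header_pattern", id),
                 get_field(r, "section_category", id)))
  rulebook(targets, contexts, sections,
           name = if (is.null(raw$name)) "unnamed" else raw$name,
           version = if (is.null(raw$version)) "0" else as.character(raw$version))
}

#' Save a rulebook to a JSON file
#'
#' Writes the format read by [load_rulebook()]; the round trip is lossless.
#'
#' @param rb A [rulebook()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_rulebook <- function(rb, path) {
  stopifnot(inherits(rb, "rulebook"))
  strip <- function(rule) {
    r <- unclass(rule)
    if (!is.null(r$direction) && is.na(r$direction)) r$direction <- NULL
    if (!is.null(r$max_scope_tokens) && is.infinite(r$max_scope_tokens))
      r$max_scope_tokens <- "unlimited"
    r
  }
  obj <- list(name = rb$name, version = rb$version,
              targets = lapply(rb$targets, strip),
              contexts = lapply(rb$contexts, strip),
              sections = lapply(rb$sections, strip))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' The built-in ischemia rulebook
#'
#' The default rulebook for nuclear stress test impressions. Target rules
#' cover direct ischemia terms, reversibility terms (a reversible defect is
#' the textual hallmark of ischemia), and bare perfusion findings (which are
#' only positive evidence when a reversibility cue attaches to them). Context
#' rules cover negation ("negative for", "no evidence of", ...), fixed-defect
#' cues (scar, not ischemia), artifact attributions ("attenuation artifact",
#' "resolves on prone imaging"), reversibility cues, hedges ("likely",
#' "favored to be" — which do not refute), and the conjunction terminators
#' "and"/"but" that cut modifier scopes at clause boundaries. Section rules
#' recognize the common report headers.
#'
#' @return A [rulebook()]; the same object on every call.
#' @examples
#' rb <- default_ischemia_rulebook()
#' summary(rb)
#' @export
default_ischemia_rulebook <- function() {
  tr <- function(id, pat, cat) target_rule(id, pat, cat)
  cr <- function(id, pat, cat, dir = NULL, mst = 10)
    context_rule(id, pat, cat, dir, mst)
  sr <- function(id, pat, cat) section_rule(id, pat, cat)
  rulebook(
    name = "ischemia-default", version = "1.0",
    targets = list(
      tr("t-ischemia",            "ischemia",            "ISCHEMIA_TERM"),
      tr("t-reversible-ischemia", "reversible ischemia", "ISCHEMIA_TERM"),
      tr("t-reversibility",       "reversibility",       "REVERSIBILITY_TERM"),
      tr("t-reversible-defect",   "reversible defect",   "REVERSIBILITY_TERM"),
      tr("t-reversible-defects",  "reversible defects",  "REVERSIBILITY_TERM"),
      tr("t-perf-defect",         "perfusion defect",    "PERFUSION_FINDING"),
      tr("t-perf-defects",        "perfusion defects",   "PERFUSION_FINDING"),
      tr("t-perf-abnormality",    "perfusion abnormality", "PERFUSION_FINDING"),
      tr("t-perf-abnormalities",  "perfusion abnormalities", "PERFUSION_FINDING"),
      tr("t-reduced-counts",      "reduced counts",      "PERFUSION_FINDING")),
    contexts = list(
      cr("c-negative-for", "negative for",        "NEGATED_EXISTENCE", "FORWARD"),
      cr("c-no-evidence",  "no evidence of",      "NEGATED_EXISTENCE", "FORWARD"),
      cr("c-wo-evidence",  "without evidence of", "NEGATED_EXISTENCE", "FORWARD"),
      cr("c-without",      "without",             "NEGATED_EXISTENCE", "FORWARD"),
      cr("c-no",           "no",                  "NEGATED_EXISTENCE", "FORWARD"),
      cr("c-negative",     "negative",            "NEGATED_EXISTENCE", "FORWARD"),
      cr("c-fixed",        "fixed",               "FIXED",    "FORWARD"),
      cr("c-prim-fixed",   "primarily fixed",     "FIXED",    "FORWARD"),
      cr("c-artifact",     "artifact",            "ARTIFACT", "BIDIRECTIONAL"),
      cr("c-artifactual",  "artifactual",         "ARTIFACT", "BACKWARD"),
      cr("c-atten-artifact", "attenuation artifact", "ARTIFACT", "BACKWARD"),
      cr("c-prone",        "resolves on prone imaging", "ARTIFACT", "BACKWARD"),
      cr("c-reversible",   "reversible",          "REVERSIBLE", "FORWARD"),
      cr("c-part-reversible", "partially reversible", "REVERSIBLE", "FORWARD"),
      cr("c-which-reversible", "which is reversible", "REVERSIBLE", "BACKWARD"),
      cr("c-likely",       "likely",              "UNCERTAIN", "FORWARD"),
      cr("c-favored",      "favored to be",       "UNCERTAIN", "BIDIRECTIONAL"),
      cr("c-and",          "and",                 "TERMINATE"),
      cr("c-but",          "but",                 "TERMINATE")),
    sections = list(
      sr("s-impression", "IMPRESSION", "IMPRESSION"),
      sr("s-findings",   "FINDINGS",   "FINDINGS"),
      sr("s-indication", "INDICATION", "INDICATION"),
      sr("s-technique",  "TECHNIQUE",  "TECHNIQUE"),
      sr("s-history",    "HISTORY",    "HISTORY"),
      sr("s-comparison", "COMPARISON", "COMPARISON")))
}
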