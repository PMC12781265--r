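---
title: "Rule-based classification of myocardial ischemia from stress test reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based classification of myocardial ischemia from stress test reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stressnlp)
```

## The task and the model

A nuclear stress test images myocardial radiotracer uptake at rest and under
stress. Its report's impression states, in free text, whether a perfusion
defect is *reversible* (present at stress, resolving at rest — the hallmark
of ischemia), *fixed* (present in both — scar, not ischemia), or an
*attenuation artifact* (tissue blocking signal, not pathology). One report
may describe several myocardial territories with different results;
clinically, ischemia in any territory makes the study positive.

`stressnlp` models this reading process with three deterministic layers:

1. **Target matching.** Case-insensitive token-sequence rules mark mentions
   of three concept classes: `ISCHEMIA_TERM` ("ischemia"),
   `REVERSIBILITY_TERM` ("reversibility", "reversible defect"), and
   `PERFUSION_FINDING` ("perfusion defect", "reduced counts"). A bare
   perfusion finding is not itself evidence of ischemia.
2. **Context scoping.** Modifier rules mark cues of six classes —
   `NEGATED_EXISTENCE`, `FIXED`, `ARTIFACT`, `REVERSIBLE`, `UNCERTAIN`, and
   `TERMINATE` — each (except `TERMINATE`) with a direction and a token
   budget. A cue governs a window of tokens on its forward, backward, or
   both sides; the window is cut by the sentence boundary, by the nearest
   `TERMINATE` marker (the conjunctions "and"/"but"), and by the rule's
   `max_scope_tokens`. Targets inside a cue's window receive the matching
   attribute flag. This is the ConText family of algorithms, specialized to
   perfusion reporting.
3. **Polarity and aggregation.** A mention is positive iff it carries
   positive evidence (ischemia/reversibility category, or a perfusion
   finding bound to a `REVERSIBLE` cue) and no refuting flag (`is_negated`,
   `is_fixed`, `is_artifact`). Hedges never refute: "likely ischemia" is
   positive — a hedged positive still triggers clinical follow-up, and the
   operational cost of missing ischemia exceeds that of a false alert. The
   document is positive iff any mention is positive.

The any-positive disjunction is the package's reading of "positive weighted
more highly than negative": the observable contract is binary, and a strict
disjunction satisfies every behavioral example we encode, including the
mixed sentence "Small, primarily fixed defect and a mild, reversible
defect", where the terminator "and" confines the fixed cue to the first
clause and the reversible second clause decides the document.

```{r}
classify_document(report_document(
  "ex1", "Small, primarily fixed defect and a mild, reversible defect"))
```

## The default rulebook

The shipped rulebook (`default_ischemia_rulebook()`, also serialized at
`inst/extdata/ischemia_rulebook.json`) is authored to be behavior-complete
on a canonical set of thirteen example phrases covering hedged positives,
negated and fixed findings, artifact attributions, and multi-clause
sentences (`reference_phrases()`); those phrases double as its regression
contract (`cmd_validate_rules()`). Rule counts are deliberately small —
10 target, 19 context, 6 section rules — and every pattern is a literal
token sequence (with `*` as a single-token wildcard), not a regular
expression, so a clinician can audit the whole file.

Direction choices worth noting:

* `fixed` is a **forward** refuting cue ("fixed ischemia" is scar).
* artifact cues are **backward** ("... consistent with attenuation
  artifact" trails its finding); the bare token `artifact` is bidirectional.
* `which is reversible` is **backward** — it is a relative clause attaching
  to the finding before it.
* `favored to be` is a bidirectional hedge: it precedes its complement but
  describes the finding before it.
* A `REVERSIBLE` cue immediately adjacent to a `PERFUSION_FINDING`
  ("reversible defect" when "defect" alone is the target) binds it even if
  scope arithmetic would not reach — the cue is syntactically the head
  noun's modifier.

When `FIXED` and `REVERSIBLE` cues both reach one mention, refutation wins
(the mention is not positive); with `options(stressnlp.verbose = TRUE)` the
classifier logs such conflicts by report id.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `max_scope_tokens` (per context rule) | 10 tokens | how far a cue reaches in each allowed direction; `Inf` = to the sentence boundary. Ten tokens spans a typical impression clause without letting a sentence-initial "no" govern an entire run-on sentence. |
| text-selection `policy` | `IMPRESSION_THEN_FULL_IMPRESSION_SECTION` | impressions are less prone to false positives, so they are always preferred; the fallback extracts the IMPRESSION section from the full report when the impression field is empty (common in warehouse extracts) and is recorded in the provenance tag. `IMPRESSION_ONLY` reproduces the reference configuration exactly. |
| `decimals` in `compute_metrics()` | 1 | rounding is **half-up** (87.45 → 87.5), the convention of printed diagnostic tables; base R's round-half-even would disagree on boundary values. F1 is computed from unrounded precision/recall, then rounded. |

## Text layer conventions

Offsets are 0-based, half-open. Sentences break at newline runs and at
`.?!` followed by whitespace and an uppercase letter or digit; enumerated
markers ("1.") never end a sentence, so numbered impressions survive.
Tokenization splits on whitespace and detaches `,.;:()/`; it is lossless
(inter-token gaps are pure whitespace), which makes span arithmetic exact.
Section headers match at line start, case-insensitively, tolerating a
trailing colon or dash — multi-site corpora are heterogeneous in exactly
this way. These segmentation rules are this package's own fixed convention:
impressions are short and telegraphic, and a deterministic splitter keeps
every classification reproducible and auditable.

Overlapping rule matches resolve longest-first, then leftmost, then by rule
order; this prevents "ischemia" from shadowing "reversible ischemia", which
matters because modifiers attach to whole mentions. The matcher is verified
against a brute-force enumeration oracle on randomized sentences, and the
scope engine against a per-pair membership oracle (10,000 randomized
sentences of at most 12 tokens in the acceptance suite).

## The synthetic corpus

No clinical data ships with (or is needed by) the package. The generator
(`generate_corpus()`) emulates impressions built from phrase templates:
the thirteen canonical phrases verbatim, plus parameterized templates with
`{size}` and `{territory}` slots covering reversible and fixed defects,
artifact attributions, negations, and neutral boilerplate (ejection
fraction, wall motion, comparison lines). Positive reports contain at least
one positive sentence plus up to three negative/neutral distractors — so
every generated positive exercises multi-territory aggregation — and
negative reports contain only negative/neutral sentences. Site boilerplate
(one of five variants) is prepended, and a configurable fraction of reports
also carry a sectioned full report whose IMPRESSION equals the impression
text, exercising the sectionizer fallback.

Design choices:

* **Exact prevalences.** The positive count is `round(n × prevalence)`
  (half-up), not a per-document coin flip, so split prevalences are testable
  as equalities. The benchmark splits are 440 documents at 17% (75
  positives), 115 at 43% (49), and 99 at 43% (43) — 654 in total, 67%
  training share. The validation/test pool's higher prevalence reflects
  enrichment for suspected positives in the reference annotation protocol.
* **Noise as coverage gaps.** `noise_fraction` draws documents from
  out-of-coverage paraphrases — a positive phrased as "stress induced
  hypoperfusion ... suggestive of flow limitation" (a miss) or an unrefuted
  historical mention of ischemia (a false alarm). This emulates the error
  *mechanism* of a rules system (lexical coverage), not any particular error
  *rate*. The default is 0.
* **Determinism.** A corpus is a pure function of its `corpus_spec`
  (including the seed); generation saves and restores the caller's RNG
  state.

What passing tests on this corpus do and do not show: with
`noise_fraction = 0` the classifier is 100% accurate **by construction** —
that is a self-consistency check of pipeline, rulebook, and generator, not
an estimate of performance on real reports. Real-world accuracy depends on
lexical coverage of each site's reporting style, which synthetic templates
cannot measure. The reproducible performance claims are therefore of a
different kind: the five evaluation metrics recomputed from the published
test-set confusion matrices (e.g. rules-based precision 88.1%, recall
97.4%, F1 92.5% over 99 reports), which `scripts/acceptance.R` re-derives
from the printed integer cells.

## Numerical and degenerate-input choices

* Zero denominators in metrics yield `NA`, never 0 — a silent zero would
  corrupt model comparisons.
* Documents with no target mentions classify negative with an empty
  evidence excerpt: absence of documented ischemia is a negative screen.
* A document with neither impression nor usable full text is an error
  carrying its `report_id`; in batch mode errors are aggregated in the run
  summary (and fatal only under `strict`), because one malformed row must
  not abort a million-document batch.
* A forward cue at sentence end has an empty scope (zero-length span at the
  cue boundary); empty input text yields zero sentences and zero tokens.
* Evidence excerpts are formatted `"span text [CATEGORY; modifiers: ...]"`
  joined by `" | "` — bit-stable, so regression tests can compare them
  exactly.

## Problem sizes in the test suite

The shipped suite verifies the scope engine against its brute-force oracle
on 10,000 randomized sentences, label-faithfulness on a noise-free corpus
of 1,000 documents, and the benchmark split structure at full size
(440/115/99); unit tests use smaller replicates of the same properties.
These sizes give the randomized properties broad coverage while keeping the
whole suite fast enough to run on every change.

## Known limitations

* **Single-sentence scope.** "This defect is reversible" referring to a
  defect in a previous sentence is not linked — standard ConText behavior;
  cross-sentence anaphora is out of scope.
* **No severity, territory, or function extraction.** The output is the
  binary indicator plus evidence; per-vessel sub-labels, defect size
  grading, and ejection fraction are non-goals.
* **Lexical coverage is the accuracy ceiling.** New phrasings require new
  rules; `cmd_validate_rules()` guards edits against the canonical phrase
  set, but coverage of a new site's lexicon must be audited on that site's
  text.
* **No spelling correction or abbreviation expansion**; patterns match
  surface tokens only.
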