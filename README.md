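# stressnlp

Rule-based NLP classification of myocardial ischemia status from nuclear
cardiac stress test reports.

## The problem

Whether a patient has non-invasive evidence of myocardial ischemia — the
key prerequisite for appropriate invasive coronary angiography — is usually
buried in the free-text impression of a nuclear stress test report rather
than stored in a discrete data field. Quality-of-care programs that monitor
procedure appropriateness across a large, multi-site health system need that
binary fact extracted automatically, auditably, and at warehouse scale.

`stressnlp` implements a deterministic, clinician-auditable pipeline for
that task: a target matcher finds mentions of ischemia terms, reversibility
terms, and perfusion findings; a ConText-style engine attaches directional
modifiers (negation, fixed-defect, artifact, reversibility, hedges) with
token-bounded, terminator-cut scopes; and a document-level aggregator turns
mention polarities into one binary indicator. The package also ships the
evaluation machinery (confusion matrices and the five standard metrics) and
a gold-labeled synthetic report corpus generator, so the whole pipeline is
testable end to end without access to any clinical data.

## The decision rule

For each target mention *t* with context attributes applied:

    POSITIVE(t)  ⇔  [ category(t) ∈ {ISCHEMIA_TERM, REVERSIBILITY_TERM}
                      ∨ has_reversible_modifier(t) ]
                    ∧ ¬( is_negated(t) ∨ is_fixed(t) ∨ is_artifact(t) )

Hedges (`is_uncertain`) never change the outcome — "likely ischemia" is
positive. The document is positive iff **any** mention is positive: ischemia
in one myocardial territory makes the report positive no matter how many
other territories are negative. Evaluation uses the standard cells
a (TP), b (FP), c (FN), d (TN):

    sensitivity = a/(a+c)   specificity = d/(b+d)   precision = a/(a+b)
    NPV = d/(c+d)           F1 = 2·P·R/(P+R)   (from unrounded P, R)

## Worked example

```r
library(stressnlp)

doc <- report_document("r-0001", paste(
  "Fixed perfusion defect in the inferior wall.",
  "Small reversible defect in the anterior wall.", sep = "\n"))
res <- classify_document(doc)
res
#> <classification r-0001: ischemia=1 (impression)>
#>   evidence: reversible defect [REVERSIBILITY_TERM; modifiers: c-reversible]

classify_document(report_document("r-0002",
  "Negative for reversible ischemia"))$ischemia
#> [1] 0

m <- compute_metrics(confusion_matrix(a = 37, b = 5, c = 1, d = 56))
m
#> <metrics over 99 documents>
#>   Sensitivity/Recall         97.4%
#>   Specificity                91.8%
#>   Precision/PPV              88.1%
#>   Negative Predictive Value  98.2%
#>   F1                         92.5%
```

The first report is positive: the fixed inferior defect is scar and is
refuted, but the reversible anterior defect is positive evidence, and any
positive territory makes the document positive. The second is negative:
"negative for" scopes forward over the ischemia mention.

Synthetic corpora with exact prevalences:

```r
splits <- generate_benchmark_splits(seed = 7)
lengths(splits)
#>      train validation       test
#>        440        115         99
```

### Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "stressnlp", package = "stressnlp"))')
Rscript "$CLI" generate --output-prefix corpus --benchmark --seed 7
Rscript "$CLI" classify --input corpus-test.jsonl --output preds.jsonl
Rscript "$CLI" evaluate --predictions preds.jsonl --gold corpus-test.jsonl
Rscript "$CLI" validate-rules --rulebook inst/extdata/ischemia_rulebook.json
```

## Documentation

The methods vignette (`vignettes/rules-based-ischemia-classification.Rmd`)
describes the pipeline's model and assumptions, the default rulebook, the
scope-resolution semantics, what the synthetic corpus does and does not
emulate, and known limitations.
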