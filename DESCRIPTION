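Package: stressnlp
Title: Rule-Based Classification of Myocardial Ischemia from Cardiac Stress Test Reports
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A deterministic, auditable natural language processing pipeline that
    classifies nuclear cardiac stress test report impressions as positive or
    negative for myocardial ischemia. Implements token-sequence target matching,
    ConText-style directional modifier scoping with termination, report
    sectionization, document-level label aggregation, confusion-matrix evaluation
    metrics, and a gold-labeled synthetic report corpus generator, together with
    a command-line front end for batch classification and evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    caret,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
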