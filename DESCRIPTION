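Package: acidep
Title: Acidic Extracellular pH Dependency Scoring for Tumor Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how much a tumor type's prognosis depends on
    acidosis-responsive genes. Implements a fold-change differential
    expression pipeline for two-condition-versus-control expression
    experiments (mild and severe extracellular acidosis versus
    physiological pH), Venn partitioning of condition-specific gene sets,
    2x2 contingency comparison of acid-modulated genes against external
    expression signatures, rank-order signature concordance, and a
    prognostic "hit" score over top-ranked acid-induced and acid-reduced
    genes with strict and inversion-tolerant tallies. A synthetic-data
    generator with planted ground truth stands in for deposited microarray
    data and database annotations so every stage can be benchmarked
    offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
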