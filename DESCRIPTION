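Package: mircons
Title: miRNA Differential Expression, Consensus Target Prioritization and
    CRE Promoter Scanning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An in-silico pipeline for small-RNA profiling studies of murine
    allergic airway inflammation: two-colour array differential expression
    with normexp background correction, robust-spline within-array
    normalization, between-array scaling and an empirical-Bayes moderated
    t-statistic; delta-delta-Ct quantification and nonparametric statistics
    for qPCR data; seed-match miRNA target-site detection with k-of-n
    consensus over multiple predictors and binding-site-count
    prioritization; and exact-string scanning of promoters for the
    palindromic CRE element (TGACGTCA). Ships a synthetic-data generator
    that emulates every input with known ground truth so the whole pipeline
    is testable end-to-end without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    splines,
    MASS,
    Biostrings,
    yaml
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
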