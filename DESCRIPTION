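Package: ekaryotypeR
Title: Expression-Based Karyotyping and Tumor Cohort Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers chromosomal copy-number alterations from bulk RNA-seq
    expression profiles (e-karyotyping): genes are ordered along the genome,
    expression is centered on a panel of normal reference samples, winsorized,
    and segmented by an exact penalized piecewise-constant fit solved by
    dynamic programming, with gain/loss calls subject to deviation, size and
    significance rules. Also provides nearest-centroid molecular subtype
    assignment by Spearman correlation (PAM50-style, including "mixed" calls),
    epithelial-mesenchymal-transition sum scores, complete-linkage expression
    clustering, two-sided Fisher co-occurrence tests for paired gene
    perturbations, Kaplan-Meier curves and log-rank comparisons across
    perturbation groups, and a fully synthetic cohort generator (planted
    copy-number events, subtype signatures, perturbation tables and grouped
    exponential survival) so every stage is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
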