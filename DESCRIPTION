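Package: cccr
Title: Clustermatch Correlation Coefficient for Mixed-Type Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the Clustermatch Correlation Coefficient (CCC), a
    clustering-based association statistic that detects both linear and
    nonlinear relationships between numerical and/or categorical features.
    Features are internally clustered (quantile partitions over a sweep of
    cluster counts for numerical features, category-defined partitions for
    categorical ones) and the coefficient is the clamped maximum Adjusted
    Rand Index over all partition-pair combinations. Includes a batched,
    globally-indexed ARI execution engine with a memory-budgeted batch
    planner and deterministic reduction, permutation p-values, Pearson and
    Spearman baselines with percentile-tier intersection (UpSet-style)
    analysis to surface nonlinear gene pairs, gene-metadata association,
    a synthetic data generator reproducing canonical nonlinear expression
    motifs, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    parallel,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
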