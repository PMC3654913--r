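Package: omdr
Title: Ordinal Multifactor Dimensionality Reduction for Gene-Gene
    Interaction Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects gene-gene interactions (epistasis) affecting ordinal
    categorical phenotypes via ordinal multifactor dimensionality reduction
    (OMDR). Multi-locus genotype cells are collapsed to predicted ordinal
    classes by a per-genotype odds-ratio rule, classifiers are scored with
    Kendall's tau-b on the true-versus-predicted confusion matrix, and a
    generalized cross-validation consistency statistic (GCVC) based on
    top-K selection reports multiple best interactions.  Includes an
    exhaustive and staged combination search, an odds-ratio-driven
    genotype/phenotype simulator under Hardy-Weinberg equilibrium for
    power studies, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
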