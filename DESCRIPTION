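Package: syndromap
Title: Topological Syndromic Mapping of Multivariate Clinical Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds syndromic maps of heterogeneous clinical cohorts with a
    Mapper (reeb-graph) pipeline: patients are compared with a
    norm-correlation distance over standardized common data elements,
    projected onto a two-coordinate multidimensional-scaling lens by stress
    majorization, and grouped through an equalized overlapping cover with
    per-bin single-linkage clustering. Graph regions can be tested for
    variable and genotype enrichment (Kolmogorov-Smirnov, chi-square, Fisher,
    Benjamini-Hochberg), and candidate genotypes are confirmed with a
    two-timepoint repeated-measures factorial general linear model using
    Type III sums of squares and Tukey-Kramer posthoc comparisons. Includes
    a synthetic traumatic-brain-injury cohort generator with a plantable
    low-recovery subgroup for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    car,
    readxl,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
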