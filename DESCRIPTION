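Package: groupRR
Title: Random Regression Genetic Evaluation from Repeated Group Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and pedigree-based mixed-model analysis of longitudinal
    feed-intake phenotypes recorded at the pen (group) level. Simulates a
    multi-generation pig population with first-order Legendre polynomial
    additive-genetic and permanent-environment curves, allocates animals to
    pens under alternative grouping designs, applies random or
    phenotype-dependent drop out, and fits random regression models to either
    individual records or per-pen summed records. Variance components are
    estimated by average-information REML with an EM fallback on sparse mixed
    model equations (inverse numerator relationship matrix with inbreeding);
    breeding values are obtained by BLUP and validated by the accuracy and
    bias of a whole-trajectory selection index.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
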