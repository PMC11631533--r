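Package: pcblup
Title: Fast Multitrait Genetic Evaluation via Principal Components and Univariate BLUP
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Approximates full multivariate pedigree-based genetic evaluation by
    transforming an individuals-by-traits phenotype matrix into orthogonal
    principal components, fitting an independent univariate REML/BLUP animal
    model to each component, and back-transforming component breeding values to
    the original trait scale. Includes pedigree parsing with inbreeding and
    sparse inverse of the additive relationship matrix, SVD-based and Bayesian
    (model-based) PCA with missing-data imputation, EM and average-information
    REML, staged multitrait REML (univariate starts, pairwise bivariate
    covariances, fixed-component multitrait BLUP), selection indices, and rank
    concordance statistics, plus a synthetic-data generator emulating forest
    tree breeding trials.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
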