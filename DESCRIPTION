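Package: canalax
Title: Canalization and Taylor Approximability of Boolean Network Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how canalization in Boolean update rules shapes
    how well synchronous Boolean network dynamics are approximated by low-order
    continuous Taylor polynomials. Provides truth-table algebra (bias, essential
    variables, average sensitivity), canalizing-depth and layer-structure
    decomposition of Boolean functions with matching random generators (exact
    depth, minimal depth, nested canalizing with prescribed layers), the unique
    multilinear extension of a Boolean function and its Taylor truncations, the
    mean approximation error (MAE) between a Boolean network and its clipped
    continuous approximation, exact and sampled attractor analysis, constrained
    null-model generators that preserve degree, bias and/or canalizing depth of
    a reference network, random N-K Kauffman ensembles, and a tidy analysis
    layer (predictor tables, Spearman screens, paired Wilcoxon comparisons,
    LASSO regularization paths).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
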