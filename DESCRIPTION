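Package: nbid
Title: Negative Binomial Modeling and Differential Expression for UMI Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical modeling of unique molecular identifier (UMI) counts
    from single-cell RNA sequencing. Fits Poisson, negative binomial (NB), and
    zero-inflated negative binomial (ZINB) distributions per gene; performs
    backward model selection with boundary likelihood-ratio tests; runs binned
    chi-square goodness-of-fit tests on depth-equalized (down-sampled) counts;
    and tests differential expression with NBID, a negative binomial regression
    with per-cell size-factor offsets, optional covariates, and independent
    per-group dispersions. Includes a semi-synthetic simulation framework
    (gene-swap differential expression, UMI thinning, batch-confounded designs)
    and FDR / precision-recall evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix,
    MASS,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
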