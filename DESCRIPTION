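Package: netlatent
Title: Comparing Gaussian Graphical and Latent Variable Models of a
    Covariance Matrix
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits Gaussian graphical (partial-correlation network) models
    and confirmatory factor models (correlated factors, second-order g,
    bifactor, and multi-general-factor variants) to the same observed
    covariance or correlation matrix by maximum likelihood, so the two
    model families can be compared on identical data. Provides
    significance pruning of the saturated partial-correlation matrix,
    cross-sample network replication (extract on one sample, confirm on
    another), local identification checking via the rank of the Jacobian
    of the implied-covariance map, standard errors with explicit
    singularity diagnosis, the standard SEM fit-index set (chi-square,
    CFI, TLI, RMSEA with noncentral chi-square confidence interval, AIC,
    BIC) with qualitative fit labels, model-comparison tables, shipped
    WAIS-IV model templates, and a synthetic-data generator for
    population networks and factor structures with finite-sample
    multivariate normal sampling.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
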