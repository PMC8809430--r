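Package: countssm
Title: Bayesian State-Space Models for Effort-Adjusted Count Surveys
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits Bayesian state-space models to monthly, multi-site count
    surveys of the kind used to index relative abundance of vultures and
    other raptors. The latent log-abundance follows a random walk with
    drift; observed counts are Poisson with survey effort as a scaled and
    centered covariate and log-normal extra-Poisson observation noise, so
    process and observation error are separated. Inference is by adaptive
    Metropolis-within-Gibbs MCMC with Gelman-Rubin convergence checks and
    an observation/process error-ratio adequacy diagnostic. Includes a
    synthetic-data generator matching the survey design, posterior
    relative-abundance summaries (per species, per site, and per-draw
    cross-species totals), and exact questionnaire statistics (two-tailed
    Fisher test for 2x2 tables, Kruskal-Wallis rank test with tie
    correction).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
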