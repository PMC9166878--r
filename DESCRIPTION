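Package: carelessRT
Title: Response-Time-Based Mixture Modeling of Careless and Insufficient
    Effort Responding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detection and modeling of careless and insufficient effort
    responding (C/IER) in computer-administered questionnaires using item-
    or screen-level response times. Implements a latent response mixture
    model combining a generalized partial credit model with lognormal
    response times under a distance-difficulty effect for attentive
    behavior, and content-free category probabilities with a common
    lognormal response-time distribution for C/IER. Includes Bayesian
    estimation by adaptive Markov chain Monte Carlo with the discrete
    attentiveness indicators marginalized, posterior attentiveness
    classification, a fully synthetic data generator with four C/IER
    response patterns, aggregated timing measures (TT, FRT, TTFRT, AAT)
    with response-time trimming, and classical indicator-based screening
    (long string, even-odd consistency, Mahalanobis distance, multiple
    hurdle).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
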