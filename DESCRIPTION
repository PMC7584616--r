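Package: cgmtbr
Title: Uncertainty and Duration Planning for CGM Time-in-Range Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Closed-form prediction of the sampling uncertainty of
    time-below-range (TBR) and related continuous glucose monitoring (CGM)
    metrics under an AR(1) model of the dichotomized glucose process.
    Provides the standard deviation of the TBR estimation error as a
    function of recording length, a finite-trial correction for the
    tail effect that arises when the true hypoglycemia probability is
    replaced by the whole-trial estimate, trial-duration planning,
    per-subject estimation of the process parameters from CGM traces via
    sample autocovariance and weighted nonlinear least squares, a
    two-state Markov-chain simulator of correlated Bernoulli hypoglycemia
    processes, and sliding-window empirical error analysis for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
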