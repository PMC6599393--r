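Package: brainstates
Title: Latent Brain-State Dynamics from Parcellated Resting-State Time Series
Version: 0.1.0
Authors@R:
    person("ADHD Dynamics", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Per-group Gaussian-emission hidden Markov models for parcellated
    resting-state fMRI time series, with cross-group latent-state alignment by
    k-means on state mean-activation maps, state-switching metrics (fractional
    occupancy, empirical transition probabilities, inter-transition intervals,
    number of transitions, outlier screening), factorial sex-by-diagnosis
    inference with partial eta squared and Cohen's d, and a fully synthetic
    multi-group cohort generator with known ground truth so that every stage of
    the pipeline is testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
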