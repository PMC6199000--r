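Package: seizurepath
Title: Effective-Connectivity Seizure Pathways via Neural Mass Model Inversion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tracks time-varying effective connectivity during epileptic
    seizures by inverting a Jansen-Rit neural mass model against ECoG with an
    assumed-density (Kalman) filter that propagates Gaussian beliefs through
    the erf firing-rate sigmoid in closed form. Includes the surrounding
    analysis pipeline: seizure segment extraction and zero-phase filtering,
    sliding-window signal energy, log-duration bimodality detection by
    k-means and Gaussian mixtures under the gap statistic, baseline-normalized
    parameter trajectories with per-time significance, long/short seizure
    contrasts, and duration-connectivity correlations with Bonferroni
    correction. A synthetic-data module generates ground-truth seizure
    catalogs and model-based ECoG so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    signal,
    mclust,
    cluster,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
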