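Package: emergeEEG
Title: Spectral and Entropy Analysis of EEG State Transitions During
    Anesthesia Emergence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing single-channel frontal EEG around
    behaviourally verified loss and return of responsiveness (LOR/ROR)
    under general anaesthesia. Provides windowed Welch power spectral
    density and density spectral arrays (DSA), band-power trends,
    Bandt-Pompe permutation entropy, a transparent 0-100 depth-of-
    anaesthesia index built from spectral log-energy ratios and the burst
    suppression ratio, paired transition statistics (Wilcoxon signed
    rank, dependent-samples Hedges' g, bootstrap AUC confidence
    intervals), pixel-wise AUC maps with cluster-based reporting,
    Kruskal-Wallis with Dunn's post-hoc comparisons, the Freeman-Halton
    exact test for r x c contingency tables, and a seeded synthetic EEG
    cohort generator emulating substance-specific emergence spectral
    trajectories so the whole pipeline is testable without clinical
    recordings.
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
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
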