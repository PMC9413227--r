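Package: meaevoked
Title: Spontaneous and Stimulus-Evoked Activity Analysis for Micro-Electrode Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for extracellular recordings of cultured
    neuronal networks on 120-electrode micro-electrode arrays (MEAs).
    Implements precise-timing spike detection on raw voltage traces with a
    noise-adaptive differential threshold, string-method burst detection,
    spontaneous activity metrics (mean firing rate, mean bursting rate, burst
    duration) with an active-electrode filter, post-stimulus time histograms
    (PSTHs) with responsiveness filtering and area normalization, and an
    early/late evoked-response classifier based on k-means clustering of PSTH
    profiles with silhouette model selection, dual-peak detection on smoothed
    class means, and a peak-separation statistic. Includes nonparametric group
    comparisons (Kruskal-Wallis with Kolmogorov-Smirnov normality screening)
    and a seeded synthetic-data generator emulating three-compartment
    cortical-like and hippocampal-like networks with full ground truth, so
    every stage of the pipeline is testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    cluster,
    jsonlite,
    nortest,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
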