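Package: pseudosort
Title: Self-Supervised Spike Sorting with Density-Based Pseudolabels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spike sorting for single-channel extracellular recordings built
    around self-supervised contrastive pretraining of a fully connected
    encoder, k-nearest-neighbor density estimation in the learned latent
    space, density-guided pseudolabel sampling with K-means++ and
    elbow-method cluster-count estimation, and iterative semi-supervised
    fine-tuning. Includes a seeded synthetic-recording generator emulating
    the statistics of single-electrode benchmark datasets, spike detection
    and waveform preprocessing (bandpass filtering, robust noise estimation,
    threshold detection, alignment, min-max normalization, gradient
    features), evaluation utilities (optimally matched accuracy, a PCA
    Gaussian-mixture baseline sorter, SNR-binned scoring), and post-sort
    unit quality metrics (full width at half maximum, refractory-period
    violation rates, firing-rate change).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    mclust,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
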