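Package: dfcstab
Title: Temporal Stability of Dynamic Functional Connectivity Subspaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised characterization of the temporal stability of
    dynamic functional connectivity (dFC) from parcellated BOLD fMRI time
    series. Computes instantaneous phase-coherence dFC via the analytic
    signal (with a nonoverlapping Gaussian-windowed correlation alternative),
    reduces each timepoint to its dominant low-rank eigen-subspace, and
    quantifies between-timepoint stability with principal angles and
    Mahalanobis distances assembled into time-by-time stability matrices.
    Stability matrices are summarized by histogram entropy and Frobenius
    distances, their lag-1 time courses are characterized as autoregressive
    processes with AIC-based order selection, and group-level lifespan
    analyses (age-cohort binning, Wilcoxon comparisons with normality
    diagnostics, quadratic-in-age regression) are provided together with a
    regime-switching synthetic BOLD generator that supplies ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
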