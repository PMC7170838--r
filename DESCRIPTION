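Package: praawave
Title: Corneal Waveform Biomechanics and Retinal Deformation via
    Variational-Autoencoder Denoising and AICc Model Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links Ocular Response Analyzer (ORA) corneal applanation
    waveforms to the peripapillary retinal arteries angle (PRAA).
    Provides a seeded generator of synthetic bimodal applanation
    cohorts with planted ground truth, waveform table input/output with
    quality-index filtering and triplicate averaging, detection of the
    two applanation peaks, the Monot1-2 retrogressive-movement
    statistic together with a documented surrogate set of classical
    waveform descriptors, a small variational autoencoder
    (400-40-20-2) for waveform denoising and latent-space traversal,
    and a two-step predictor selection procedure: Lasso screening to 20
    candidates followed by exhaustive best-subset search under the
    second-order bias-corrected Akaike information criterion, with
    nested-model ANOVA comparison. A pipeline orchestrates all stages
    from a single seeded configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
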