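Package: gsmv1
Title: Gaussian Scale Mixture Inference and Spike-Count Variability in V1
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a Gaussian scale mixture (GSM) generative model of
    primary visual cortex inputs in which trial-to-trial neuronal variability
    encodes posterior uncertainty under sampling-based inference. Provides the
    oriented quadrature filter bank defining the model receptive field and
    surround, moment-matched model training, exact scalar-mixer posterior
    inference (grid marginalization plus conditional Gaussian sampling),
    spike-count readouts and simulated experiments (mean-variance scans, size
    tuning, surround-orientation tuning), a spike-count analysis pipeline for
    trial-aligned recordings (latency estimation, inclusion criteria, Fano
    factors, mean matching, bootstrap confidence intervals), and a
    gain-modulated Poisson generator of surrogate recordings with known
    ground-truth Fano factors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
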