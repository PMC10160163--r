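Package: cineflowr
Title: Intra-Cardiac Blood-Flow Velocity Prediction from Long-Axis Cine MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts in-plane intra-cardiac blood-flow velocity fields from
    multi-phase long-axis cine magnetic resonance image sequences using a
    deeply-supervised residual U-Net trained against 4D-flow-derived pixel
    displacement fields. Includes intensity normalization over the pooled
    blood-pool histogram, velocity/displacement unit conversion, trilinear
    projection of volumetric velocities onto an imaging plane, masked
    end-point-error losses, patient-level k-fold cross-validation,
    quantitative evaluation metrics (end-point error, angle error, relative
    error, time-curve correlation, velocity histograms, threshold sweeps),
    automated E/A-ratio estimation with diastolic-function classification and
    agreement statistics, a synthetic cine-phantom generator with exactly
    known flow fields, and vector-overlay visualization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    grDevices,
    tibble,
    ggplot2,
    rlang,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
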