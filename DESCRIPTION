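Package: seqactivate
Title: Sequential Probability Ratio Tests for Real-Time fMRI Activation
    Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Voxel-wise sequential analysis of functional MRI time series.
    Implements streaming generalized least squares estimation of the
    general linear model, one- and two-sided truncated sequential
    probability ratio tests (SPRT) on contrasts of task coefficients with
    Bonferroni-adjusted stopping boundaries, a global stopping rule across
    a region of interest, a fixed-design GLM benchmark with false
    discovery rate control, a synthetic BOLD data generator with
    multi-component noise, causal real-time preprocessing (spatial
    smoothing and drift correction), and a halving algorithm for adaptive
    selection of task difficulty levels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
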