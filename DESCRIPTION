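Package: boldcv
Title: Fluctuation-Amplitude (CV) Mapping of Resting-State BOLD Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes per-voxel coefficient-of-variation (CV) maps of resting-state
    BOLD fMRI time series, with nuisance removal (motion-parameter regression,
    first-order detrending, RETROICOR physiological correction from cardiac and
    respiratory recordings), frequency-band decomposition of the fluctuation
    amplitude, partial-volume-weighted / strict-threshold / template tissue
    aggregation, and exact Wilcoxon rank-sum cohort comparison. Includes a
    synthetic 4D BOLD phantom generator with ground-truth intrinsic CV,
    physiological waveforms and scanner drift for end-to-end validation of the
    pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    rlang,
    zoo,
    yaml,
    jsonlite,
    withr,
    generics,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
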