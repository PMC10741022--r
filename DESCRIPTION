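Package: stamcube
Title: Spatio-Temporal Associative Memory Classification with Spiking Neural Cubes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies multichannel spatio-temporal recordings (EEG- or
    fMRI-like sample sets) with a brain-inspired spiking pipeline: real-valued
    time series are encoded into ternary spike trains (step-forward encoding),
    learned unsupervised in a 3D spiking reservoir with small-world
    connectivity and spike-timing-dependent plasticity, and classified by a
    dynamic evolving spiking classifier using rank-order coding and
    nearest-neighbour recall. The trained model acts as a spatio-temporal
    associative memory: it can be recalled on truncated time windows or a
    subset of input variables, and the retained memory accuracy of such
    partial recalls is quantified against the full model. Includes synthetic
    EEG-like and fMRI-like data generators, two-class signal-to-noise-ratio
    variable selection, and connectivity-based biomarker profiling of trained
    reservoirs.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
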