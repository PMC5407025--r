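Package: vsoptrack
Title: MRI Quantification of Iron-Oxide Labelled Stem Cells in Rodent Stroke
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies very small superparamagnetic iron oxide (VSOP) labelled
    stem cells and ischaemic lesions in longitudinal rodent brain MRI. Implements
    the hemisphere cell-signal-intensity asymmetry statistic (delta-CSI, the
    root-sum-of-squares of per-hemisphere coefficients of variation), infarct
    volumetry with interslice-gap interpolation, and a T2*-weighted speckle
    re-analysis (median-filter residual, local Wiener denoising, mean + 2 SD
    thresholding and histogram-based hypointense selection) that isolates
    cell-derived hypointense voxels. Ships a synthetic brain-phantom generator
    with ground-truth lesions, speckles, bias fields, noise and rigid
    inter-session misalignment so the whole pipeline is testable end to end,
    plus preprocessing (polynomial bias-field correction, brain extraction,
    mean-1000 normalisation, rigid registration) and exact Mann-Whitney group
    comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
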