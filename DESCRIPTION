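Package: utedce
Title: Sliding-Window Radial UTE DCE-MRI Reconstruction and Model-Free
    Enhancement Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dynamic contrast-enhanced (DCE) lung MRI with radial
    ultra-short echo time (UTE) acquisitions: tiny-golden-angle radial
    trajectories with ramp density compensation, Kaiser-Bessel gridding and
    wavelet-regularised iterative (FISTA) reconstruction, sliding-window
    dynamic frame assembly, model-free relative-enhancement analysis with
    background-drift correction and seven-class enhancement binning, digital
    dynamic rat-lung phantoms with an exact nonuniform-DFT k-space simulator,
    and histology tissue-fraction morphometry with SNR quality control.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    RNifti,
    Rcpp,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
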