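Package: cestrecon
Title: Dense CEST Z-Spectrum Reconstruction from Sparse Frequency Offsets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs dense chemical exchange saturation transfer (CEST)
    Z-spectra (101 frequency offsets) from sparse acquisitions (11 offsets).
    Provides a 7-pool Bloch-McConnell simulator under continuous-wave
    saturation to generate paired training data, five sequence-to-sequence
    reconstruction models (RNN, LSTM, GRU, TCN, TCN-LSTM) trained with
    backpropagation, a multi-pool Lorentzian fitting baseline, pixel-wise
    reconstruction of CEST image stacks, digital phantom generation, and an
    evaluation suite (absolute error modulus, pooled regression, SSIM, PSNR).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    RNifti,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
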