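Package: wedgefill
Title: Self-Supervised Denoising and Missing-Wedge Reconstruction for
    Cryo-Electron Tomograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Reconstructs denoised, missing-wedge-filled tomograms from
    single-axis cryo-electron tomography tilt series. The tilt series is
    split into two halves with independent noise, each half is
    reconstructed with filtered back-projection, and a 3D U-Net is fitted
    on overlapping sub-tomogram pairs with a self-supervised Fourier-masked
    loss that combines Noise2Noise denoising with Noisier2Noise-style
    inpainting of an artificially added second wedge. The fitted network
    is then applied to both half-reconstructions and the results averaged.
    Includes a parallel-beam tilt-series simulator (phantoms, projections,
    controlled-SNR Gaussian noise), wedge-mask machinery, sub-tomogram
    extraction and reassembly, evaluation metrics (correlation
    coefficients, Fourier shell correlation and 0.143-cutoff resolution,
    inside and outside the wedge), MRC and .tlt input/output, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
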