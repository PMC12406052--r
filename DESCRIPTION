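Package: ksim
Title: Shot-by-Shot k-Space Simulation, Reconstruction and Evaluation for 3D fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A modular 3D+time functional MRI simulator that generates raw
    multicoil k-space data shot by shot from a digital brain phantom via an
    extended Fourier acquisition model (tissue-wise T2* decay, off-resonance
    interpolators, BOLD contrast modulation between shots, calibrated thermal
    noise), together with frame-wise image reconstruction (density-compensated
    adjoint and wavelet-l1 compressed sensing with SURE-tuned regularization)
    and a GLM-based activation-detection scoring pipeline, so that any
    combination of acquisition and reconstruction strategy can be evaluated
    against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
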