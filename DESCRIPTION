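Package: speckleMAP
Title: Homomorphic Bayesian MAP Speckle Denoising and Image Optimization
    for MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulation and removal of multiplicative Rayleigh speckle in
    grayscale magnetic-resonance images.  Provides anatomy-like synthetic
    phantoms, a seeded speckle/additive noise generator, homomorphic
    (log-domain) separation, a per-pixel Bayesian maximum-a-posteriori
    shrinkage denoiser built on Rayleigh noise and signal densities, a
    weighted low-resolution observation model with least-squares
    reconstruction, residual-based image enhancement, between-class
    variance threshold segmentation with gradient edge detection,
    reference-based SNR and SSIM quality metrics, and the two-group
    clinical statistics (summary t-tests, 2x2 chi-square and Fisher
    tests, scale-direction interpretation for UPDRS/MoCA/MMSE) used to
    evaluate deep-brain-stimulation outcomes in Parkinson's disease.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    MASS,
    png,
    RNifti,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
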