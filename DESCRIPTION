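Package: gipret
Title: Phase Retrieval for Grating-Interferometry Phase-Stepping Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of Talbot-Lau grating-interferometer
    phase-stepping acquisitions. Provides the forward sinusoidal stepping
    model with mechanical stepping error and Poisson noise, closed-form
    per-pixel harmonic least-squares fitting, extraction of transmission,
    differential phase contrast (DPCI) and dark-field images, and four
    routes from the DPCI to the integrated phase-contrast image (PCI):
    direct one-dimensional integration, wavelet-Fourier destriping,
    ADMM minimisation of a total-variation plus air-mask regularised
    objective, and a self-supervised dual-stream convolutional network
    trained Noise2Noise-style on DPCI pairs fitted from random subsets
    of the phase-stepping frames. Includes synthetic phantom generators,
    PSNR/SSIM evaluation, TIFF stack input/output and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils,
    tools,
    tiff,
    png,
    yaml,
    jsonlite,
    optparse
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage
Config/testthat/edition: 3
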