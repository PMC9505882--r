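Package: ldctlab
Title: Low-Dose CT Denoising Laboratory with Sinogram-Domain Noise
    Simulation and Stacked U-Net Denoisers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end laboratory for studying low-dose computed
    tomography (CT) denoising on synthetic chest phantoms. Provides a
    physics-based low-dose simulator that inserts Poisson photon noise in
    the sinogram domain (parallel-beam Radon transform, Beer-Lambert
    attenuation with a bowtie beam-shaping profile, reduced incident flux,
    log conversion, filtered back-projection); a zoo of encoder-decoder
    convolutional denoisers built around a stacked modified U-Net with
    constant filter counts, stride-2 convolutional contraction and
    transpose-convolution decoders, together with U-Net, SegNet-like,
    DeConvNet-like and RedNet comparators; classical baselines (Gaussian
    smoothing, non-local means, and a simplified two-stage BM3D-style
    collaborative filter); a CPU training engine (Adam, staircase
    learning-rate decay, RMSE loss, best-validation checkpointing); and a
    full evaluation protocol with RMSE, PSNR, SSIM, the blind NIQE quality
    score, improvement scoring, noise-level-binned comparisons and noise
    masks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    EBImage,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
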