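Package: shearTGV
Title: Multiplicative Noise Removal and Deblurring with Second-Order TGV and
    Shearlet Regularization
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Joint removal of multiplicative (speckle) noise and blur from
    2-D grayscale and RGB images by minimizing a convex energy that combines
    a Gamma maximum-a-posteriori log/quadratic data fidelity with a
    second-order total generalized variation (TGV2) penalty and an l1 penalty
    on band-limited shearlet coefficients. The energy is minimized by an
    alternating direction method of multipliers (ADMM) in which every linear
    subproblem is diagonal in the Fourier domain. Includes a synthetic
    degradation simulator (MATLAB fspecial-style point spread functions,
    mean-one Gamma/Rayleigh/Gaussian noise fields, Shepp-Logan phantom and
    piecewise-polynomial test images), the restoration quality metrics PSNR,
    global SSIM, relative error and SNR, cross-channel (RGB) deblurring, and
    lossless PNG/TIFF image input and output.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, png, tiff, tools, utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'ImageGrid-methods.R'
    'degrade.R'
    'metrics.R'
    'shearlet.R'
    'tgv.R'
    'shrink.R'
    'solver.R'
    'multichannel.R'
    'io.R'
    'utils.R'
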