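# shearTGV

Joint multiplicative-noise (speckle) removal and non-blind deblurring for
2-D grayscale and RGB images, for people working with coherent imaging
data — ultrasound, SAR, laser, or any setting where the observation is

    f = (H u) · η ,

with `H` a known blur operator and `η` a mean-one noise field (Gamma with
`L` looks, Rayleigh, or clipped Gaussian). The restoration minimizes the
convex energy

    E(u, p) = ⟨log(Hu), 1⟩ + ⟨f/(Hu), 1⟩ + α‖Hu/f − 1‖₂²
            + λ Σ_j ‖SH_j(u)‖₁ + γ₁‖∇u − p‖₁ + γ₀‖ε̄(p)‖₁ ,

a Gamma maximum-a-posteriori fidelity with a convexifying quadratic
(coercive for α ≥ 26/9), an ℓ¹ penalty on the bands of a band-limited
(Meyer-window, Parseval) shearlet frame, and second-order total
generalized variation (TGV²) carried with its auxiliary vector field `p`.
The minimization is an ADMM in which every shrinkage is closed-form, the
pointwise fidelity prox is a damped Newton iteration, and the joint
`(u, p)` update is an exact per-frequency Hermitian 3×3 solve — all linear
algebra is diagonal in the Fourier domain thanks to periodic boundaries.

The package is self-contained for experimentation: it ships a degradation
simulator (MATLAB `fspecial`-style PSFs, seeded mean-one noise fields, the
Shepp–Logan phantom and piecewise-polynomial fixtures), the quality
metrics PSNR / global SSIM / RelErr / SNR, a cross-channel (RGB)
deblurring extension, lossless PNG/TIFF I/O, and a small CLI
(`inst/cli/shearTGV.R`).

## Worked example

```r
library(shearTGV)

u   <- makeTestImage("phantom", n = 256)            # clean, [0, 255]
psf <- makePsf("identity")
d   <- degradeImage(u, psf, noiseSpec("gamma", L = 10, seed = 1))
psnr(d$image, u)
#> [1] 22.27099

cfg <- presetConfig("denoise_L10")$config            # tuned benchmark preset
res <- admmRestore(d$image, psf, cfg)
res
#> RestorationResult: stopped at iteration cap after 500 iterations
#> ImageGrid: 256 x 256, 1 channel, gray scale [0, 255]
#>   intensity range [0.255, 255], mean 30.42

psnr(restoredImage(res), u)
#> [1] 28.67571
ssimGlobal(restoredImage(res), u)
#> [1] 0.9836012
relErr(restoredImage(res), u)
#> [1] 0.02232428
```

The degraded phantom comes in around 22.3 dB; the preset restoration
raises it by about 6.4 dB while keeping the phantom's edges sharp. (Exact
restored values move by a tenth of a dB or so with the noise seed.)
`solverHistory(res)` exposes the per-iteration energy, the primal
residuals of the three constraint groups, and the relative change used
for stopping. Deblurring works the same way — build the true kernel with
`makePsf("motion", length = 5, angle = 30)` or
`makePsf("gaussian", hsize = 7, sigma = 2)` and hand it to
`admmRestore()`; RGB images with cross-channel blur go through
`makeCrossChannelBlur()` and `restoreMultichannel()`.

A word on tuning: on the [0, 255] scale the ℓ¹ thresholds remove roughly
`lambda/mu1` gray levels of coefficient energy per iteration, so the
iteration count (useful range about 100–700) is itself a tuning parameter
of the method alongside `lambda` ∈ [1.5, 10]; the methods vignette
(`vignettes/shearTGV-methods.Rmd`) discusses why, and documents every
default.

## Benchmark suites

`runExperimentSuite("table4")` and `runExperimentSuite("table5")`
regenerate the phantom benchmarks (speckle at L = 10 / L = 6; motion and
Gaussian blur followed by L = 10 speckle) and emit CSV/Markdown reports;
`runExperimentSuite("multichannel")` runs the RGB stack under the
nine-kernel cross-channel recipe. Classic photograph benchmarks (Lena,
Cameraman, Rice, Parrot, ...) are not redistributable and are not
regenerated; users supplying those images at 256² should expect results
within about 1 dB of published values using the same presets.

## Command line

```sh
Rscript inst/cli/shearTGV.R degrade --input phantom --n 256 \
    --noise gamma --looks 10 --seed 1 --out degraded.png
Rscript inst/cli/shearTGV.R restore --input phantom --blur motion \
    --length 5 --angle 30 --seed 1 --outdir out/
Rscript inst/cli/shearTGV.R metrics --input out/run_restored.png \
    --reference clean.png
Rscript inst/cli/shearTGV.R suite --name table4 --outdir reports/
```
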