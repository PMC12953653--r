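# psf4d

Physics-guided image restoration for a liquid-lens continuous-zoom
microscope, in R.

An electrowetting liquid lens changes focal length with voltage, letting a
microscope zoom continuously (here across a 10x-100x band) instead of
switching objectives — but the blur of such a system drifts with
magnification, position in the field of view, and wavelength. `psf4d`
implements the full pipeline for dealing with that: it simulates the
system's four-dimensionally indexed point spread function (PSF) bank
(zoom level x field row x field column x wavelength) from a Zernike pupil
model, degrades phantom specimens through it to build paired training data,
and restores degraded images with a learnable Wiener front end plus a small
degradation-guided attention network trained under a physics-constrained
loss. It is aimed at computational-imaging researchers who want a fully
inspectable, CPU-scale reference implementation of PSF-aware restoration.

## The model in brief

**Optics.** Liquid-lens focal length follows the Young-Lippmann relation

    f(U) = -D (n_c - n_n) / [cos(theta0) + eps*eps0*U^2 / (2*H*gamma)]

so optical power is affine in the squared voltage, and the two-group zoom
magnification with fixed working distance `u` and group separation `d` is

    beta = (1 - Phi_f*u)^-1 * [1 + Phi_c*(Phi_f + 1/u)^-1 - Phi_f*d]^-1.

**Restoration.** The front end is a channel-wise learnable Wiener filter,
diagonalized in the Fourier domain:

    xhat_c = F^H [ conj(D_K) F y_c / (|D_K|^2 + e^alpha_c * sum_d |D_Gd|^2) ]

with a tanh-bounded learnable correction of the PSF spectrum `D_K`, a
content-predicted bank of eight zero-mean regularization kernels `G_d`, and
one log-strength `alpha_c` per color channel. A three-scale encoder-decoder
of degradation-guided transformer blocks (channel-transposed attention whose
keys are modulated by PSF-derived features) refines the result and upsamples
2x; training minimizes

    w_fid*MSE(xhat, x) + w_phys*MSE(Down2(xhat (*) K), y)
      + w_ssim*(1 - MSSSIM(xhat, x)) + w_tv*TV(xhat)

where the physics term re-degrades the restoration through the *identical*
spatially-variant blur + downsampling operator that generated the data. All
learnable parts run on the package's own reverse-mode autodiff tape
(`ag_*` operators), finite-difference-verified in the test suite.

## Worked example

```r
library(psf4d)

# 1. zoom trajectory: solve group powers for six magnifications
zoom_table(10.6, 101.4, 6)
#> # A tibble: 6 x 3
#>    beta power_front power_rear
#>   <dbl>       <dbl>      <dbl>
#> 1  10.6        5.74       3.37
#> 2  16.7        5.88       2.81
#> 3  26.2        6.02       2.67
#> 4  41.1        6.16       2.82
#> 5  64.5        6.31       3.15
#> 6 101.         6.45       3.61

# 2. a desk-scale 4D PSF dictionary (6 x 8 field cells, 3 wavelengths)
dict <- build_dictionary(zoom_levels = c(10, 60, 100),
                         sensor_shape = c(512L, 384L), patch_size = 64L)
dict
#> 4D PSF dictionary: 3 zoom level(s) x 6 x 8 field cells x 3 wavelength(s)
#>   zoom levels: 10, 60, 100
#>   wavelengths (um): 0.486, 0.588, 0.656
#>   kernel 33 x 33 px at 3.45 um/px

# 3. degrade a phantom and restore it
gt <- generate_specimen(1, size = 128, style = "cells")
sample <- degrade(gt, dict, beta = 60, sigma = 6, seed = 2)
params <- list(calw = calw_init(), net = dgnet_init(network_config("tiny")))
restored <- restore_image(sample$input_y, sample$psf_set, params)
psnr(restored, sample$gt_x)                     # physically-seeded restoration
#> [1] 19.34397
psnr(resize_bicubic(sample$input_y, 128, 128), sample$gt_x)  # naive baseline
#> [1] 18.28745
```

Even before any training, the Wiener front end (seeded with the true PSF)
restores 1-2 dB above bicubic upsampling; training the tiny profile for a
few epochs improves the composite loss further and adds the attention
refinement. `evaluate_model()` produces the per-magnification PSNR/SSIM
table for the full model, the Wiener-only path, and the bicubic baseline.

A command-line front end wrapping these functions lives at
`inst/cli/psf4d.R` (subcommands `zoomtable`, `build-dict`, `simulate`,
`restore`, `train`, `eval`).

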