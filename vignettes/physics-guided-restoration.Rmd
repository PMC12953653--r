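---
title: "Physics-guided restoration for a liquid-lens continuous-zoom microscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physics-guided restoration for a liquid-lens continuous-zoom microscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(psf4d)
```

## The problem

An electrowetting liquid lens changes focal length with applied voltage, so a
microscope built around liquid-lens zoom groups can sweep magnification
continuously instead of switching objectives. The price is optics: the blur
of such a system varies with the zoom state, with position in the field of
view, and with wavelength. A single deconvolution kernel cannot describe it.
`psf4d` models the blur as a four-dimensionally indexed family of point
spread functions (PSFs) — magnification x field row x field column x
wavelength — and uses that family three ways: to synthesize realistic
degraded/clean training pairs, to seed a closed-form learnable Wiener
restoration, and to constrain a small attention-based restoration network
through a physics-consistency loss.

## Optics model

Two relations anchor the optical side.

**Liquid-lens focal length (Young–Lippmann).** For conductive/non-conductive
liquid indices $n_c, n_n$, zero-voltage contact angle $\theta_0$, dielectric
constant $\varepsilon$, vacuum permittivity $\varepsilon_0$, dielectric
thickness $H$, interfacial tension $\gamma$, and aperture $D$:

$$f(U) = \frac{-D\,(n_c - n_n)}{\cos\theta_0 + \varepsilon\varepsilon_0 U^2 / (2H\gamma)}.$$

Optical power $1/f$ is affine in $U^2$; `focal_length()` and
`optical_power()` implement this and error out at the voltage where the
power crosses zero.

**Two-group zoom magnification.** With front/rear group powers
$\Phi_f, \Phi_c$, working distance $u$ and group separation $d$ (both held
constant while zooming):

$$\beta = (1 - \Phi_f u)^{-1}\,\bigl[1 + \Phi_c(\Phi_f + u^{-1})^{-1} - \Phi_f d\bigr]^{-1}.$$

The pair $(\Phi_f, \Phi_c)$ is under-determined for a target $\beta$, and no
reference power split exists for the trajectory, so `solve_powers()` fixes
the front power by a schedule linear in $\log\beta$ (5 to 6.5 D across the
band) and solves the rear power by bracketed root finding. Because the rear
bracket has a pole in $\Phi_c$, every sign change on a scan is tried and a
candidate root is accepted only if it reproduces the target magnification to
1e-6 relative. The default geometry ($u = 0.05$ m, $d = 0.174$ m) was chosen
once so that the whole 10x–100x band is reachable with rear powers inside
the -5 to +10 D range of the liquid lenses; `relay_offset` is carried as
metadata for the aberration schedule only, since $u$ and $d$ are fixed
during zooming.

## PSF simulation

Ray tracing through a real lens prescription is replaced by a parametric
Zernike pupil model (`pupil_model()`): a circular pupil carries a phase
$2\pi \sum_j c_j Z_j$ with Noll terms Z4 (defocus), Z5/Z6 (astigmatism),
Z7/Z8 (coma) and Z11 (spherical). Coefficients vary smoothly over the field
(defocus and astigmatism with the square of the normalized field radius,
coma linearly, spherical constant) and are scaled by a per-magnification
severity factor (0.4 at 10x rising to 1.2 at 100x), reproducing the
qualitative structure of zoom aberrations without claiming any particular
prescription. Chromatic defocus offsets (+0.25, 0, -0.25 waves) distinguish
the three wavelengths 0.486, 0.588 and 0.656 um (F/d/C lines, mapped to the
blue/green/red channels).

`render_psf()` evaluates the pupil on an FFT grid whose pupil radius in
frequency samples is `NA / lambda * n_pad * pixel_um`, with the image-plane
sampling fixed at 3.45 um (the sensor pitch). The intensity PSF is the
squared modulus of the pupil transform, cropped to a 33 x 33 kernel and
normalized to unit sum. Numerical choices worth knowing:

* the default embedding is 256 x 256; the default NA schedule
  (0.03–0.05 image-side) keeps the pupil radius between roughly 45 and
  110 samples;
* the 33-pixel crop captures 80–95 % of the diffracted energy for the
  default aberration ranges (Airy rings beyond the crop account for most of
  the remainder); the captured fraction is recorded per kernel in
  `dict$energy` and validated to exceed 0.75, and the crop is renormalized
  so the forward model conserves flux exactly;
* the fixed-plane peak (Strehl) decreases with any single aberration
  coefficient only within the quarter-wave regime; beyond that it is
  legitimately non-monotone, which is why the monotonicity check in the
  test suite ladders coefficients to 0.25 waves.

`build_dictionary()` renders all (level, row, col, wavelength) combinations
— 48 field cells (6 x 8 for a 2048 x 1536 sensor in 256-pixel patches)
times three wavelengths per zoom state — and `save_dictionary()` persists
the 6-D kernel array with its metadata attributes in HDF5.
`psf_lookup()` maps a sensor pixel to its half-open 256-pixel tile and
returns the stored kernel of the nearest zoom level (ties toward the lower
level); kernels are never interpolated between levels because interpolation
is not energy-preserving — re-render through the pupil model instead.

## Synthetic data

No public captures exist for this instrument, so the training data is
synthesized end to end. `generate_specimen()` draws one of four phantom
styles: band-limited correlated-color noise ("texture", with a smooth tanh
range compression so that no pixel mass sits exactly at the intensity
bounds and additive noise almost never clips), dart-thrown elliptical cells
with membranes and nuclei on a bright field ("cells"), sinusoidal gratings
of known frequency, and resolution-chart bar triplets whose periods follow
the standard $2^{1/6}$ ladder ("usaf").

`degrade()` follows the dataset recipe exactly in this order: (1)
spatially-variant blur — the frame is tiled by the dictionary's field
cells, each tile convolved with its own kernel using mirrored margins and
linear overlap-add ramps across a 32-pixel overlap so kernel seams are
smooth; (2) additive Gaussian noise with standard deviation
$\sigma \in [2, 10]$ on the 8-bit scale; (3) 2x downsampling by 2 x 2 area
averaging, the natural sensor-binning model. Because noise precedes
downsampling, the effective noise level on the degraded image is
$\sigma/2$, and the physics loss of the true ground truth on a noisy sample
has expectation $(\sigma/2/255)^2$ — a closed-form identity the tests
verify by Monte Carlo. A 512 x 512 ground-truth frame maps onto a centered
2 x 2 block of sensor cells (a declared convention for how training patches
sit on the sensor grid), and smaller frames sit inside the single centered
cell. `augment_sample()` applies the eight
dihedral transforms consistently to input, ground truth and kernels, so the
degradation relation is preserved exactly in every variant.

## Restoration model

**CALW.** The front end is a channel-wise Wiener deconvolution diagonalized
in the Fourier domain,

$$\hat{x}_c = F^H\!\left[\frac{\overline{D_K}\, F y_c}{|D_K|^2 + e^{\alpha_c} \sum_{d=1}^{D} |D_{G_d}|^2}\right],$$

with three learnable parts. The PSF spectrum $D_K$ receives a bounded
multiplicative correction $D_K(1 + g(D_K))$ where $g$ is a zero-initialized
pointwise two-layer map on the stacked real/imaginary planes with
tanh-bounded output (0.35 per plane, so the total residual stays below 0.5
and the DC magnitude within [0.5, 2]); tabulated PSFs are never exactly
right, and boundedness keeps the filter well-posed. The $D = 8$
regularization kernels start from a fixed zero-mean bank (first
derivatives, Laplacian, four oriented second derivatives,
identity-minus-mean) plus a content-predicted residual from a shallow
encoder over the degraded image, zero-initialized so the bank is exactly
the base bank at the start. Each color channel has its own log-strength
$\alpha_c$, initialized to $\log 10^{-3}$ (weak prior regularization; on
the synthetic fixtures this initialization already restores better than
any stronger setting on a grid, and it remains learnable). Computation uses
a circular convolution convention on a 16-pixel mirror-padded grid,
center-cropped afterwards, which suppresses wrap-around ringing without
changing the algebra. Because dictionary kernels live at the sensor pitch
while the degraded input is 2x coarser, the front end and the feature
fusion below see the 2x2-rebinned kernels; the physics loss keeps the
fine-pitch set.

**Degradation-guided network.** The head is an encoder–decoder of
transformer blocks at three scales (1, 1/2, 1/4), each block = layernorm →
degradation-guided multi-head channel attention (DGMSA) → layernorm → gated
feed-forward, with residual connections throughout. Attention is
channel-transposed (queries/keys/values are per-channel descriptors over
space), keeping cost linear in pixels. Physical Degradation Feature Fusion
(PDFF) modulates each scale's features in the frequency domain by the
DC-normalized transfer-function magnitude of the sample's kernels (feature
channels split into three groups tied to the RGB wavelengths), concatenates
with the originals and mixes back with a learned pointwise map; the fused
features condition attention through a per-channel scale and bias on the
keys, zero-initialized so that at initialization DGMSA is exactly plain
channel attention — a deliberately testable reduction. The output path is
a sub-pixel 2x upsampler whose final convolution is zero-initialized, with
a global residual from the bilinear-upsampled CALW output: at
initialization the whole network is exactly the Wiener front end, and
training only ever has to learn a correction on top of a physical
restoration. The `tiny` profile (channels 16/32/64, one block per scale,
~103k parameters including CALW) is CPU-trainable; `base`
(48/96/192, 2/3/3 blocks) mirrors the same design larger.

All learnable components run on a small reverse-mode autodiff tape written
for this package (`ag_*` operators on dense arrays, including a composite
Wiener operator with analytically derived gradients for the corrected
spectrum, the regularization bank and $\alpha_c$). Every operator accepts
plain arrays or tape nodes, so the forward model and the differentiable
loss share one implementation; all gradients are verified against central
finite differences in the test suite.

## Loss

Training minimizes

$$w_{fid}\,\mathrm{MSE}(\hat{x}, x) + w_{phys}\,\mathrm{MSE}\bigl(\mathcal{D}(\hat{x} \circledast K_{opt}),\, y\bigr) + w_{ssim}\,(1 - \mathrm{MSSSIM}(\hat{x}, x)) + w_{tv}\,\mathrm{TV}(\hat{x})$$

where $\mathcal{D}$ is the identical patch-convolve-then-area-downsample
operator used by the data generator and $K_{opt}$ is the CALW-corrected
kernel set (values detached from the tape: the physics term steers the
image, the correction itself learns through the restoration path). A
physics-constrained fidelity objective can be read with or without a
standalone ground-truth MSE term; this implementation includes one,
because structural similarity alone under-constrains color fidelity.
Default weights $w_{fid} = 1$, $w_{phys} = 0.5$, $w_{ssim} = 0.15$,
$w_{tv} = 10^{-4}$ were chosen once so the terms are of comparable
magnitude on the synthetic fixture; all are exposed in `loss_weights()`.
MS-SSIM uses the standard five-scale weights and 11 x 11 Gaussian window
(weights renormalized when small images only admit fewer scales); TV is the
anisotropic mean absolute first difference. During training the output is
left unclipped (clipping would kill gradients at the bounds); inference
clips to [0, 1].

## Training and evaluation

`train_model()` follows the reference training recipe at desk scale: Adam (0.9,
0.999), initial learning rate 2e-5, cosine annealing restarting every 20
epochs, batch size 8. The full schedule is 200 epochs on ~12,000 pairs of
256 x 256 inputs; the package's standard smoke fixture is 64 pairs of
64 x 64 ground truth at three zoom levels for 5 epochs (about two minutes
on one CPU core), which is enough for the loss to decrease monotonically
and for held-out PSNR to exceed the bicubic-upsampled-input baseline by
more than 1 dB — most of that margin is contributed by the physically
seeded Wiener front end, which is the design's point. One trajectory
detail worth knowing: during the first few epochs held-out PSNR passes
through a small transient dip (a fraction of 0.02 dB per epoch) while the
structural-similarity and total-variation terms rebalance against MSE;
SSIM and the composite loss improve monotonically from the start, and PSNR
rises clearly above its initial value over a 25-epoch horizon. The
improvement check in the test suite therefore evaluates at 25 epochs,
resuming the 5-epoch smoke checkpoint. Every stochastic step
derives from the master seed, so runs are bit-reproducible and a resumed
checkpoint (parameters + Adam state + epoch counter) follows the identical
trajectory of an uninterrupted run. `evaluate_model()` reports per-
magnification PSNR/SSIM for the full model, the Wiener-only front end and
the bicubic baseline. Only phase-1-style training on synthetic degradation
is implemented; pairing real captures against a second instrument's ground
truth is a dataset swap, not a code path, and is out of scope.

## What the synthetic results do and do not show

The generator emulates the documented degradation process (spatially
variant blur from the 4D dictionary, additive Gaussian sensor noise,
sensor binning) on procedural phantoms. It does not emulate real tissue
statistics, illumination nonuniformity, ghosting from the liquid-lens
transmittance, registration error between instruments, or camera noise
beyond the additive Gaussian model. Passing tests therefore demonstrate
that the pipeline is internally consistent — the restoration inverts the
degradation it models, the physics loss sits exactly on its noise floor,
and learning improves held-out fidelity — not that any particular PSNR
would be attained on real captures. Real-capture restoration quality
depends on the physical prototype and its capture set, neither of which is
available at desk scale, and is deliberately not estimated here.

## Known limitations

* The Zernike pupil model is a stand-in for ray tracing; its severity
  schedule and NA trajectory are plausible, not calibrated.
* The front/rear power split along the zoom trajectory is an assumed
  schedule, not a calibrated one.
* The physics term detaches kernel values; spectrum-correction gradients
  flow only through the restoration path.
* Kernel lookup is nearest-level; continuous-magnification users should
  re-render kernels at the requested magnification.
* One CPU core is assumed; there is no batching across cores.
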