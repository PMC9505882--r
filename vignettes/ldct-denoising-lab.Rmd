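---
title: "Methods: simulating and denoising low-dose CT at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and denoising low-dose CT at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldctlab)
```

# The problem

Low-dose CT (LDCT) screening acquires chest scans at a fraction of the
standard radiation dose. Fewer photons reach the detector, so the
projection data carry more Poisson counting noise, which filtered
back-projection (FBP) turns into streaks concentrated in the patient's
body. `ldctlab` is a self-contained laboratory for studying this problem:
it simulates matched full-dose / low-dose image pairs on synthetic chest
phantoms, trains convolutional denoisers on them — the central model is a
stacked modified U-Net — and scores every method with a full
reference/no-reference quality protocol (RMSE, PSNR, SSIM, NIQE, and
improvement scores). Everything runs on one CPU with no external data.

# The noise model

Photon noise is inserted in the *sinogram* domain, where it physically
arises, not in the image:

1. **Forward projection.** The image is scaled from pixel intensities to
   attenuation line integrals ($\mu$-scaling) and projected with a
   parallel-beam Radon transform over $n_{\theta}$ equispaced angles in
   $[0^\circ, 180^\circ)$, giving $\rho(\omega, \theta)$.
2. **Beer–Lambert attenuation.** Expected detector counts are
   $\lambda(\omega,\theta) = I_{0L}\,P_b(\omega)\,e^{-\rho(\omega,\theta)}$,
   with incident flux $I_0 = K c \cdot mA \cdot s$ (scanner constant,
   collimation factor, tube current, exposure time) reduced to
   $I_{0L} = d \cdot I_0$ by the dose fraction $d$ (0.1 emulates a 10%
   dose scan). $P_b$ is a bowtie beam-shaping profile along the detector
   axis, normalised to 1 at the centre.
3. **Poisson sampling.** Detected counts are independent Poisson draws
   with mean $\lambda$; disabling them yields the deterministic pipeline.
4. **Log conversion.** $\rho_L = -\ln(I_L / I_{0L})$, with sampled counts
   floored at 1 before the log (the log is undefined at zero; a one-count
   floor is the standard convention). The known $\ln P_b$ term is
   subtracted, emulating the scanner's air calibration.
5. **Reconstruction.** Ram-Lak-filtered back-projection (Hann apodisation
   optional) returns the synthetic low-dose image, clipped to
   $[0, 1.5]$ to absorb reconstruction overshoot.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `doseFraction` | 0.1 | $I_{0L}/I_0$; the study condition is a 10% dose |
| `K, c, mA, s` | 100, 1, 700, 1 | incident flux $I_0 = 7\times 10^4$ cps; 700 mA sits in the 650–750 mA full-dose range of chest protocols |
| `bowtie` | `gaussian_edge`, strength $-\log 0.3$ | $P_b(d)=e^{-\lambda (d/d_{max})^2}$, edge weight $\approx 0.3$ |
| `nAngles` | image side | angle count of the parallel-beam geometry |
| `muScale` | auto | set so a body-width path (0.7 side) at intensity 1 attenuates by $e^{-4}$, giving a realistic count dynamic range without vendor HU calibration |

With these defaults a 10%-dose ray through the body centre detects on the
order of $10^2$ photons, which is exactly the regime where relative
counting noise becomes visible as streaks.

## Numerical choices

*Forward projector.* Pixel-driven splatting: each pixel is split into
2×2 subpixels, each adding a quarter of its value to the two detector
bins adjacent to $t = x\cos\theta + y\sin\theta$ with linear weights.
Because splat weights sum to one, every angle receives exactly the image
mass (mass conservation holds to machine precision); the subpixel split
suppresses the sampling comb that plain pixel-driven projection exhibits
at oblique angles. The detector spans the image diagonal.

*FBP.* The band-limited Ram-Lak impulse response is used to build the
frequency-domain ramp (avoiding the DC bias of naively sampling
$|f|$), projections are filtered with a zero-padded FFT, and the
back-projection samples the filtered projections with linear
interpolation, scaled by $\pi / n_\theta$. A 128-px phantom projected at
180 angles reconstructs at over 30 dB PSNR inside the body; the body
*edge* carries ringing, which is the dominant round-trip error. Outputs
may overshoot, hence the documented $[0, 1.5]$ clip.

*Zero counts.* At very low doses individual detector cells can count 0
photons; the 1-count floor bounds $\rho_L$ at $\ln I_{0L}$.

## The bowtie profile and where the noise sits

The bowtie filter concentrates flux (and hence relative noise) in the
body region; the vendor profile is proprietary, so the package provides
`flat` and the parametric `gaussian_edge` profile. With either profile,
photon noise in the reconstruction concentrates *inside* the body — body
rays are attenuated by up to $e^{-4}$, so their counts, and signal-to-noise,
are far lower than air rays — and the tests assert exactly this
(inside/outside noise-variance ratio above 1, plus the detector-level
property that edge counts fall below centre counts under the bowtie).

One ordering we deliberately do *not* assert: that removing the bowtie
makes the noise mask *relatively broader* outside the body. Under a
centre-normalised profile ($P_b \le 1$) the bowtie can only reduce
edge-ray flux, which raises outside noise; the measured inside/outside
ratio is therefore slightly *higher* for the flat profile. The published
"broader noise without bowtie" contrast compared a Poisson-with-bowtie
pipeline against an additive-Gaussian sinogram-noise experiment, which is
a different comparison; in this package the focusing of noise is driven
by Beer–Lambert attenuation plus Poisson statistics, not by the bowtie
itself.

# The phantoms

`generatePhantom()` draws one bright body ellipse (intensity 0.75–0.9) on
an exactly-zero background and fills it with rejection-sampled interior
ellipses of varied intensity — the minimal geometry that reproduces what
the denoising problem needs: a compact "area of interest" that
concentrates photon noise, internal low-contrast structure, and sharp
edges. Everything is seeded; identical specs give bit-identical images,
and paired datasets derive per-pair seeds as `seed + i` for both the
geometry and the Poisson draws.

What the phantoms do *not* emulate: anatomical texture, HU calibration,
scanner blur, electronic noise (deliberately omitted; it is minor in
modern scanners), fan-beam or helical geometry, and real projection data.
Passing tests therefore demonstrate that the pipeline and the learning
machinery behave correctly under controlled count statistics — not that
any trained weights transfer to clinical scans.

# The networks

All denoisers are regression networks (1-channel in and out, linear
output) built from a declarative `NetworkConfig`:

* **Proposed (`stacked_modified_unet`).** Two stacked U-Nets, encoder
  depth 3, a *constant* filter count on every layer (128 at full scale),
  dual 3×3 convolution blocks, stride-2 convolution for contraction
  (no pooling), transpose-convolution decoder blocks and expansion,
  concatenation skips within each stack, and a concatenation of the first
  stack's output and final decoder features into the second stack.
* **Comparators.** `unet` (filters doubling 64→1024 at depth 4,
  max-pooling, dropout retained), `segnet_like` and `deconvnet_like`
  (constant filters, max-pooling, conv vs transpose-conv decoders, no
  skips), and `rednet` (no contraction/expansion, summation skips every
  second layer). Batch normalisation is omitted everywhere, which is what
  makes the SegNet/DeConvNet-style regressors trainable for denoising.

Stacked small kernels trade parameters for depth at equal coverage: a
block of $n$ stride-1 $k \times k$ layers has a composite receptive
field of side $k + (n-1)(k-1)$ — a dual 3×3 covers a single 5×5 and a
triple 3×3 covers a single 7×7 — and `empiricalReceptiveField()` verifies
this on built models with a single-pixel perturbation probe.

Design points that the source material leaves open, resolved here:
dual 3×3 blocks are the default (the selected configuration, though
triple is constructible); the inter-stack concatenation carries the first
stack's output image plus its final decoder features; SegNet-style
max-unpooling indices are replaced by a stride-2 transpose convolution
(regression stability); He-uniform seeded initialisation.

The engine itself is written in R against OpenBLAS: convolutions are one
GEMM per layer through a precomputed im2col gather, transpose
convolutions are the exact adjoints of strided convolutions, and the
whole graph is validated against finite-difference gradients in the test
suite.

# Training protocol

Full scale: Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\epsilon = 10^{-8}$), RMSE loss, batch size 2, 300 epochs, learning rate
$10^{-4}$ multiplied by 0.8 every ten epochs. The first reduction takes
effect at epoch 11 — 29 reductions by epoch 300 — because that reproduces
the protocol's printed final rate of $1.5\times 10^{-7}$ (30 reductions
would give $1.2\times 10^{-7}$). Validation runs once per epoch over the
full validation split, and the returned model is the epoch with minimum
validation RMSE (checkpointing instead of early stopping). The data
split is a seeded random partition with floor(0.5 n) training and
floor(0.3 n) validation pairs, remainder test. Images enter the network
in $[0, 1]$ (low-dose inputs may reach 1.5 after clipping) without
per-image standardisation.

**Desk scale.** The package's default profile (`deskTrainConfig()`) is
64-px images, 32 filters, 16 pairs, 20 epochs, learning rate $10^{-3}$
with the same decay law: a run of a few minutes on one CPU. The shorter
schedule takes proportionally larger steps; at $10^{-4}$ a 20-epoch run
would barely move the weights. These sizes are the package's chosen
study conditions for tests and examples; the full 512-px/128-filter
profile is available (`trainConfig()`, `filters = 128`) but is a
GPU-scale undertaking.

The *overfit check* — two pairs driven far below the identity-map RMSE —
uses batch size 1 and $3\times 10^{-3}$ decayed by 0.8 every 35 epochs
over 300 epochs, validating on the training pairs so the checkpoint
tracks training performance. With only two images a batch-2 epoch is a
single optimizer step, which is why the check halves the batch; the
residual that is slowest to fit is the FBP edge-ringing at the body
boundary, and after 300 epochs the checkpointed model sits at about a
tenth of the identity RMSE and is still descending. Memorising two
images to high precision is step-starved under this protocol, not
capacity-limited.

**A scaling limitation, stated plainly.** The advantage of the stacked
model over a single modified U-Net at equal epochs — reported at full
scale — does not reproduce at mini scale (32 px, 8 filters, 8 pairs,
8–40 epochs): the deeper stack optimises more slowly and both models
reach the mini-scale loss floor. The suite therefore does not assert
that ordering; what it does assert is that the trained stacked model
beats the identity map on held-out pairs and removes more noise in
noisier images.

# Quality metrics

*RMSE* is the training loss, $\sqrt{\sum_i (t_i - o_i)^2 / P_x}$.

*PSNR* is $20\log_{10}(f_{max}/\sqrt{mse})$ with $f_{max}$ the configured
data range (1 for normalised phantoms), not the per-image maximum, so
scores are comparable across methods; identical images return an `Inf`
sentinel.

*SSIM* is implemented in the standard product form with stabilisers
$C_1 = (0.01 f_{max})^2$, $C_2 = (0.03 f_{max})^2$, $C_3 = C_2/2$ and an
11×11 Gaussian window ($\sigma = 1.5$). The source formula prints the
three components added; a sum of three near-1 terms would exceed 1,
contradicting the stated "higher is closer", so the conventional product
of the cited standard is used.

*NIQE* fits a multivariate Gaussian to natural-scene-statistics features
of sharp patches: GGD shape/variance of the MSCN coefficients plus AGGD
parameters of the four orientation products, over two dyadic scales (18
features per scale, 36 total). Patch size 48 and sharpness threshold 0.5
are the protocol values; the threshold selects patches (mean local
contrast above 0.5 of the per-image maximum) and is *not* a term in the
distance — the formula's $\tau$ is read as that selection threshold. The
score is the Mahalanobis-type distance with the pooled covariance
ridge-regularised by $\epsilon I$, $\epsilon = 10^{-6}\,tr/dim$, so small
patch counts at desk scale can never crash the inversion. Images are
rescaled internally to the conventional 0–255 working range, which also
makes the score invariant to a declared global intensity scaling.

*Improvement scores* are denoised − low-dose for PSNR/SSIM and low-dose −
denoised for NIQE (lower NIQE is better), so positive always means
"better". Binned comparison tables use equal-width bins over the observed
low-dose score range (the published grouping widths are unstated; 8 bins
by default), and the per-method overall mean equals the count-weighted
mean of bin means by construction.

The NIQE model used in evaluation should be fitted on clean images
disjoint from the evaluated pairs (the training split's clean images, in
the examples).

# Classical baselines

Gaussian smoothing ($\sigma = 0.45$ px), non-local means (5×5 patches,
11×11 search, $h = 3.5\hat\sigma$), and a *simplified* two-stage
BM3D-style collaborative filter: block matching, 2-D DCT per 8×8 block
with a 1-D Haar transform across each group of up to 16 similar blocks,
hard thresholding at $2.7\sigma$, weighted aggregation; then a second
matching pass on the basic estimate with empirical Wiener shrinkage. It
is faithful in structure to collaborative filtering but is not the
reference BM3D implementation. Where a noise level is needed and not
given, the Immerkær Laplacian-difference estimator supplies
$\hat\sigma$. Defaults were tuned once on the phantom fixtures and
frozen; the calibration was repeated once when the forward projector was
replaced, since that changed the artifact/noise mix the first calibration
saw.

# Problem sizes used by the tests

Unit tests run at 8–96 px. The acceptance suite uses: 128-px phantoms at
180 angles for reconstruction quality; 128-px, 8-seed batches for the
dose-monotonicity and noise-localisation physics; the 64-px/32-filter/
16-pair/20-epoch desk profile for held-out learning; the 300-epoch
two-pair run for the overfit check; and 8 seeded 64-px fixtures for the
classical-baseline ordering. These are the package's chosen desk-scale
study conditions.

# Known limitations

* Parallel-beam geometry only; the theoretical formulation is
  parallel-beam even though clinical scanners are fan-beam/helical.
* The vendor noise-insertion tool operates on real projection data; the
  fidelity gap between it and this emulation is acknowledged, not
  bridged. Published full-scale scores (mean improvements, per-image dB
  values) are not reproducible here and are not targets of this package.
* Phantoms are geometric, not anatomical; trained desk-scale weights are
  demonstrations of the machinery, not clinical denoisers.
* DICOM input is out of scope (no DICOM reader in the R stack this
  package builds on); images travel as 16-bit TIFF/PNG.
* NIQE absolute values on phantom corpora are much larger than on
  natural-image corpora — phantoms are not natural scenes — but the
  orderings and improvement signs, which are what the protocol uses, are
  well behaved.
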