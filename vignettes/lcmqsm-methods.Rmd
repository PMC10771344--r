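---
title: "Dipole physics, phantom simulation, and the modulated network in lcmqsm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dipole physics, phantom simulation, and the modulated network in lcmqsm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the modelling choices behind `lcmqsm`: the
discrete dipole forward model and its inversions, the synthetic phantom
generator, the latent-code modulated network, and the numerical
conventions that make the package's exactness contracts hold. It states
no empirical numbers beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## The forward model and its discrete conventions

A susceptibility distribution χ(r) (ppm) placed in a static field B₀
shifts the local field by the convolution of χ with the z-component of
the unit dipole response, d(r) = (3cos²θ − 1)/(4π‖r‖³), θ being the
angle between r and B₀. In k-space this is a pointwise product with
D(k) = 1/3 − (k·b̂)²/‖k‖². Working in normalized field-shift units
(δB/B₀, ppm) removes |B₀| from all numerics. Three discrete conventions
matter:

* **DC bin.** D is undefined at k = 0. We set D(0) = 0 (exposed as
  `dc_convention`): the volume-mean susceptibility produces no local
  field contrast and is unobservable, the usual QSM reference
  convention. Consequently every inversion — TKD and COSMOS alike —
  recovers χ only up to its mean, and recovery tests compare against
  zero-mean references.
* **Nyquist symmetrization.** On even-sized grids the Nyquist frequency
  aliases with its negative, so for a tilted b̂ the sampled formula
  assigns inconsistent values on Nyquist planes and the operator loses
  its evenness (D(k) = D(−k)) and, with it, realness of the
  reconstructed field. `build_dipole_kernel()` therefore averages the
  kernel with its k → −k image; values are clamped to the analytic range
  [−2/3, 1/3] to remove one-ulp floating-point excursions. With this
  convention the forward operator is exactly real, even, and
  self-adjoint, and multi-orientation least squares is exact to machine
  precision on noiseless data.
* **Boundary model.** The convolution is periodic (pure FFT, no
  padding), matching the pointwise k-space product exactly; a 2×
  zero-padding flag (`pad = TRUE`) is available to approximate the
  free-space field of compact sources. The sampled-k operator's far
  field differs from the continuum dipole sum by a small angular
  discrepancy concentrated near the polar axis and equator (a
  consequence of sampling the kernel's k → 0 discontinuity on a finite
  lattice, independent of grid size); agreement is tightest along
  generic directions, which is where the real-space oracle tests probe.

The frequency lattice uses unnormalized discrete Fourier frequencies
scaled by 1/(N·voxel size) per axis; only the direction of k enters D,
so the overall frequency scale is immaterial (and tested to be).

## Inversions

**TKD.** χ(k) = δB(k)/D(k) where |D(k)| > T, else 0. The threshold T
(dimensionless, default 0.2, the conservative end of the usual 0.15–0.2
range) trades recovered spectrum for noise robustness. Bins at exactly
|D| = T are zeroed — they belong to the ill-conditioned set. The
composite forward-then-TKD map is a k-space projector (idempotent),
which the tests exploit as an exact round-trip contract.

**COSMOS.** With fields from ≥ 2 orientations, the normal equations
decouple per k-bin and the least-squares solution is closed form:
χ(k) = Σᵢ Dᵢ(k)δBᵢ(k) / Σᵢ Dᵢ(k)², zeroed where the denominator falls
below 1e−6 (the same ill-conditioning logic as TKD's threshold). The
`max_iter = 200` / `tol = 1e-5` arguments describe the equivalent
iterative solve's budget; the decoupled solve is exact, so they are
recorded but never bind.

## The phantom generator

The generator emulates the synthetic-data protocol the package is built
around: an ellipsoidal VOI (semi-axes 0.4/0.45/0.35 of the grid) holding
a smooth background (|χ| ≤ 0.05 ppm, k-space low-passed white noise) and
blob regions drawn in [−0.15, 0.15] ppm as deep-gray-matter stand-ins; a
global linear amplification factor drawn uniformly from [1, 3];
spherical sources whose values are drawn uniformly from [−0.4, 0.4] ppm
and **overwrite** (not add to) the tissue, keeping |χ| within the stated
range; a field computed by the forward model plus i.i.d. Gaussian noise;
and a magnitude proxy with region contrast co-located with χ, sharp
sphere contours, and a mild multiplicative bias field, clipped to [0, 1]
and zero outside the VOI.

Values the protocol does not pin down are package choices, set once:
noise_std = 0.005 ppm (about 5–10% of typical field amplitudes — visible
but not dominant, as in well-processed in-vivo field maps), 4 spheres of
radius 2–4 voxels per volume, 6 blob regions. All draws come from one
seeded generator in a documented order, so a sample's provenance is its
config plus one integer and regeneration is bit-identical.

What the generator does **not** emulate: MR signal formation (multi-echo
phase evolution, T2* decay, wrapping), background fields, anatomical
geometry, and spatially correlated noise. Tests passing on these
phantoms therefore certify the algorithmic contracts — physics,
inversion algebra, learning signal — not in-vivo image quality.

## The network

The architecture follows the three-pathway design: an encoder chain over
the field patch produces full-resolution features FB₁..FBₙ and, after
two ×2 downsamplings, a bottleneck F_d; a decoder convolves F_d, pools
it by a VOI-restricted global average, and emits one latent code per
modulated block through separate linear heads (one latent pathway,
per-block projections); the cross-fusion block processes each FBᵢ by a
3³ convolution, fuses all levels with the masked-magnitude features
through a 1×1×1 convolution, and finishes with per-level 3³ heads; the
modulated convolution module starts from the TKD pre-estimate and chains
three (configurable 2–5) modulated blocks, each combining its modulated
convolution output with the fused features by concatenation plus a 3³
convolution.

Numerical and design choices:

* **Demodulation index set.** The per-output-channel normalization sums
  over input channels and spatial taps of that output channel, the
  convention of the weight-demodulation technique the block is built on.
  ε (default 1e−8) guards the all-zero case; after demodulation each
  output channel's squared norm is exactly s/(s+ε) < 1.
* **Entry masking.** All inputs are multiplied by the VOI mask; the
  bottleneck features are re-masked (mask mean-pooled to F_d resolution,
  thresholded at 0.5) before the decoder convolution. Without that
  re-masking the decoder convolution would smear background into the VOI
  and the latent codes would not be background-invariant; with it they
  are bit-invariant to arbitrary out-of-VOI perturbation.
* **No batch-dependent normalization.** Leaky rectifiers (slope 0.1)
  only; demodulation already stabilizes scale, and batch statistics
  would break background independence. Inputs are consumed in physical
  ppm units — no per-volume normalization anywhere.
* **Residual head.** The output head is zero-initialized and the initial
  MCM input (χ_int, or the field under the `LCMnet_deltaB` ablation) is
  added to the head output, so the untrained network reproduces its
  pre-estimate exactly and training learns a correction. This is the
  package's reading of the pre-estimation's role — a raw approximation
  that lends the model "stability and convergence speed" — and it is
  what makes that benefit real at the learning rate used: the network
  refines a physically meaningful starting point instead of regrowing
  the susceptibility map from near-zero outputs. `residual = FALSE`
  restores a pure feed-forward head.
* **Unstated widths.** n = 3 encoder levels and 32 base channels are
  implementation defaults; the desk-scale experiments use 2 levels and 8
  channels.

## Training and evaluation

The loss is ‖m(Ŷ−Y)‖²_F + α‖m(f_LoG(mŶ) − f_LoG(mY))‖²_F with m the VOI
indicator. Masking is applied *before* filtering as well as after, so
the loss is zero exactly when the masked volumes coincide and voxels
outside the VOI can never contribute through the filter's support. The
discrete LoG kernel (σ = 1.5 voxels, 9³ taps by default) is the sampled
analytic 3-D LoG, mean-subtracted so it sums to exactly zero and
annihilates constants exactly; filtering uses symmetric boundary
padding, and the loss gradient uses the exact adjoint (zero-pad full
correlation followed by the padding fold). α = 0.1 balances the two
terms at typical phantom scales; it is a package default, not a
protocol value. Optimization is AdamW — decoupled weight decay 5e−4,
learning rate 1e−4, 30 epochs, batch 4, 64×64×32 patches by default —
with per-epoch mean losses recorded and bit-deterministic runs under a
fixed seed on a fixed BLAS/thread configuration.

The desk-scale experiments in the tests and the acceptance script use
16³ volumes, 10 training and 5 held-out samples, a 2-level/8-channel
model, 200 optimization steps of batch 2, and 3 seeds — sizes chosen so
the full suite runs in minutes on one CPU while still exhibiting the two
qualitative learning properties they assert: the trained network beats
its TKD input on held-out RMSE, and replacing χ_int by the raw field
(`LCMnet_deltaB`) inflates the first-epoch loss.

Metrics are the field's usual four, with formulas fixed by this package
(none are prescribed upstream): RMSE = 100·‖x̂−x‖/‖x‖ over the VOI;
PSNR = 10·log₁₀(peak²/MSE) with peak the reference's in-mask range,
capped at 120 dB; MSSIM with a Gaussian window (σ 1.5, 7³) and in-mask
dynamic range, averaged over VOI voxels; HFEN = 100-scaled relative
error of LoG-filtered volumes sharing the loss kernel. Metric values are
comparable within this implementation only.

## Known limitations

* Single-echo, single-field-map samples only; no phase preprocessing
  (masking, unwrapping, background-field removal) — inputs are assumed
  to be clean local field maps.
* The magnitude proxy carries structural contrast but no MR physics;
  conclusions about the magnitude pathway's value on real data require
  real magnitude images.
* CPU-only; training at the full default width (3 levels, 32 channels,
  64×64×32 patches) is possible but slow — the package is a reference
  implementation, not a production trainer.
* Reconstruction quality on in-vivo or challenge data is out of scope;
  no trained weights ship with the package.
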