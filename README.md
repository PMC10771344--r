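# lcmqsm

Quantitative susceptibility mapping (QSM) reconstructs the magnetic
susceptibility χ of tissue (in ppm) from the local magnetic field shift
δB/B₀ measured by MRI phase imaging. The two are linked in k-space by the
dipole kernel

    δB(k) = D(k) · χ(k),    D(k) = 1/3 − (k·b̂)² / ‖k‖²

where b̂ is the unit B₀ direction. D vanishes on a double cone at the
magic angle (≈54.7°), so single-orientation inversion is ill-posed:
thresholded k-space division (TKD) zeroes the ill-conditioned bins
(|D| ≤ T) and divides elsewhere, while multi-orientation COSMOS solves
the per-bin least-squares problem across head tilts and serves as the
gold standard.

`lcmqsm` implements this physics plus a latent-code modulated
convolutional network (LCMnet) for single-orientation reconstruction,
all testable at desk scale on built-in synthetic phantoms. The network
takes three inputs: the field map (encoded into multi-level features and
a latent code by VOI-restricted global average pooling), the VOI-masked
magnitude image (combined with the field features in a cross-fusion
block), and the TKD pre-estimate χ_int, which seeds a chain of modulated
convolution blocks. Inside each block the latent code l scales the
kernel weights per input channel,

    w′_{p,q,r,c} = l_c · w_{p,q,r,c}

and weight demodulation renormalizes each output channel,

    w″ = w′ / sqrt(Σ_{p,q,r,c} (w′)² + ε),

making the convolution sensitive to the input intensity distribution
while keeping training stable. Training minimizes a masked MSE plus
high-frequency error norm (HFEN, Laplacian-of-Gaussian filtered) loss
with AdamW (lr 1e-4, weight decay 5e-4). Ablation variants
(`LCMnet_NoMod`, `LCMnet_NoFusion`, `LCMnet_deltaB`) are configuration
flags. The whole stack — forward model, TKD, COSMOS, phantom simulator,
network, training loop, and PSNR/RMSE/MSSIM/HFEN metrics — is written
for researchers who want an inspectable, CPU-scale reference
implementation rather than a GPU production pipeline.

## Worked example

Simulate a brain-like phantom (ellipsoidal VOI, smooth background,
deep-gray-matter-like blobs, global amplification drawn from [1, 3],
spherical susceptibility sources in [−0.4, 0.4] ppm, forward-model field
plus noise), invert it with TKD, and score the result:

```r
library(lcmqsm)
g    <- grid_geometry(c(32, 32, 32), voxel_size = c(1, 1, 1))
cfg  <- phantom_config(g, n_sources = 3, seed = 42)
s    <- generate_sample(cfg)
kern <- build_dipole_kernel(g)
chi0 <- tkd_invert(s$field, kern, tkd_config(0.2), mask = s$mask)
rep  <- metric_report(chi0$data, s$chi$data, s$mask$data)
```

This prints (via `sprintf` formatting of `rep` and the provenance):

```
TKD vs ground truth:  PSNR 23.96 dB  RMSE 59.57  MSSIM 0.442  HFEN 51.81
amplification factor drawn: 2.118
well-conditioned k-space fraction at T=0.2: 0.528
```

RMSE and HFEN are normalized ×100 (100 = as wrong as predicting zero);
at T = 0.2 TKD discards ~47% of k-space, which is where its error comes
from. Training an LCMnet on such samples (`prepare_patches()` +
`train()`) learns a correction on top of χ_int that lowers the held-out
RMSE below the TKD input; `run_ablation_suite()` reproduces the
qualitative ablation ordering on synthetic data.

A command-line front end covering the same pipeline (simulate, forward,
tkd, cosmos, train, reconstruct, evaluate, ablate) is installed at
`inst/cli/lcmqsm`; NIfTI volumes carry the voxel geometry, YAML files
the configuration, JSON the reports and provenance.

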