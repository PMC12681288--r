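---
title: "Unrolled reconstruction of undersampled 3D Dixon MRI: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unrolled reconstruction of undersampled 3D Dixon MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unrolledmri)
```

## The problem

Quantitative muscle MRI in neuromuscular disease tracks the replacement of
muscle by fat through the per-voxel fat fraction FF = F/(W+F), measured from
multi-echo gradient-echo Dixon acquisitions. 3D protocols are slow; k-space
undersampling shortens them but aliases the images. This package implements
unrolled optimization networks that reconstruct undersampled single-coil 3D
k-space while preserving FF accuracy, together with everything needed to
exercise and evaluate them end to end on synthetic data: Fourier operators,
variable-density Poisson-disc masks, three-point Dixon separation, image and
segmentation-agreement metrics, a thigh phantom generator, a CPU training
loop, and a complexity audit.

## The reconstruction model

With $k$ the unknown full k-space, $k_{us}$ the acquired undersampled data,
$D$ the binary sampling mask and $F$ the (centered, orthonormal) Fourier
transform, reconstruction solves

$$\hat k = \arg\min_k \|k_{us} - Dk\|_2^2 + \lambda R(F^H k).$$

A gradient iteration is unrolled into a fixed number of *cascades*, each
owning a learned step size $\mu_{it}$ and a learned regularizer:

$$\hat k^{it+1} = \hat k^{it} - \mu_{it} D(\hat k^{it} - k_{us})
  + F\,\mathrm{Net}(F^H \hat k^{it}),$$

with $\hat k^1$ the zero-filled $k_{us}$. The penalty weight $\lambda$ has no
runtime home: the network absorbs both the regularizer gradient and its
scale. Four variants are provided:

* **varnet** — the regularizer is a 3D U-Net (channels double at each of the
  five encoder stages; two 3×3×3 convolutions per block with instance
  normalization, LeakyReLU 0.2 and dropout; 2×2×2 max pooling; mirrored
  decoder with kernel-2 stride-2 transpose convolutions and skip
  concatenations; final 1×1×1 convolution).
* **halfvarnet** — the regularizer is a 3D Half U-Net: the encoder keeps a
  constant channel width, and the decoder is reduced to parameter-free
  upsampling of every encoder output to full resolution followed by an
  elementwise sum; only the final stage keeps a learned two-convolution
  block. This divides forward FLOPs by ≈2.7 and parameters by ≈74 per
  regularizer.
* **dircn / halfdircn** — densely interconnected versions: cascade $it$'s
  regularizer consumes the channel concatenation of all previous image
  iterates (so its first convolution has $2\,it$ input channels), and the
  decoders of consecutive cascades are interconnected (same-resolution
  decoder features for the full U-Net; the pre-final-block summed map for
  the Half U-Net, doubling that block's input channels).

Complex data are handled as two-channel (real/imaginary) images around each
regularizer call, since FF computation needs the reconstructed phase.

### Normalization and two deliberate deviations

Each regularizer input is standardized jointly over its channels
(`normalize_two_channel()`); the output is rescaled by the same standard
deviation, but the mean is **not** re-added. Re-adding it would place an
impulse on the always-sampled DC bin at every cascade, so that a zero-weight
regularizer would no longer leave sampled k-space entries exactly equal to
the acquired ones. We hold exact data consistency at zero weights to be the
defining contract of the DC term and invert only the scale.

For the dense variants, the often-cited identity residual from the
regularizer's input image to its output is realized by the additive
pass-through of $\hat k^{it}$ in the update above, using the identity

$$\hat k - \mu D(\hat k - k_{us}) + F\,\mathrm{net}
  = F\!\left(F^H \hat k + \mathrm{net}\right) - \mu D(\hat k - k_{us}).$$

An *explicit* additive residual on top of this update would double $\hat k$
and again break exact data consistency; the two formulations are otherwise
the same map, so nothing is lost.

## Undersampling masks

3D GRE acquisitions sample the readout axis fully, so undersampling lives on
the (ky, kz) phase-encode plane and acceleration is defined there. Masks are
drawn by dart throwing with a local exclusion radius
$r(\rho) = r_0 (1 + \alpha \rho)$, $\alpha = 2.5$, where $\rho$ is the
normalized elliptical distance from the k-space center — a variable-density
Poisson-disc pattern. A central ellipse holding 4% of the plane points is
fully sampled (the "4% of k-space" is interpreted on the phase-encode plane;
this is a configurable convention). The base radius $r_0$ is calibrated by
bisection until the empirical acceleration is within 5% (in practice ≈1%) of
the nominal factor; masks are bit-reproducible per seed.

## Three-point Dixon separation

The protocol's TE grid (2.38 ms steps at 1.5 T) alternates exactly between
fat–water out-of-phase and in-phase conditions. From the first three echoes
$S_1, S_2, S_3$, the B0-induced phase per echo step is estimated as
$\phi = \arg(S_3 \bar S_1)/2$, the dominant-species sign as
$s = \mathrm{sign}\,\mathrm{Re}\{S_1\overline{S_2 e^{-i\phi}}\}$, and then
$W = (|S_2| + s|S_1|)/2$, $F = (|S_2| - s|S_1|)/2$,
$FF = 100\,F/(W+F)$ clamped to $[0, 100]$ (percent scale; the evaluation
metrics use peak 100 accordingly). The scheme is exact on noiseless data for
$|\Delta B_0| < 1/(4\,\Delta TE)$ and needs no phase unwrapping; the
$\phi$-mod-$\pi$ ambiguity is accepted, with an optional 3×3×3 smoothing of
the B0 phasor (`smooth_phase`) for noisy data. No T2* or multi-peak fat
correction is applied — FF here is the three-echo biomarker, not a
confounder-corrected one. Background is removed before evaluation with an
Otsu threshold, per-slice hole filling and largest-component selection.

## The synthetic phantom: what it emulates and what it does not

`make_thigh_phantom()` builds an elliptical thigh cross-section whose axes
vary smoothly along z: a subcutaneous fat ring (FF 90%), a cortical bone
void, and n muscle compartments (nearest-seed partition) with W+F = 1 and
assigned FFs. The default ten-muscle assignment spans 4.5–83% with median
8.9%, mirroring the mostly-mild clinical FF distribution. Echoes follow the
single-peak fat model $S(TE_n) = (W + F e^{i2\pi\Delta f TE_n})
e^{i2\pi B_0 TE_n} e^{-TE_n/T2^*} e^{i\theta_0}$ plus complex Gaussian noise
(default SD 2% of the mean foreground signal, a realistic 1.5 T GRE level);
$\Delta f = 1/(2\Delta TE) = 210$ Hz so the TE grid alternates exactly. B0
is a smooth polynomial with default 50 Hz peak, inside the unambiguous
Dixon band.

The phantom does **not** emulate multi-peak fat spectra, T2* heterogeneity,
coil sensitivities, motion, or anatomy-specific texture. A green end-to-end
test therefore establishes that the pipeline is self-consistent and that the
networks remove undersampling artifacts on piecewise-smooth tissue — not
clinical-grade performance.

## Training at desk scale

Training follows the reference recipe: Adam (lr 0.001 by default), batch
size 4 via gradient accumulation, MSE loss between the two-channel inverse
FFT of the predicted k-space and the fully sampled reference image
(complex-valued fidelity, since phase must be reconstructed), model
selection at the lowest validation loss with ties to the earliest epoch.
Echoes of one acquisition are independent samples but never straddle
dataset splits; one mask per acceleration is shared across echoes
(configurable convention). Dropout is active in training only. No learning
rate schedule is used.

The networks, reverse-mode autodiff and Adam are implemented in the package
itself (Rcpp im2col/col2im kernels + BLAS matrix products) because no deep
learning framework is available in the supported environment; every
operation's gradient is finite-difference tested. Desk-scale tests train a
2-cascade HalfVarNet (8 channels, 3 stages) on 32×32×8 phantoms in minutes
on one CPU; these runs use dropout 0 (a 29k-parameter model on clean
phantoms does not need stochastic regularization, which only adds variance
to the smoke signals) and a learning rate up to 10× the clinical default,
appropriate for single-volume overfitting runs; both choices are test-scale
settings, not changes to the stated defaults.

## Complexity audit conventions

`count_parameters()` counts every convolution/transpose-convolution weight
and bias plus one $\mu$ per cascade; it equals the instantiated model's
count by construction and is property-tested over random configurations.

`count_forward_flops()` uses one fixed convention, reverse-engineered so
that a single rule reproduces all printed reference figures for these
architectures (within 0.25%): 2 FLOPs per multiply-accumulate; convolutions
*and* transpose convolutions charged kernel-volume taps per output element;
bias 1, instance norm 4, LeakyReLU 1 and dropout 1 FLOP per element on block
outputs; max pooling $2^d-1$ comparisons; upsampling and summation 1 FLOP
per element; Fourier/data-consistency operations excluded; everything
counted on the pooling-padded grid (128×128×36 → 128×128×48 for five
stages, pinned by the single-U-Net figure). Under this convention the
12-cascade HalfDIRCN predicts ≈2418 GFLOPs while the corresponding printed
figure is 2268; that figure is inconsistent with the additive model fitting
all the others and is excluded from acceptance rather than fitted.

Checkpoint size is 12 bytes per parameter: float32 weights plus the two
Adam moment buffers.

```{r audit}
complexity_audit(list(network_config("varnet", 8),
                      network_config("halfvarnet", 8),
                      network_config("halfvarnet", 12),
                      network_config("dircn", 8),
                      network_config("halfdircn", 8),
                      network_config("halfdircn", 12)))
```

## Numerical choices and degenerate inputs

* FFTs are centered (DC at `floor(n/2)+1`) and orthonormal, making the DC
  residual scale-free; adjointness is tested to 1e-6.
* A constant regularizer input takes the sentinel path `sd = 1` in the
  normalization (no division by zero).
* `three_point_dixon()` sets indeterminate voxels (|S2| = 0) to FF 50; the
  sign term breaks exact ties toward water.
* Odd spatial sizes are zero-padded symmetrically to the pooling grid and
  cropped back exactly; padding happens after normalization.
* Poisson-disc bisection stops at 1% of the target budget or 40 iterations;
  the same dart order is reused across iterations so the calibration is
  monotone and deterministic.
* `mu` scalars initialize to 1 (a full DC projection per cascade); He
  initialization elsewhere; instance normalization carries no affine
  parameters (the variant-defining parameter counts pin this choice).
* Two groups of parameters are analytically dead and receive exactly zero
  gradient: biases of convolutions immediately followed by instance
  normalization (a per-channel constant is removed exactly by the
  normalization) and the first cascade's `mu` (the zero-filled initial guess
  satisfies `k^1 = k_us` on the mask support, so the first DC residual
  vanishes identically). Both are retained because the architecture's
  parameter counts include them; the gradient-liveness test asserts they are
  dead for exactly these reasons and that everything else trains.

## Known limitations

Single-coil Cartesian data only; no sensitivity maps, non-Cartesian
trajectories, or prospective undersampling. Segmentation masks are consumed,
never produced. The FLOP counter is an accounting convention, not a runtime
model. Training at the clinical scale (128×128×36, 8 cascades, hundreds of
epochs) is far outside CPU reach; the package's training loop is exercised
and validated at phantom scale.
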