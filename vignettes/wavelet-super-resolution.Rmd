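---
title: "Wavelet-domain frequency-separated super-resolution: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet-domain frequency-separated super-resolution: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wavesr)
```

This vignette documents the scientific and numerical choices behind
`wavesr`: the wavelet model, the network design, the training procedure,
what the synthetic phantom does and does not emulate, and the places
where the design was genuinely open and a decision had to be made.

## The stationary Haar model

`swt2_level1()` computes a one-level two-dimensional *stationary*
(undecimated) Haar transform. Every coefficient is a signed half-sum of
a 2×2 pixel window — with `a` the current pixel, `b` its right
neighbour, `c` the pixel below, `d` the diagonal:

\[
A = \tfrac12(a+b+c+d),\quad
H = \tfrac12(a+b-c-d),\quad
V = \tfrac12(a-b+c-d),\quad
D = \tfrac12(a-b-c+d).
\]

Three properties of this normalization drive everything else:

* for pixels in \([0, 255]\), \(A \in [0, 510]\) and
  \(H, V, D \in [-255, 255]\), with the bounds attained at constant-255
  and half-and-half corner images;
* the detail planes sum to zero *exactly* (their kernels have zero DC
  response and circular filtering loses nothing at the boundary), so
  their means vanish for any image;
* \(\operatorname{mean}(A) = 2\,\operatorname{mean}(I)\), because the
  approximate kernel entries sum to 2.

**Boundary handling is periodic (circular).** This is the unique
convention under which the 2×2 signed half-sum picture is self-consistent
at every pixel of every image, and it preserves the exact zero-sum detail
property. It also imposes no parity constraint, so odd-sized images are
transformed directly. One printed form of the \(H_{12}\) entry in the
original presentation of these identities is inconsistent with the other
fifteen entries (it repeats the \(A\) formula); the package implements the
value implied by the periodic sliding-window evaluation,
\(H_{12} = \tfrac12(a+b-c-d)\) with roles taken at the wrapped window.

The inverse (`iswt2_level1()`) averages the four redundant per-pixel
reconstructions. For planes that actually came from the forward transform
this is exact to machine precision (the test suite checks
\(\max|ISWT(SWT(I)) - I| \le 10^{-8}\) over a thousand random images);
for planes predicted by a network — which are generally *not* a
consistent transform of any image — the average is the natural
least-squares choice.

## Network design

The network consumes the approximate plane (1 channel) and the stacked
detail planes (3 channels, fixed order H, V, D from `split_bands()`)
through two separated paths, reflecting their different statistics:
approximate coefficients are non-negative with large dynamic range
(ReLU activations), detail coefficients are signed and sparse (Tanh
activations). Pixels are divided by 255 before the transform so the
approximate band lives in \([0,2]\) (ReLU-compatible) and details in
\([-1,1]\) (Tanh-compatible); the division is undone after the inverse
transform.

* **Approximate path** (five blocks: three standard convolutions and two
  ghost extension blocks, all ReLU): 3×3 conv to `base_filters` →
  ghost block (doubling channels) → 1×1 conv back to `base_filters`
  (concatenation is informative but redundant; the 1×1 conv prunes it) →
  ghost block → 3×3 conv → sub-pixel head.
* **Detail path** (shallower, because the sub-bands are sparse): 3×3 conv
  → spatial-attention ghost block → 1×1 conv → sub-pixel head emitting
  three planes.

The **sub-pixel heads** are linear (no nonlinearity after the final
convolution): predicted detail corrections must span negative values and
should not saturate. The pixel shuffle maps \(s^2\) channel groups onto
an \(s \times s\) sub-pixel grid; it is a pure permutation of values, and
its adjoint (the un-shuffle) is used in backpropagation.

The **hard-sigmoid** in the attention gate is the piecewise-linear
`clamp((x + 3) / 6, 0, 1)` — the widely used mobile-network convention —
since only "a hard-sigmoid" is specified by name. The gate's merge
convolution takes the concatenated channel-wise average-pool and max-pool
maps (2 input channels) to a single channel and is **bias-free**, which
makes its parameter cost exactly \(2k^2\), matching the closed-form
accounting in `param_count()`.

Two block combinations are supported, mirroring the published ablation:
`G+S` (ghost blocks in the approximate path, the spatial-attention ghost
block in the detail path — the default) and `G+G` (ghost blocks
everywhere). The approximate path's "low-attention" blocks are read as
plain ghost blocks; both combinations are constructible and differ by
exactly 18 parameters per substituted block at \(k = 3\).

### Residual prediction

Whether the network should predict high-resolution coefficients
*directly* (the literal reading of the loss definition) or predict
*differences* was genuinely ambiguous in the source material, which both
writes the loss over absolute coefficients and describes the
reconstruction as producing "residual wavelet coefficients". The package
implements both and defaults to the residual form
(`network_config(residual = TRUE)`): the two paths predict corrections
that are added to the wavelet planes of the **bicubic upscale of the
input**. Those base planes are a consistent transform, so their inverse
is exactly the bicubic upscale — an untrained model already reproduces
the bicubic baseline, and training spends its entire budget on the
missing high-frequency content. At desk scale this matters decisively:
in a 20-epoch experiment the direct form was still ≈1.5 dB *below*
bicubic while the residual form was ≈1.8 dB above it. The direct form
remains available via `residual = FALSE`.

In residual mode the prediction heads are initialized at a small scale
(`head_init_scale = 0.01` times the He/Glorot draw): the initial
correction is then near zero (the model starts *at* the baseline), while
the weights stay nonzero so gradient flows to every layer from the first
step. Elsewhere initialization is He-uniform on the ReLU path and
Glorot-uniform on the Tanh path, with zero biases; the initializer was
unspecified upstream, and these are the standard matches to the two
activation families.

## Training procedure

`train_model()` optimizes the wavelet-domain L2 loss
\(\frac{1}{2N}\sum_n (\lVert \Delta A_n\rVert^2 + \lVert \Delta D_n\rVert^2)\)
with Adam (\(\beta_1 = 0.9, \beta_2 = 0.999\)), gradient **global-norm
clipping** (default threshold 0.001 — the published value; "norm
clipping" is read as global-norm rather than per-value clipping, and the
threshold is configurable since clipping this aggressive may slow larger
runs; note Adam's per-parameter normalization makes the *direction*, not
the magnitude, the main casualty of clipping), and a cosine decay
schedule.

The published schedule pseudocode sets, at epochs that are not multiples
of `decay_epoch`,
\(lr = (1-\alpha)\cdot\tfrac12(1+\cos(\pi\,\text{epoch}/\text{decay\_epoch})) + \alpha\)
— an *absolute* assignment with values near 1.0 at early epochs — while
the accompanying text states an initial learning rate of 0.001. Taken
literally the two are incompatible (a rate of ~1.0 diverges immediately).
`cosine_decay_lr()` implements the pseudocode literally, and the training
loop applies its value as a **decay multiplier on the configured
`initial_lr`**, which reconciles both statements and is how cosine decay
is conventionally parameterized. `decay_epoch` defaults to 100 (the value
stated in prose) with the pseudocode's 30 available through
configuration.

Patch preparation follows the standard protocol: HR crops of
`patch_size` (default 48) on a regular grid, each paired with its
bicubic downscale. The stated crop overlap ("48×48 … with 48 pixels
overlapping") is self-contradictory (overlap equal to size means stride
zero), so the default stride is 24 — 50% overlap — and configurable. The
degradation operator was never stated; bicubic downscaling (Keys kernel,
\(a = -0.5\), antialiased when shrinking) is the field-standard choice.
The last 10% of the shuffled patches are held out and scored by
reconstruction PSNR after every epoch; all shuffling, splitting and
initialization derive from the single `train_config(seed)`, so runs are
bit-reproducible on CPU.

## Numerical choices

* Dense convolutions run as one batched GEMM over an im2col matrix held
  in single precision — the standard arithmetic precision for CNNs —
  with the element-wise activation fused into the kernel; parameters,
  their gradients and the optimizer state remain double precision.
* Convolution padding is zero "same" padding (feature maps keep their
  spatial size through every block); only the wavelet transform itself
  uses periodic boundaries, where exactness matters.
* The channel max-pool routes its gradient to the first maximal channel
  on ties; the hard-sigmoid derivative is \(1/6\) strictly inside
  \((-3, 3)\) and 0 outside.
* PSNR of identical images returns `Inf` as an explicit sentinel.
  SSIM uses 11×11 Gaussian windows (σ = 1.5) over the valid region with
  the standard constants \(c_1 = (0.01\cdot255)^2,
  c_2 = (0.03\cdot255)^2\); although the statistic is often described as
  lying in \([0, 1]\), the covariance term can make it negative for
  anticorrelated patches, and the implementation does not clamp.
* `ssim()` requires images of at least 11×11 (one full window).

## The synthetic phantom

`make_phantom()` emulates exactly the statistical signature the
frequency-separated design relies on: strong low-frequency anatomy
(smooth gradients, large elliptical lung fields) plus sparse edges
(ellipse boundaries, curved rib bands), with an optional Gaussian noise
floor (default σ = 1.5 gray levels, a mild detector-noise stand-in).
Noise-free phantoms concentrate >95% of wavelet energy in the
approximate band and keep >90% of diagonal-detail pixels below 5% of the
band maximum — the regime in which learning sparse detail corrections is
meaningful. The generator is *not* an anatomical simulation: it has no
pathology, no scatter or beam-hardening physics, and its edges are
cleaner than real radiographs. Tests passing on phantoms therefore
demonstrate the correctness and trainability of the pipeline, not
clinical performance on hospital data.

The default experiment sizes used throughout the test suite — 2000
patch pairs from 25 phantoms of 256², a `base_filters = 8` network,
20 epochs at scale ×2, five seeds — were chosen as the smallest
configuration at which the trained model separates cleanly (≳ +0.3 dB)
from the bicubic baseline on held-out patches.

## Known limitations

* One decomposition level and the Haar family only; no multi-level or
  other wavelet support (the lightweight model is the point).
* Single scale factor per trained model (×2, ×3 or ×4), grayscale only;
  color inputs must be converted explicitly.
* The direct (non-residual) prediction mode exists for completeness but
  needs far more training than the desk-scale experiments here provide.
* Training is single-threaded CPU; the implementation is tuned for small
  models, not for reproducing full-scale GPU training runs.
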