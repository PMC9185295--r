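---
title: "Methods: optical-flow stacking and PCANet+ features for micro-expression recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: optical-flow stacking and PCANet+ features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Micro-expressions are involuntary facial movements lasting a fraction of a
second, with sub-pixel to few-pixel intensity of motion concentrated in
sparse facial regions. Classifying a short clip by its micro-expression
class is hard for two reasons: the motion signal is faint relative to the
(static) facial identity signal, and labeled corpora are tiny — far too
small to fit large backpropagation-trained networks without severe
overfitting. `ofpcanet` therefore uses a *shallow, analytically trained*
architecture: dense optical flow amplifies the motion and suppresses
identity, temporal stacking exposes short-range dynamics, and a two-layer
PCANet+ — whose convolution filters are closed-form PCA eigenvectors, not
gradient-descent solutions — produces features for a linear SVM. Evaluation
is leave-one-subject-out (LOSO), the person-independent protocol: every
fold holds out *all* clips of one subject.

## Optical flow against the reference frame

The first frame of each clip is the reference. For each later frame
`t = 2..L` the solver estimates the displacement field `(u, v)` mapping
reference pixels to that frame, minimizing a discretized objective with
three parts:

1. **Brightness constancy** (weight `alpha`, default 10): a robust
   Charbonnier penalty `sqrt(x^2 + eps_data^2)` on
   `I_t(x + u, y + v) - I_1(x, y)`, linearized by first-order Taylor
   expansion and re-warped coarse-to-fine so motions of several pixels are
   handled despite the small-motion linearization.
2. **Trajectory-subspace consistency** (weight `beta`, default 1): the
   per-pixel motion trajectory `(u(1..L-1), v(1..L-1))` is penalized by its
   squared distance to the span of `R` basis trajectories. The basis is
   unspecified in the underlying formulation beyond its existence; we use
   the first `R = min(6, L-1)` orthonormal discrete-cosine (DCT-II)
   vectors — smooth, standard for trajectory subspaces, and containing the
   constant and near-linear trends that dominate brief facial motions.
   The `pairwise` backend drops this term and solves frames independently.
3. **Total variation** (weight 1): isotropic Charbonnier-smoothed TV of
   `(u, v)` per frame, `sqrt(|grad u|^2 + |grad v|^2 + eps_tv^2)`.

### Numerical scheme

The solver alternates (a) per-frame lagged-diffusivity (IRLS) updates of
the linearized data + TV + subspace-attachment objective, solved by
red-black successive over-relaxation (`omega = 1.8`) on the per-pixel 2x2
systems, with (b) projection of all trajectories onto the basis span. The
subspace penalty enters the flow update through the *fixed* projection
target of the previous half-step, which makes the alternation a
majorize-minimize scheme. On a 3-level pyramid (scale 0.5, Gaussian
pre-smoothing) each level runs 5 warping passes of 10 sweeps
(`iterations_per_level = 50`).

Numerical choices, all config-overridable:

* `eps_data = 0.01` (intensity units, matched to 8-bit quantization and
  typical sensor noise on `[0, 1]` images) and `eps_tv = 0.05` (pixels).
  These keep the IRLS weights bounded; a much smaller `eps_tv` makes the
  diffusivity explode on smooth flow and stalls convergence.
* Gradients are central differences; warping is bilinear with
  border-clamped sampling; the data-term gradient averages the warped
  moving-frame gradient with the reference gradient.
* At the finest level every outer pass is accepted through backtracking
  (step halving) on the *true* discretized energy, so the reported
  `energy_trace` is non-increasing by construction; if no damped step
  decreases the energy the solver stops early.
* The solver is deterministic: zero initialization at the coarsest level,
  no randomness anywhere.
* Returned fields are quantized to float32 — the precision of the
  Middlebury `.flo` cache format — so cached and freshly computed flow are
  bit-identical and caching can never change downstream results.

On smooth synthetic textures the solver recovers global translations of up
to ~3 px with mean endpoint error well below 0.1 px (measured away from an
8-px border band, where clamped sampling makes ground truth itself
ill-defined). Large *cumulative* displacements of localized bumps (10+ px
late in a long clip) are tracked qualitatively but underestimated —
acceptable here because classification depends on the location and
direction pattern of the motion rather than its exact late-clip magnitude.

## Sliding-window stacking

The `L-1` flow fields are sampled by a window of length `T` (default 5)
and step `s = (T-1)/2` (floored, minimum 1 so `T = 1` is valid). Window
`i` covers flow frames `(i-1)s+1 .. (i-1)s+T` and yields one
`N x M x 2T` tensor: the `T` u-fields, then the `T` v-fields. The window
count is `floor(((L-1) - T)/s) + 1`. A subtlety: the count is often
written `floor((L-T)/s)` in terms of the *clip* length `L`, although only
`L-1` flow fields exist; we count complete windows inside the flow
sequence so every window indexes valid frames, and drop trailing frames
not covered by a complete window.

## PCANet+ feature learning

Each layer extracts the `k x k x C` patch around every pixel (zero padding
`(k-1)/2`), subtracts each patch's own mean, and learns the `D` filters
minimizing patch reconstruction error under orthonormality — the top-`D`
eigenvectors of the patch scatter `P P^T`, computed by a symmetric
eigensolver. Implementation details:

* The scatter is accumulated as a streaming sum over tensors, so peak
  memory is set by the patch dimension, not the batch size, and training
  is independent of tensor order.
* Eigenvector signs are fixed (largest-magnitude entry positive, first
  index on ties) so filters are reproducible across eigensolvers. Among
  *equal* eigenvalues the eigenvector ordering is solver-dependent and the
  filter set is non-unique; ties keep the solver's descending order.
* "Convolution" is fixed to be correlation with zero padding; for learned
  filters the distinction is immaterial, but oracle tests need one fixed
  convention.
* Between layers, stride-1 3x3 mean pooling (symmetric/reflect padding, so
  borders are not darkened by zeros) adds the nonlinearity PCANet lacks
  and is applied before hashing, consistent with the pooled responses
  being the layer's output.

Encoding: each group of `F_lambda = 8` pooled response maps is collapsed
into one integer map by Heaviside hashing (`label = sum_f 2^(f-1) [map_f >
0]`, so labels lie in `[0, 255]`); each hash map is split into `B` non-
overlapping blocks (default a 2x2 grid, near-equal sizes, remainder pixels
to the last row/column — the block geometry is not fixed by the reference
architecture, so it is a package choice and configurable) and histogrammed
into `2^F_lambda` bins. Both layers are encoded and concatenated, giving
`sum_l B_l (D_l / F_lambda) 2^F_lambda` features; per-block histogram mass
always equals the block's pixel count. With the reference SMIC geometry
(`D1 = 32`, `D2 = 16`, `B = 4`) this is 6144 dimensions.

## Classification and evaluation

Per-tensor features of a clip are averaged (element-wise mean; sum is
available) into one clip feature. Features are standardized per dimension
using training-fold statistics only, and classified by a linear one-vs-rest
SVM (libsvm via e1071, `C = 1`, no inner tuning loop — mirroring the
absence of any hyper-parameter search in the reference protocol). LOSO
folds follow subject first-appearance order; fold predictions are pooled
into one confusion matrix before computing metrics (micro-pooling, which
matches reporting a single accuracy per dataset).

Metrics: accuracy `sum TP_i / total`; per-class precision and recall with
the 0-when-undefined convention (warned); macro-F1 as the unweighted mean
of per-class F1. The quantity printed as "macro-recall" in some write-ups
uses the *precision* denominator `TP_i + FP_i`; we treat that as a typo,
report the `FN_i`-based macro-recall as the headline, and also expose the
mean precision as `macro_precision` so both variants are available.

## The synthetic-data generator

Real micro-expression corpora are license-restricted, so the package ships
a generator whose defaults define the study conditions used by the tests:
6 subjects, 3 clips per subject (classes cycling), 64 x 64 frames, 10
frames per clip, peak motion 2 px/frame (inside the small-motion regime),
intensity noise 0.01 added *after* warping so brightness constancy is
mildly violated, 8-bit PNG output. Each subject has its own smooth random
texture (two-scale filtered noise; identity lives in texture), each class
a smooth Gaussian-bump displacement field at a class-specific location —
an upward lower-face drift, a downward upper-face drift, and a radial
dilation — mimicking sparse localized action units. Frame `t` is the
bilinear backward warp of the base by `(t-1)` times the field, and the
ground-truth fields are written as `.flo` files for flow testing.
Everything is driven by one seed and is byte-identical across runs.

What the generator does *not* emulate: photo-realistic faces, head pose
and illumination nuisances, class-dependent *temporal* dynamics
(onset-apex-offset profiles), and spatially overlapping class patterns.
Because the class signature is a spatially distinct pattern growing
linearly in time, a *single* flow field already identifies the class:
under the default conditions the pipeline reaches pooled LOSO accuracy
1.0 both with stacking (`T = 3`) and without (`T = 1`). Passing the
end-to-end test therefore demonstrates that the whole chain — flow,
stacking, feature learning, LOSO classification — is wired correctly and
recovers controllable class structure; it does not demonstrate the
real-data advantage of stacking over single-field encoding, which arises
from temporal complexity this generator deliberately lacks. The
corresponding strict `T = 3 > T = 1` comparison in the acceptance suite
documents this ceiling effect by failing at the accuracy ceiling rather
than by weakening the generator's stated conditions.

## Problem sizes in the test-suite and acceptance runs

Unit tests run on small in-memory fixtures (images of 16-64 px, patch
matrices of a few hundred columns). The end-to-end checks use the
18-clip default synthetic dataset at 64 x 64 with the reduced
`synthetic-small` preset (`T = 3`, two layers of eight 5x5 filters), and
the architecture check trains the full SMIC-geometry bank
((7x7x10)x32, (9x9x32)x16) on two 170 x 139 stacked tensors — enough to
exercise every shape and the streaming scatter at full dimensionality.

## Known limitations

* Only frame-directory clips are supported; video containers would need an
  external decoding backend that the R stack does not provide.
* The flow solver underestimates large cumulative displacements of
  small-support motions (coarse pyramid levels average them away).
* Histogram features discard spatial detail below the block scale; with
  the default 2x2 grid, localization is coarse by design.
* Degenerate PCA spectra make filters non-unique (documented tie-break).
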