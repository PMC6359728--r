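---
title: "Recognizing spray areas with the mutual subspace method"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing spray areas with the mutual subspace method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msmrec)
```

## The problem and the model

A UAV sprayer flying over cropland or an orchard must distinguish, from
its downward-looking camera stream, *spray* areas (crop rows, canopy)
from *non-spray* areas (farm roads, ridges, bare soil, buildings). The
decision has to be cheap enough to run per frame window on board, which
motivates a classical linear method over deep models: the mutual
subspace method (MSM).

Every frame is reduced to a pattern vector $x \in \mathbb{R}^{64}$:
grayscale conversion, resize to $8\times 8$, row-major flattening. A
category observed over $n$ frames is summarized by the leading
eigenvectors of its autocorrelation matrix

$$C = \frac{1}{n}\sum_{j=1}^{n} x_j x_j^{\top},$$

i.e. an uncentered PCA. The retained eigenvectors
$\varphi_1,\dots,\varphi_d$ span the class *reference subspace*. A single
pattern $p$ is scored against a class by the squared cosine of the angle
between the vector and the subspace (the subspace-method / CLAFIC
similarity)

$$\cos^2\theta = \frac{\sum_{i=1}^{d}(p\cdot\varphi_i)^2}{\lVert p\rVert^2},$$

and an image *set* is scored by first fitting its own subspace $Q$ and
then measuring the canonical (principal) angles between $Q$ and each
reference subspace $P$: the canonical cosines are the singular values of
$B_P^\top B_Q$ for orthonormal bases $B_P, B_Q$, and the MSM similarity
is the squared largest cosine (optionally the mean of the top $t$
squared cosines). The query is assigned to the class with the largest
similarity, equivalently the smallest canonical angle.

The underlying assumption is that the within-class variability of
small, downsampled aerial views is approximately linear: frames of one
land cover populate a low-dimensional cone in pattern space. The model
cannot use overall brightness alone — every similarity above is
invariant to rescaling a pattern — so categories must differ in the
*direction* of their typical patterns (texture, structure,
orientation), which is also what distinguishes canopy rows from bare
soil in practice.

## Pipeline parameters

| parameter | default | meaning |
|---|---|---|
| sampling interval | 20 | keep frame 0, then every 20th frame of the raw stream |
| pattern size | 8×8 (k = 64) | area-average resize before vectorization |
| grayscale weights | 0.299, 0.587, 0.114 | ITU-R BT.601 luma, the common JPEG/video convention |
| `tau` | 0.95 | cumulative contribution rate selecting the subspace dimension |
| `dim` | `NULL` | fixed-dimension override of `tau` |
| `centered` | `FALSE` | subtract the class centroid before PCA |
| window `w` | 4 | consecutive frames per online window |
| `stride` | 1 | step between windows (fully overlapping) |

Notes on the genuinely open choices:

* **Centering.** The classical CLAFIC/MSM formulation uses the raw
  autocorrelation matrix; a covariance-about-the-centroid variant is
  equally defensible and sometimes described alongside it. Both are
  implemented (`centered = TRUE/FALSE`); uncentered is the default and
  the centering flag is recorded in persisted models, so results are
  always attributable to one convention.
* **Similarity scale.** Canonical-angle similarities are reported as
  $\cos^2\theta$ uniformly, so single-pattern (SM) and set (MSM) scores
  live on the same scale; $\cos^2$ is monotone in $\cos$, so
  classification decisions are unaffected by the choice.
* **Offline scoring granularity.** The offline protocol reports
  per-image confusion counts, yet MSM proper needs image sets. Default:
  each test image is scored individually by the SM similarity
  (`mode = "image"`); `mode = "set"` groups consecutive test images
  into sets of `set_size` and classifies each set by canonical angles.
  Both produce the same style of confusion matrix.
* **Split convention.** `split_first_last_half()` puts the middle frame
  of an odd-length sequence into the *testing* half by default
  (107 → 53 train / 54 test), with `direction = "ceil"` available.
* **Tie-breaking.** Equal similarities resolve to the first category in
  model order, with a message; category order otherwise never affects
  predictions.
* **Window dimension.** A 4-frame window has rank ≤ 4 (less for
  near-identical frames); the window subspace dimension is the model's
  dimension rule clamped to the window rank, silently for windows.

## The synthetic scene generator

No aerial video ships with the package; the generator produces labeled
surrogate streams with exactly the statistical structure the classifier
exploits, nothing more:

* class appearance = fixed template (any matrix in $[0,1]$, upscaled by
  block replication; oriented stripe textures are the bundled idiom) plus
  per-pixel Gaussian noise with standard deviation `within_class_sd`;
* temporal structure = stationary AR(1) noise with lag-1 correlation
  `temporal_corr`, so consecutive frames cohere like video;
* transition/noise frames = uniform random pixels, maximally unlike
  either class template, for exercising noise-frame removal;
* frames are generated at 64×64 (configurable) and pushed through the
  *real* preprocessing path — grayscale, area-average resize,
  vectorization — so preprocessing is tested, not bypassed;
* determinism: a sequence is a pure function of (parameters, seed);
  datasets derive per-sequence seeds as master seed + sequence index.

The standard study conditions used by the tests and the acceptance
script are 200 frames per class, `within_class_sd = 0.05`,
`temporal_corr = 0.5`, with vertical-stripe vs horizontal-stripe
templates (angularly well separated: a separable fixture) or identical
templates (a zero-separation fixture whose accuracy must sit at chance
within binomial error). These sizes keep the complete synthetic study
under a couple of minutes on one core while leaving no ambiguity about
the expected outcome.

What the generator does **not** emulate: photorealistic canopy texture,
illumination changes, camera motion blur, geometric/lens distortion, or
correlated (structured) noise. Passing the synthetic end-to-end checks
therefore demonstrates that the pipeline is correct and that the method
separates angularly distinct textures under temporal correlation — it
does not certify field accuracy on real imagery, which depends on how
linearly separable real canopies are at 8×8 resolution.

## Numerical choices

* Canonical cosines are computed by SVD of $B_P^\top B_Q$ — numerically
  superior to eigen-decomposing projector products and exactly
  equivalent; values are clipped into $[0,1]$.
* Eigenvalues below $10^{-12}\lambda_{\max}$ count as zero for rank
  decisions; a requested dimension above the rank is clamped with a
  warning. Subspaces over tied eigenvalue blocks are defined only up to
  rotation within the block, and every similarity is invariant to that
  rotation (property-tested).
* Tiny principal angles are validated through their sine (the norm of
  the projection residual), because $\arccos$ cannot resolve angles
  below about $10^{-8}$ in double precision.
* Accuracy percentages are kept at full precision internally;
  `round_half_up()` (half away from zero) is used for one-decimal table
  display, matching common table conventions rather than banker's
  rounding.
* Zero patterns, empty streams, mask-length mismatches, non-binary
  confusion labels and empty confusion matrices raise immediate errors
  rather than propagating NaNs.

## Limitations

* Linear subspaces only: kernel, constrained and orthogonalized MSM
  variants are out of scope.
* Noise-frame removal is mask-driven (manifest or manual list); there is
  no automatic noise detector.
* Brightness-only class differences are invisible to the method by
  construction.
* The bundled field-trial confusion counts are inputs for the accuracy
  arithmetic; the package makes no claim about re-deriving them from
  imagery.
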