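---
title: "Synthetic T1 images for longitudinal new-lesion detection: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic T1 images for longitudinal new-lesion detection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Detecting *new* T2 lesions between a baseline and a follow-up MRI scan is the
standard radiological marker of multiple sclerosis disease activity.
Automated detectors work best with two contrasts per timepoint — T2-FLAIR
(lesions hyperintense) plus T1-weighted (lesions hypointense, inverted
gray/white contrast) — but longitudinal protocols frequently acquire only
FLAIR. This package implements a complete pipeline to test one remedy:
*synthesize* the missing T1 volume from the FLAIR volume with a conditional
adversarial network, and feed the synthetic T1 (called **T1S**) to the
detector in place of the unacquired acquisition.

Three experimental arms make the comparison paired and fair; they differ only
in the detector's input channels:

| arm | detector inputs |
|---|---|
| `baseline` | FLAIR + original T1 |
| `flair_only` | FLAIR |
| `synthetic` | FLAIR + T1S |

## Pipeline stages

### 1. Synthetic longitudinal cohort (`phantom_spec`, `make_dataset`)

No public dataset accompanies the task at desk scale, so the package renders
its own longitudinal phantom cases: a three-tissue ellipsoidal brain
(CSF/GM/WM shells with jittered geometry and a smooth boundary perturbation),
rendered under two contrast lookups (FLAIR-like and T1-like), with additive
Gaussian noise (default sd 0.03), a smooth multiplicative bias field
(amplitude 0.2), partial-volume mixing at tissue boundaries, a small random
rigid misalignment between timepoints (up to 2 voxels / 2 degrees), and 2–5
new white-matter lesions (radius 1.2–3 voxels) present only at follow-up.
Lesions are FLAIR-hyperintense and T1-hypointense, as in disease. Every case
carries its exact new-lesion ground-truth mask.

The default grid is 64³; all problem sizes in this package (grid, cohort
size, network widths, step counts) are desk-scale choices made for a CPU-only
environment and are configurable upward.

### 2. Preprocessing (`preprocess_case`)

The baseline volumes are affinely registered to the follow-up FLAIR
(masked mean-squared-difference objective, Nelder–Mead over a two-level
coarse-to-fine pyramid; transform concatenation when a separate template is
supplied), the brain is masked (three-class Otsu thresholding + largest
connected component + morphological closing, with a plug-in contract for
externally computed masks), and in-mask intensities are mapped to [0, 1] by
percentile-clipped min–max normalization (1st/99th percentiles).

### 3. FLAIR intensity clustering (`cluster_intensities`)

The generator is conditioned not on raw FLAIR but on a hard clustering of
in-brain FLAIR intensities into `c` clusters (tissues plus partial-volume
shells), one-hot encoded. A seeded 1-D Gaussian-mixture EM (k-means++
initialization, 5 restarts, variance floor 1e-6) replaces FSL FAST; clusters
are relabeled in ascending-mean order so labels are canonical. `c = 7` is the
default operating point (the best detection trade-off among 3/5/7/9).

### 4. Cluster-conditioned synthesis (`synth_fit`, `synthesize_t1`)

A 3-D pix2pix-style setup on 32³ patches (stride 16):

- **Generator**: residual U-Net of 8 blocks (4 encoder + 4 decoder), two
  3×3×3 convolutions with batch normalization per block, summation skip
  connections, stride-2 downsampling, nearest-neighbour upsampling, sigmoid
  single-channel output.
- **Discriminator**: residual network of 4 blocks with pooling, global
  average pooling and a linear real/fake head per patch.
- **Losses**: discriminator binary cross-entropy with one-sided label
  smoothing (real target `1 − 0.1`); generator `1 ×` adversarial fooling term
  `+ 100 ×` masked mean absolute error (the pix2pix 1:100 convention).
  Setting `adv_weight = 0` reduces the model to voxelwise regression, used
  for smoke tests and pretraining.
- **Optimizer**: Adam (the source publication states both "gradient descent"
  and "Adam"; Adam is used).

Inference tiles the cluster one-hots at stride 16 and blends overlapping
predictions with a strictly positive separable Hann window — after weight
normalization the window is a partition of unity, so constants are conserved
and patch seams vanish.

### 5. Joint detection (`detector_fit`, `predict_new_lesions`)

Per modality, a registration U-Net maps the (baseline, follow-up) patch pair
to a dense displacement field; the baseline is warped by trilinear
resampling. The warped baselines and follow-ups of all modalities feed a
segmentation U-Net producing a two-class voxel softmax. Both sub-networks
are trained **end-to-end** in a single computation graph:

\[
\mathcal{L} = \sum_{m} \big( \mathrm{MSE}_{\text{mask}}(B_m \circ \phi_m, F_m)
 + \lambda\, \mathrm{smooth}(\phi_m) \big) + \mathrm{CE}_w(\hat y, y)
\]

with `smooth` the sum over displacement channels and axes of the mean squared
forward difference, and `CE_w` a weighted softmax cross-entropy. The
registration final convolutions are zero-initialized so training starts at
the identity deformation.

Two deliberate deviations from the plain description, both driven by extreme
class imbalance (new-lesion voxels are ~0.1% of patch voxels at desk scale):
the positive class is weighted (`lesion_weight`, default 30) and
lesion-containing patches are oversampled to 50% of each batch. Without
either, training at these sizes settles on the all-background solution.

Inference tiles at stride 16 with Hann blending; the probability map is then
`postprocess`ed: binarize at probability ≥ 0.5 (inclusive), label
26-connected components, remove components smaller than 3 voxels (0.3 is the
common alternate threshold).

### 6. Evaluation and comparison (`score_case`, `compare_models`)

Quality of T1S: **MAE** (the *median* absolute error — the convention of the
source formulation, despite the acronym) and a global three-factor **SSIM**,
both in-mask. Detection: lesion-wise matching under the one-voxel-overlap
rule, then sensitivity `tp/(tp+fn)`, FDR `fp/(fp+tp)` and precision (so
precision + FDR = 1). Stable (no-new-lesion) cases are scored by whether any
false-positive component appears (`fp_case_count`, nearest-integer percents).
Arms are compared with a paired two-sided Wilcoxon signed-rank test. The
implementation is exact for n ≤ 25 *including ties* (midranks with a
dynamic-programming distribution over doubled rank sums) and uses the
tie-corrected normal approximation with continuity correction above; zero
differences are dropped, undefined per-case scores are dropped pairwise.

## Numerical engineering

R has no deep-learning framework in this environment, so the networks run on
a small in-package engine: Rcpp/RcppArmadillo kernels (3-D convolution via
im2col + GEMM, pooling, upsampling, trilinear warping) under a tape-based
reverse-mode autograd over dense 5-D arrays. Every operation's gradient is
finite-difference checked in the test suite. Everything is seeded through a
single master seed (`derive_seed`), and identical config + seed reproduces
every output bit-identically, including `scores.tsv` files.

## Limitations

- The phantom emulates contrast relationships, noise, bias, partial volume,
  misalignment and focal new lesions — not real anatomy, pathology spectra,
  scanner artifacts, or inter-subject variability. Results on phantoms check
  *mechanism*, not clinical effect sizes.
- Networks are desk-scale (widths 2–8); the architecture matches the full
  method, but capacity does not.
- Registration is mono-modal (masked MSE); no mutual-information metric.
- Skull stripping is intentionally simple, with a plug-in contract for masks
  from dedicated tools.
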