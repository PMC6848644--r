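---
title: "Methods: cascaded SNpc segmentation and hyperintense-area quantification"
author: "nmseg authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cascaded SNpc segmentation and hyperintense-area quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Neuromelanin-sensitive MRI (a T1-weighted fast-spin-echo sequence) shows
the substantia nigra pars compacta (SNpc) as two hyperintense crescents
in the midbrain, because iron–neuromelanin complexes shorten T1. In
Parkinson's disease (PD) the dopaminergic, neuromelanin-containing
neurons are lost and the hyperintense extent shrinks. A practical
diagnostic statistic is the *hyperintense SNpc area*: the number of
SNpc-mask pixels whose intensity exceeds a background-referenced
threshold, times the in-plane pixel area. Producing that statistic
automatically requires segmenting the midbrain and the SNpc — a task
this package solves with a two-stage convolutional cascade — and the
package supplies everything around it: a synthetic phantom cohort
generator with ground truth, training-time augmentation, the threshold
statistic itself, and the evaluation layer (Dice, ROC/AUC, DeLong,
rank correlations, group tests).

## The quantification model

For one subject, let the *midbrain* be the union of the BACKGROUND and
SNPC labels on the two consecutive axial slices with the largest
midbrain pixel count (`selectSlices()`; ties go to the smaller index).
The *background* is the midbrain minus the SNpc. Pooling the background
pixels of both slices gives the mean signal intensity MSI and the
sample standard deviation SD (denominator $n-1$). The threshold is

$$T_k = \mathrm{MSI} + k \cdot \mathrm{SD}, \qquad k \in \{1, 1.5, 2\},$$

and the hyperintense area is

$$A_k = \#\{\,p \in \mathrm{SNpc} : I(p) > T_k\,\} \times s_r s_c \ \mathrm{mm}^2,$$

with $s_r = s_c = 0.43$ mm by default. Three conventions matter for
reproducibility and are fixed as follows:

* **Strict inequality.** "Above the threshold" is read literally as
  $>$; a pixel exactly at $T_k$ is not counted.
* **Sample SD** rather than population SD, the standard estimator for a
  measured region.
* **Pooled background**: one MSI/SD per subject across the slice pair,
  not per-slice statistics averaged afterwards.

Because $T_k$ is an affine function of the background statistics, any
monotone affine intensity map $x \mapsto a x + b$ ($a > 0$) transforms
the threshold the same way it transforms the SNpc intensities, so the
suprathreshold *set* — and hence the count — is exactly invariant. This
is verified as a property test and is also why the network's input
normalisation cannot bias the statistic. The count is non-increasing in
$k$ by construction. The per-cohort sweep (`thresholdSweep()`) picks the
$k$ with the highest ROC AUC (orientation: low area indicates PD),
breaking ties toward the smaller $k$; external-validation mode applies a
previously frozen $k$ without re-sweeping and records the source run in
the provenance log.

The quantities are areas (mm²): the computation multiplies a 2D pixel
count by an in-plane pixel area, and no volume reconstruction across
more than two slices is attempted.

## The segmentation cascade

Two independent U-nets perform successive tasks: network 1 labels each
pixel midbrain vs outside from the image alone; network 2 labels SNpc
vs background *within* the midbrain, receiving the image concatenated
with network 1's midbrain probability map (soft gating; a hard-mask
mode exists). Architectural choices:

* Encoder–decoder with skip connections; max pooling replaced by 3×3
  convolution with stride 2; 2×2 transposed-convolution upsampling;
  ReLU activations; 1×1 convolution to 2 classes with softmax.
* The two losses are *disconnected*: each network has its own Adam
  state, and an update for one never touches the other's weights
  (`freeze =` in `trainConfig()` makes this testable bit-for-bit).
* Network 2's cross entropy is restricted to pixels inside the
  ground-truth midbrain, since its task is only defined there. Network
  1's loss covers every crop pixel.
* Per iteration: one random slice and random square crop per batch
  element, batch size 2, mean cross entropy, Adam
  ($\beta_1 = 0.5$, $\beta_2 = 0.999$), no early stopping.
* Inference runs on full slices (reflect-padded to a multiple of
  $2^{\mathrm{depth}-1}$, then un-padded); within the predicted
  midbrain, network 2's argmax decides SNpc vs background; everything
  else is OUTSIDE, so predicted SNpc ⊆ predicted midbrain by
  construction. Exact probability ties resolve to the lower class
  index (OUTSIDE, then BACKGROUND), making inference deterministic.

The networks and their optimisation (im2col convolutions, transposed
convolutions, softmax cross entropy, full backpropagation, Adam) are
implemented natively in R on BLAS matrix products; the backward pass is
validated against finite differences in the development history and the
training loop against overfitting oracles in the test suite.

**Presets.** No channel schedule is prescribed for the original model,
so width and depth are configuration: the `"paper_like"` preset (depth
4, 64 base channels, 256 px crops, Adam $\alpha = 10^{-4}$, the
documented full-scale recipe) and the `"desk"` preset (depth 3, 8 base
channels, 96 px crops) that trains on a single CPU in minutes. Two
desk-scale deviations from the full-scale recipe are deliberate design
choices:

* **Input normalisation.** The full-scale recipe trains on raw
  intensities. At desk scale the networks receive per-slice z-scored
  input by default (`normalize = "zscore"`), which makes convergence
  robust across the augmented intensity range; `"none"` restores the
  literal behaviour. The quantification statistic is computed from the
  original intensities either way.
* **Learning rate.** `trainConfig()` defaults to the full-scale
  $\alpha = 10^{-4}$; the desk-scale runs in the tests and the
  acceptance script pass $\alpha = 10^{-3}$, matched to the much
  smaller parameter count and iteration budget of the desk networks.

**Cross-validation.** `crossValidate()` stratifies folds to a 1:1
HC:PD ratio (round-robin within group under the training seed), trains
each fold's model on the remaining folds, and designates the fold-1
model as the deployment model.

## Augmentation

Training data are expanded by intensity deviation $A(\mathrm{orig}+B)$
with $A \in \{0.7, 1.0, 1.3\}$, $B \in \{-100, 0, 100\}$, rotations of
$-30°/0°/+30°$ and rescaling to 90/100/110%, applied identically to
image and mask (bilinear vs nearest-neighbour, so labels stay in the
three-letter alphabet; the canvas is preserved and pixels entering from
outside take the slice minimum / OUTSIDE). Whether the three axes are
crossed is not prescribed; both combination modes exist
(`cartesian`, 81 variants; `per_category`, 13 variants — the union of
single-axis deviations). The desk-scale runs use `per_category`, which
keeps one epoch at 13 samples per subject; `cartesian` is the stronger
regulariser and reproduces every single-axis case. Augmentation is
precomputed into the training pool rather than sampled on the fly.
Rotation and rescaling use an inverse-mapped affine resampler written
for exact image/mask pairing in row-major coordinates.

## The phantom generator

Every downstream stage is testable without patient data on synthetic
midbrain phantoms that emulate the *structure* of the study data:

* 128×128 px slices at 0.43×0.43 mm; 4 slices of which 2 consecutive
  ones carry the midbrain (so slice selection is exercised); slice
  thickness 2.5 mm, gap 0.5 mm.
* The midbrain is the union of two overlapping ellipses (a convex
  "butterfly"); each SNpc crescent is an angular sector of an annulus
  anchored laterally, intersected with the midbrain. The second
  midbrain slice is drawn 8% smaller, as on more caudal sections.
* Intensities: outside 50, midbrain background 100, hyperintense SNpc
  100 + 40, additive Gaussian noise with SD 8 everywhere (Rician
  optional; Gaussian is the standard approximation at midbrain SNR and
  keeps the noiseless oracle exact). The SD-8 default puts the
  hyperintense contrast at 5 noise SDs and the background–outside
  contrast at about 6 — clearly separable, as in real NM-MRI, while
  leaving the threshold statistic genuinely noisy.
* The PD effect reduces the *extent* of the hyperintense sub-region:
  a fraction (HC 0.95, PD 0.55 by default; per-subject jitter SD 0.06)
  of anatomical SNpc pixels — those closest in angle to the crescent
  midline, so the loss erodes the crescent from its tips — receives the
  hyperintense mean. This matches the measured quantity (a
  suprathreshold area); a `delta` mode attenuates contrast instead for
  robustness experiments. The 0.95/0.55 defaults give group-mean areas
  of roughly 60 vs 35 mm², the same order and direction as real
  HC-vs-PD cohorts, and an effect size large enough that a 20 + 20
  cohort separates with AUC near 1 from ground-truth masks.
* Per-subject rigid jitter (shift ≤ 3 px, rotation ≤ 5°, scale ± 5%)
  is applied analytically to the shape parameters, so masks are exact
  rasterisations, never resampled. Subject seeds derive from
  `hash(cohort seed, index, group)`, making generation
  order-independent and regeneration file-identical (checksums are
  compared in the tests). Degenerate jitter (an empty crescent) causes
  regeneration under a derived sub-seed, failing after 10 attempts.
* Clinical covariates are simulated so the evaluation layer has
  something real to correlate: PD UPDRS-III increases as the
  hyperintense extent shrinks, building in a negative area–severity
  correlation; ages overlap heavily between groups.

What the phantoms deliberately do **not** model: bias fields, partial
volume, k-space artefacts, anatomical shape variability beyond rigid
jitter, or inter-reader delineation disagreement. Passing phantom tests
therefore demonstrates the correctness and internal consistency of the
pipeline — segmentation recoverability, statistic invariances,
diagnostic-performance preservation — not clinical performance on
patient images.

## Evaluation layer

* **Dice**: $2|A \cap B| / (|A| + |B|)$ over the chosen structure on
  the selected slice pair; both-empty returns 1 (agreement on absence —
  the conservative choice for phantom slices without midbrain). Rated
  low/moderate/high at 0.40 and 0.80, band edges exactly as printed
  (0.79 is moderate, 0.80 high).
* **ROC/AUC**: rank-based (equal to Mann–Whitney $U/(n_1 n_2)$), ties
  at half credit; the optimal cut-off maximises Youden's J with ties
  broken toward higher specificity — the criterion is not prescribed
  anywhere, so the standard deterministic choice is used and
  documented. Orientation `low_is_positive` for areas (PD has smaller
  areas).
* **DeLong**: placement-value covariance for paired curves,
  $z = (\widehat{A}_1 - \widehat{A}_2)/\sqrt{\widehat{\mathrm{var}}}$,
  two-sided normal p. Self-comparison returns $z = 0, p = 1$ without
  touching the covariance estimate. Implemented in-package so these
  contracts hold exactly; the test suite cross-checks against pROC and
  a type-I calibration simulation.
* **Spearman** with average ranks; strength bands on $|r|$ at
  0.20/0.40/0.60/0.80. **Group tests**: classic equal-variance
  Student's t (Welch off by default, documented), Mann–Whitney, and
  the chi-squared test without continuity correction on 2×2 tables.

## Numerical and degenerate-input choices

* Mask encoding on disk: unsigned 8-bit 0/1/2 for
  OUTSIDE/BACKGROUND/SNPC; `labelMap` arguments accept other dialects.
  Left and right SNpc are not distinguished — the statistic is one
  area per subject.
* All indices are 1-based (R convention), row-major `(row, col,
  slice)`; slice index increases superior → inferior.
* Background SD of 0 makes `relativeVariation()` fail explicitly
  rather than return infinity; fewer than two background pixels is an
  error naming the slices.
* Non-finite voxels fail image loading with the offending count;
  unmapped mask integers fail with the values listed.
* Training problem sizes in the tests and acceptance script: 16
  training subjects, 10 epochs, per-category augmentation (2,080
  gradient samples), held-out evaluation on 8 subjects, and a 20 + 20
  cohort for the diagnostic chain — sizes chosen so the full suite
  runs on a single CPU in minutes while leaving the recovery
  thresholds (midbrain Dice ≥ 0.90, SNpc ≥ 0.70, truth-mask AUC ≥
  0.95) genuinely demanding.

## Known limitations

* The cascade is 2D (per-slice), as the delineation protocol it
  automates; no 3D context is used.
* The desk preset's capacity is far below the full-scale model;
  phantom recovery says nothing about patient-scale accuracy.
* DeLong requires paired scores on identical subjects; no
  unpaired-comparison mode is provided.
* The phantom's PD effect is one-dimensional (extent or contrast); it
  does not emulate sub-regional (posterolateral) loss patterns, which
  the area statistic itself also ignores.
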