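---
title: "Methods: seed protein estimation from bench-top hyperspectral scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seed protein estimation from bench-top hyperspectral scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsiseed)
```

## The problem

Wheat protein content (7.69–19.65% of seed mass in the populations this
pipeline targets) is normally measured by destructive combustion chemistry.
Bench-top hyperspectral imaging offers a non-destructive alternative: seeds
on a scanning stage are imaged by two pushbroom sensors, a VNIR camera
(400–1000 nm, 300 bands) and a SWIR camera (960–2500 nm, 362 bands), with a
50% Spectralon panel in frame for reflectance calibration. Protein leaves a
spectral fingerprint — amide N–H and C=O overtones in the NIR — so per-seed
reflectance spectra and spatial–spectral patch models can both predict
protein. This vignette documents the models, parameters and numerical
choices of each stage, what the synthetic data generator does and does not
emulate, and the package's known limitations.

## Radiometric calibration

The sensor model is linear: a raw digital number is
`DN = L · R · t_int + dark`, with `L` the incident radiance, `R` a per-pixel,
per-band response, and `t_int` the integration time in seconds. Calibration
inverts this in three steps: dark-frame subtraction (negative differences are
clipped to zero — dark-noise excursions below the dark level are physically
spurious), response estimation from a bright panel scan divided by the
panel's known radiance, and division by `R · t_int`. Reflectance is then the
scene radiance over the per-band *mean* radiance of the panel region times
the panel's nominal reflectance (0.5). The mean is our choice of aggregation
over the panel region; a trimmed mean would also be defensible but makes no
difference on the simulator where the panel is spatially flat. Cells whose
bright signal does not exceed dark are flagged invalid and produce zero
radiance rather than a division by a non-positive response.

Reflectance, not radiance, is the default unit fed to all downstream stages:
the segmentation rule and the protein–reflectance relationship are stated in
reflectance terms, and reflectance is invariant to lamp intensity.
Absorbance (log 1/R) is a plausible alternative input we deliberately left
out of scope.

## Co-registration

The two sensors view the same planar stage from different heights, so the
mapping between their pixel grids is a planar homography — in practice
dominated by an anisotropic scale (the resolution ratio) plus a translation
of a few SWIR pixels. Feature-based matching (SIFT-like) fails on this data:
the two spectral ranges render the same materials with different contrast,
and seeds are visually repetitive. The package therefore estimates the
transform from matched fiducial-marker tie points:

* minimal 4-point DLT fits inside a RANSAC loop (up to 2000 iterations,
  inlier reprojection threshold 7.0 px, seeded and hence reproducible),
* Hartley normalization in every DLT solve for conditioning,
* a final least-squares DLT refit on the consensus set,
* degenerate samples (any three collinear points) are skipped; fully
  collinear tie-point sets are an error.

Reported alignment error is the RMSE of reprojection residuals. When more
than four markers are available, `compare_methods()` holds out 25% of them
and reports held-out RMSE, which avoids the optimism of quoting residuals on
the points the transform was fitted to. The naive baseline maps points by
the dimension ratio alone (`x · w_SWIR / w_VNIR`); it is exact for
zero-translation scenes and degrades linearly with the sensor offset, which
is the qualitative ordering the held-out comparison reproduces on every
synthetic scene with ≥ 2 px of translation.

Warping uses inverse mapping with bilinear sampling, one shared transform
for all bands; out-of-frame samples are zero. The warped VNIR cube and the
SWIR cube concatenate to a 662-band stack whose wavelength list retains the
960–1000 nm overlap (monotone within each sensor block, not across the
seam — `band_at()` still resolves nearest wavelengths correctly).

Coordinates are 0-based pixel centers, x = column, y = row, in all geometry
code.

## Segmentation

A pixel is classed as seed iff all five conditions hold at the 410 (B1),
456 (B2), 553 (G), 654 (R) and 852 (N) nm bands:

* B1 < B2,
* 0.7·B1 ≤ R ≤ 12.5·B1,
* 1.2·B1 ≤ N ≤ 15·B1,
* B2 < G and 1.2·B2 < G.

The two-sided bounds are our reading of the rule's chained inequalities,
which as printed mix ≤ and ≥ within a single chain; read as bounds they form
a consistent predicate (seed tissue has a rising visible/NIR slope; tray,
panel and markers are spectrally flat or falling). The background conditions
are the logical complement, making the rule total. The predicate sits behind
`rule_mask()` alone so an alternative reading can be swapped in.

Cleanup follows the classic morphology pipeline: opening with a 3×3 square
structuring element (removes isolated noise pixels; idempotent), then hole
repair by flood fill — a one-pixel guard border guarantees the top-left
corner is background, a 4-connected flood marks reachable background,
unreached zeros are holes inside seeds and become seed, and the border is
stripped. Flood fill is 4-connected (conservative background spread) while
component labeling is 8-connected (seed cohesion); the printed method states
neither, and these are the conservative choices in each direction.
Components must satisfy 250 < area < 1500 px strictly — specks and fused
seed pairs fall outside. Grid labels cluster centroid y into rows with a gap
tolerance of half the median component height, order by x within rows, and
emit column-letter + row-number (A1…D6 for the 4-wide, 6-long tray). Crops
are 32×32 windows centered on the centroid, zero-padded at frame edges, with
non-component pixels zeroed.

## Spectral features and splits

Per-seed spectra are masked means over seed pixels only. Savitzky–Golay
smoothing uses window 7, polynomial order 3 (it passes cubics through
unchanged; verified to 1e−9 in the tests). Band ratios `R_jk = X_j / X_k`
are enumerated for all j < k in lexicographic order — C(C−1)/2 features, with
denominators below 1e−8 producing a 0 (flagged) rather than dropping the
column, so the feature matrix keeps one shape across samples. Ratios are
computed on raw reflectance and the full feature matrix is min-max
normalized afterwards, fitted on the training rows only; values outside the
training range are not clipped, and constant training columns map to zero.

The data split uses a 3:1 test:train ratio and 4:1 validation:train ratio:
`n_test = round(n/4)`, `n_val = round((n − n_test)/5)` with **half-up**
rounding, the remainder training. Half-up is the only rounding convention
that reproduces both published triples (5057 → 3034/1264/759 and
4746 → 2847/1187/712): floor fails the second, ceiling fails the first.

Protein classes are low < 10%, 10–14% medium (both ends inclusive — "10–14%"
read as the closed interval), high > 14%. Summary statistics use type-7
(linear interpolation) quantiles and a mode defined as the most frequent
value after rounding to 0.01; the published tables do not state their
quantile convention, which is why the package asserts only the
convention-free identities (range = max − min, IQR = Q3 − Q1).

## Feature-based models

Random forest (500 trees, unlimited depth) and radial-kernel SVR (C = 10,
ε = 0.1) are the two regressor families; none of these hyperparameters are
stated by the method's source, so they are package defaults, all exposed.
Permutation importance is the drop in R² when one feature column is
shuffled, averaged over 10 repeats, scored on a held-out fold — scoring on
the training rows gives every feature a spuriously positive drop. Top-100
band selection for the reduced dataset variant uses descending importance
with ties broken toward the lower wavelength, computed on the training
partition only to avoid leakage into test metrics. The three dataset
variants are (1) all bands, (2) top-100 bands plus the 4950 ratios of those
bands, (3) all bands plus all ratios (at 662 bands, 219,453 columns — the
full variant is memory-heavy and intended for batch machines; tests exercise
the construction at reduced band counts).

## The hybrid 3D/2D network

Patches are reduced along the band axis by pixel-space PCA: every pixel is
an observation in band space, the top-K basis is fitted on training pixels,
and each patch becomes H × W × K with spatial structure intact. K is a
tuning choice; the package default is 30, and the scaled-down recovery runs
use K = 8 (see below). A raw-662-depth mode remains available, since the
full-depth input is part of the design space.

The network stacks three valid-mode 3-D convolutions (joint spatial–spectral
kernels), a reshape merging depth and channels, one 3×3 2-D convolution, and
two dense layers (256, 128) before the task head — a linear unit for
regression (MSE loss) or a 3-way softmax (categorical cross-entropy).
Activations are ReLU. Named kernel sets 1–3 are (3,3,7)/(3,3,5)/(3,3,3),
(3,3,11)/(3,3,9)/(3,3,7) and (5,5,15)/(5,5,11)/(5,5,9); a `"compact"` set of
three (3,3,3) kernels serves small spectral depths such as K = 8, where the
named sets would exhaust the depth axis (8 − 6 leaves 2 planes; a depth-5
kernel cannot follow).

Two channel-attention variants extend the base model:

* **Global attention** after the 3-D block: the H × W × D × C feature map is
  mean-pooled over height, width *and* depth (the stated 1×1×1×C attention
  shape forces pooling over depth as well), passed through a C/2 bottleneck
  dense layer (ReLU) and an expansion layer (sigmoid), and each channel is
  rescaled by its gate.
* **Squeeze-and-excitation** after the 2-D layer: per-channel spatial means,
  a C/r bottleneck (r = 2 by default, chosen for symmetry with the attention
  bottleneck), sigmoid gates, channel-wise rescaling.

With all gate weights and biases zero both blocks multiply their input by
exactly sigmoid(0) = 0.5, which the tests use as an analytic anchor, and the
full backward pass is verified against central finite differences on a tiny
attentive model (biases jittered off the ReLU kinks, where the loss is
genuinely one-sided and a finite-difference check is undefined).

Training uses Adam (lr 1e−3, β 0.9/0.999), minibatches of 32, and a single
seeded RNG stream for initialization and shuffling, so runs are bit-identical
on one CPU. Batch normalization is deliberately omitted: at the problem
sizes this package targets (hundreds of patches, small nets) plain
ReLU + Adam trains stably, and BN's distinct train/eval statistics would
complicate the determinism guarantees for no measured benefit in the
recovery runs. Convolutions are implemented by im2col — patch extraction
into a matrix and one matrix product — with the index tables cached per
shape; the backward scatter reuses the same tables.

## The synthetic scene generator

The generator exists because the original scanner data are not publicly
available. It renders, analytically per pixel, a flat tray scene: seeds as
filled ellipses (default 40 × 20 px, area ≈ 628 px — comfortably inside the
250–1500 px component filter) on a 6 × 4 trough grid, a constant-0.5 panel
strip, and twelve 5-px-radius fiducial disks of reflectance 0.9 along the
tray borders. The SWIR frame is the same continuous scene evaluated through
a known VNIR→SWIR homography on the coarser grid (default scale 0.5/0.48
with a (3.2, −2.4) px translation, emulating the sensor offset; projective
terms default to zero but are settable). For pure scale+translation
transforms the SWIR frame dimensions are exactly the scaled VNIR dimensions,
so the naive resampling baseline's dimension ratio equals the true scale and
its error isolates the translation, as intended.

Seed reflectance follows
`base(λ) · dips(λ) · (1 − α·(p − 7.69)/11.96)` with α = 0.35: a smooth
spline base curve rising through the visible into the NIR, multiplicative
Gaussian moisture dips at 1450 and 1950 nm, and a multiplicative protein
link. Only the qualitative structure is sourced — higher protein means lower
reflectance at every band, and the lowest-protein (highest-moisture) seeds
show the deepest absolute dips — so the functional form, α, and the dip
depths are simulator choices, documented here and configurable. Because the
link is multiplicative and the base curve satisfies the five-band
segmentation rule with margin, every protein level remains segmentable. The
tray has a slight downward spectral tilt so the B1 < B2 condition fails
robustly on background even under noise. Noise is i.i.d. Gaussian per pixel
and band (default sd 0.01 reflectance units), clipped at zero.

Ventral vs dorsal orientation is exposed as an `orientation_contrast` knob
(dorsal faces 3% brighter by default) rather than a claimed physical model —
no quantitative ventral/dorsal difference is available to emulate.

What the simulator does **not** emulate: BRDF and edge-scattering physics,
crease topography and within-seed texture, spatially correlated sensor
noise, wavelength-dependent blur, and per-sample (rather than per-seed)
ground-truth granularity. Passing tests therefore demonstrate that the
pipeline's machinery is correct and self-consistent, not that the published
accuracy figures transfer; the published headline numbers (R² 0.77 RF, 0.82
classification accuracy) were obtained on unreleased real data and are
mirrored here only qualitatively (monotone-link recovery, method orderings).

## Problem sizes used in tests and the acceptance script

The packaged runs are scaled for a desk machine, as a package design choice:
scene pairs use 60 VNIR / 72 SWIR bands (full 300/362-band cubes are
supported but slower to render), and the model-recovery runs use 400
standalone simulated seeds, 16 × 16 patches, K = 8 components, the compact
kernel set, and 30 epochs. Under those conditions the held-out random forest
reaches R² ≥ 0.9, the regression CNN R² ≥ 0.5, and the classification CNN
≥ 0.8 accuracy on well-separated classes, each with fixed seeds; the
acceptance script recomputes all of these from scratch.

## Known limitations

* `resample_naive()` implements exact area averaging; for non-integer scale
  factors the box sums are computed via a bilinearly interpolated integral
  image, which differs from some library implementations in the last
  fractional pixel.
* The RANSAC estimator targets scale+translation-dominated transforms;
  rotation-rich or strongly projective registration is out of scope, as is
  automatic tie-point detection.
* Variant 3 at full 662-band resolution materializes ~219k columns; use the
  reduced variants or a band stride on desk machines.
* The CNN is a faithful, seeded CPU implementation; it is not optimized for
  GPU-scale sweeps, and determinism is guaranteed only single-threaded.
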