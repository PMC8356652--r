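---
title: "Self-learning segmentation of brain MR slices: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-learning segmentation of brain MR slices: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements: the
models, the parameters that matter, the design choices made where the design
was genuinely open, and what the synthetic tests do and do not demonstrate
about real magnetic-resonance data.

## The pipeline

A single grayscale slice travels through five stages:

1. **Adaptive bilateral filter** — edge-preserving denoising
   (`adaptive_bilateral_filter()`).
2. **Fuzzy-entropy threshold** — a global intensity cut used by the
   likeliness model and reported as a run statistic (`fet_threshold()`).
3. **Region-count selection** — the first HARIS phase: sweep candidate
   region counts, score each refined partition, pick the plateau
   (`select_k()`).
4. **Region assembly** — the second HARIS phase: intensity classes refined
   by Lloyd reassignment around per-region local-best feature pixels
   (`haris_segment()`).
5. **Tumor classification** — either the adaptive structural-similarity
   (ASSI) correlation index against a tumor reference patch, or the
   fuzzy-membership reassignment variant (`classify_pixels()`,
   `fuzzy_segment_refine()`), restricted to a geometric brain mask.

A run optionally appends its choices (region count, threshold, class
profile, reference patch) to an **experience store**; later runs warm-start
from that store. `run_pipeline()` wires the stages together and
`metric_report()` scores the result against ground truth when one exists.

```{r}
library(slns)
ph <- generate_phantom(phantom_spec(seed = 1))
cfg <- run_config(haris = list(k_min = 2, k_max = 8))
rep <- run_pipeline(ph$image, ph$labels, cfg)
rep$k; rep$fet_threshold; rep$metrics$dice
```

## Adaptive bilateral filter

Each output pixel is a fuzzy-weighted centroid of its `(2r+1)^2`
neighbourhood. A neighbour at spatial distance `d` with intensity difference
`delta` receives membership

```
c = exp(-d^2 / (2 r^2)) * P(same class | delta)
```

raised to the fuzzifier exponent `x` (default 2), and the centroid is
`sum(c^x * i) / sum(c^x)` — the pixel-belongingness form. The second factor
is a Bayesian posterior (`pixel_likeliness()`): same-class intensity
differences are modelled as `N(0, sqrt(2) * sigma_n)` with `sigma_n`
estimated robustly from the Laplacian residual (`estimate_noise_sd()`),
different-class differences as uniform over the 0–255 range, and the
same-class prior as the probability that two random pixels fall on the same
side of the fuzzy-entropy threshold split. Working on the intensity
*difference* keeps the factor a function of `|i_x - i_y|`, which is what
makes the filter edge-stopping: a 110-versus-220 boundary contributes
essentially zero cross-class weight, so the skull/brain gradient survives
filtering (the suite asserts at least 50% of the clean-twin gradient).

The center pixel's own intensity is replaced by a **contra-harmonic
brightness target** `sum(i^2) / sum(i)`. A plain window target mixes
cross-class intensities at strong edges and creates halo bands, so the
target is the same-class-weighted contra-harmonic mean of the neighbours,
blended with the plain-window value through a small fallback mass
(`w0 = 0.5`): when a pixel has no same-class neighbours at all — an isolated
impulse — the plain contra-harmonic target takes over and the impulse is
pulled toward the window's brightness, which is exactly the impulse-
suppression role of the contra-harmonic mean. Constant images are exact
fixed points of the whole construction.

Defaults: `window_radius = 3`, `passes = 2`, `fuzzifier_x = 2`. Two passes
of the radius-3 filter reduce the residual deviation from a noise-free twin
by roughly an order of magnitude at noise SD 5 while preserving edges;
the deeper smoothing is what makes both the region-count elbow and the
similarity-index classification sharp.

## Fuzzy-entropy thresholding

`fet_threshold()` scans all 254 interior cuts and scores each with a
histogram-weighted fuzzy-entropy statistic; ties break toward the smaller
cut. The default `"entropy"` form assigns every intensity a membership to
its own side of the cut, `mu = 1 / (1 + |i - mu_side| / 255)` with
`mu_side` the side's mean intensity, and minimizes the weighted binary
Shannon entropy (base 2) of those memberships: pixels near their class mean
are crisp, so the minimizing cut separates the intensity modes. Two
alternative forms are kept: `"printed"` — a difference of the two sides'
`mu log2 mu` sums over complementary logistic memberships centred at the
candidate cut (slope 8 intensity units), maximized — and `"sum"`, the
conventional total fuzzy entropy, minimized. The logistic-membership forms
depend on the data only through the histogram weights and behave
degenerately on skewed histograms (they park the cut at a histogram end or
flush against a mode), which is why the class-mean form is the default; the
behaviour is documented by the delta-mass and bimodal tests.

`interclass_variance()` is the classical between-class (Otsu-form) variance
`w1 w2 (mu1 - mu2)^2` of a two-way split, and `intraclass_correlation()` is
the homogeneity ratio `sigma_s^2 / (sigma_s^2 + sigma_i^2)`; both feed the
region-count fitness below. A separate bookkeeping identity relating
successive between-class variances is implied by the two-phase design but
adds nothing operational, so only the explicit form is implemented.

## HARIS region-count selection and assembly

**Phase 2 first, since phase 1 reuses it.** `haris_segment()` partitions
the 256-bin intensity histogram into `k` contiguous classes with an exact
dynamic program (contiguous clusters are optimal in one dimension), then
runs Lloyd reassignment to convergence — the optimum is already a Lloyd
fixed point, so the within-class deviation trace is short and
non-increasing, which the suite asserts. Labels 1..k are ordered by class
mean. Each region's **local-best feature pixel** is the member whose
intensity minimizes the mean absolute deviation to the region — the member
nearest the region median, first in row-major order on ties. Regions are
intensity classes and may be spatially disconnected; no spatial
connectivity is enforced, matching the intensity-driven design.

**Phase 1.** `select_k()` scores each candidate k by the weighted fitness

```
score(k) = [wx * norm(between-class variance) + wy * norm(1 - mean intraclass correlation)] / (wx + wy)
```

with both terms min-max normalized over the sweep (the raw ratios differ by
orders of magnitude, so normalization makes the two weights commensurable).
Both terms are non-decreasing in k, so a bare argmax would drift to `k_max`
on noisy data; the "ties break toward smaller k" rule is therefore
generalized to a **plateau rule**: the smallest k whose score is within
`plateau_tol` (default 0.02) of the sweep maximum. On a clean four-class
phantom the score plateaus exactly at k = 4; with noise the plateau begins
within one of the true class count, which is the recovery contract the
acceptance suite checks. The weights default to `wx = wy = 0.5`. `k_min`
defaults to 23 — the stated prior for full-resolution clinical slices —
but the few-class phantom studies use `k_min = 2`; both are plain config
fields.

`haris_objective()` exposes the raw plug-in fitness
`wx * Tot_pix / pix_seg + wy * T_s / N_r` for the hand-worked fixtures and
the monotonicity property.

## ASSI classification

`assi()` is the familiar luminance/contrast/structure product with the
standard stabilizers (`C1 = (0.01*255)^2`, `C2 = (0.03*255)^2`,
`C3 = C2/2`), reweighted by a noise-confidence factor
`omega = sigma_p^2 / (sigma_p^2 + sigma_e^2 / 2)`. The first argument is
the *reference* window: omega measures whether the reference's structure
rises above the noise floor, so it is a shared factor across candidates and
never inverts a comparison by the candidate's variance luck. All exponents
default to 1 (the classical product); `sigma_e` defaults to the
Laplacian-residual estimate.

`classify_pixels()` applies the `CI > Threshold` rule two ways:

* **Region mode** (the pipeline default): one representative interior
  window per region — cut at the member nearest the region median whose
  whole window lies inside the region, so representative patches never
  straddle a boundary — and the whole region is classified at once. The
  decision threshold defaults to an adaptive midpoint between the dominant
  (most populous) region's CI and the maximum region CI, which is robust to
  the multiplicative wobble of the structure and noise factors. A slice
  with no tumor-like region yields an empty mask because the dominant
  region is itself the maximum; slices genuinely lacking any outlier class
  should be run with an explicit `ci_threshold`.
* **Pixel mode**: a sliding-window CI map against the reference,
  thresholded per pixel. The window defaults to 3 because a window of side
  `w` erodes a blob boundary by `(w-1)/2` pixels; at the smallest study
  tumors (radius 8) anything wider costs more Dice at the boundary than it
  gains in stability.

The cold-start (bootstrap) reference is the region whose mean deviates most
from the dominant region's mean inside the brain mask — an explicit
artifact policy for the first run, replaced by the experience store's
patch afterwards.

The **fuzzy-membership variant** reads the membership adjustment
`vertex - (vertex - i) / (1 - mem)` as a homogeneity-scaled distance
`|i - vertex| / (1 - mem)` with `mem` the region's intraclass correlation,
reassigns pixels to the nearest vertex under that distance, and moves each
vertex by `vertex + (J' - vertex) / (1 - mem)` with `J'` the new region
mean. The tumor region is then chosen by the same most-deviant rule.

The **brain mask** is geometric: the most populous intensity class with no
pixels on the image border is taken as parenchyma and its hole-filled
extent is the mask, so enclosed tumor blobs are inside while skull,
background and filter transition bands are outside. A patch classifier
(below) can supply a learned non-brain exclusion instead, but the default
pipeline stays geometric and deterministic.

## The self-learning layer

The trainable component is deliberately small: a dense one-hidden-layer
rectifier network on flattened fixed-size patches, squared-error cost
`||f(i) - j||^2 / 2`, errors backpropagated as
`(W^l)^T e^(l+1) * f'(x^l)`, plain gradient descent (default learning rate
0.01, no momentum — the saturation behaviour of richer optimizers is not
part of the contract), deterministic for a fixed seed. Backpropagation is
verified against central-difference gradients to 1e-5 relative error. The
convolution/pooling/recurrent stack that a full-scale implementation would
wrap around this is out of scope here: only the cost, error and activation
rules are specified tightly enough to implement and test.

The **experience store** is an append-only JSON-lines file. Each record
holds the run id, chosen k, threshold, per-class intensity profile and the
tumor reference patch as a base-16 payload at 1/100-intensity precision —
integer quantization can flatten a denoised patch to a constant, whose
zero variance would zero the confidence factor, so sub-integer texture is
preserved deliberately. The warm-start prior is the running mean of stored
k and threshold plus the most recent patch; an empty store means the
pipeline runs cold, and a stored patch that is degenerate (zero variance)
or mismatched in size is ignored in favour of the bootstrap rule. The
store is never rewritten; corruption is reported with the offending line,
never silently reset.

## Metrics

`confusion()` counts pixels; `metric_report()` derives sensitivity,
specificity, accuracy, Jaccard similarity and the Matthews correlation
coefficient, returning `NA` plus an `undefined` flag when a denominator
vanishes (never a silent zero). `tumor_burden()` counts the tumor-core and
enhancement-rim classes with whole tumor = core + rim. On real images an
enhancement rim requires a contrast-enhanced channel; the phantom rim class
gives those semantics a testable geometric meaning (a dilation band around
the core).

## The phantom generator

`generate_phantom()` emulates a single axial brain slice: dark background
(mean 10), bright skull annulus (220), mid-intensity parenchyma (110), one
or more bright tumor disks (190) with an optional dilation-band enhancement
rim (240), plus clipped additive Gaussian noise rounded to 8 bits. Geometry
is circles and annuli only, so exact area oracles are trivial; truth labels
are the noise-free geometry. `phantom_suite()` jitters tumor contrast
(±10), radius (inside 8–16 pixels) and count (a 30% chance of a second
tumor) from one seeded stream. The study conditions — 128×128 pixels,
noise SD 5, one tumor — are the generator defaults; they echo the
brain-110/tumor-190 intensity layout used throughout the threshold
examples.

What the phantoms do **not** emulate: MRI physics (bias fields, Rician
noise, partial-volume effects), anatomical texture, irregular tumor
margins, or multi-slice context. Passing the synthetic suite therefore
demonstrates the internal correctness and mutual consistency of the
stages — exact formula fixtures, oracle-equivalent threshold scans,
recovery of known geometry under Gaussian noise — not clinical accuracy.
Published full-scale results on clinical cohorts are measured under
conditions this desk-scale artifact deliberately does not reproduce.

## Numerical choices and degenerate inputs

* Intensities are clipped to \[0, 255\]; all internal math is double
  precision; 8-bit quantization happens only at generation and file I/O.
* Threshold scans are exhaustive over the 254 interior cuts — no
  optimization shortcuts — and tie-break toward the smaller cut.
* The region-count sweep is clamped when an image has fewer distinct
  intensities than `k_min` (warning), and duplicate centroids merge when k
  exceeds the distinct-intensity count (warning).
* An all-zero filter window returns 0 from the contra-harmonic mean by
  convention; an empty split side contributes 0 between-class variance.
* Zero total evidence in the Bayesian posterior returns the uniform
  posterior with a warning; all-zero memberships in the belongingness
  centroid are an error naming the cause.
* Every stochastic component (generator, suite jitter, network
  initialization) draws from a local seeded stream via `withr::with_seed`,
  so library calls never disturb the caller's RNG and identical
  configuration plus store state reproduce bit-identical masks and reports.

## Known limitations

* Single 2-D slices only; volumes must be sliced explicitly.
* DICOM files are not read; convert to NIfTI or PNG first.
* The adaptive classification threshold assumes at least one outlier
  region inside the brain mask; tumor-free slices need an explicit
  threshold to report "no tumor".
* Regions are intensity classes: spatially separate lesions of similar
  intensity share one region (their union is still the tumor mask).
* The experience prior carries a single reference patch; it helps when
  consecutive slices resemble each other and is ignored (bootstrap) when
  unusable, so it can equal — but by design never undercut — the cold
  start by more than the tested margin.
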