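---
title: "Quantifying myotube fusion, size and fiber type with myofuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying myotube fusion, size and fiber type with myofuse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myofuse)
```

## The assays

myofuse automates three image-based readouts of skeletal-muscle biology:

1. **Fusion index (FI).** In a myoblast differentiation assay, cells are
   stained for DNA (DAPI, the "blue" channel) and myosin heavy chain (MHC).
   The FI of a field is the fraction of all nuclei lying within *qualified*
   myotubes — MHC-positive objects containing at least a minimum number of
   nuclei (default 3). Field FIs are averaged, unweighted, into one value
   per well; the assay convention is four fields per well.
2. **Myotube diameter.** The mean diameter of long, multinucleated
   myotubes, measured along the medial axis and skipping regions where
   nuclei cluster. This automates what is classically a manual caliper
   measurement in ImageJ.
3. **SDH fiber typing.** Succinate-dehydrogenase histochemistry stains
   oxidative fibers darker. Per-fiber mean optical density
   (OD = log10(I0/I)) is thresholded into oxidative vs glycolytic classes,
   and section-level fractions are reported.

A synthetic image generator with exact ground truth, and the group
comparison statistics used to report such assays (percent change, Student's
t with an F-test fallback to Welch's t), complete the toolbox.

## The nuclei segmentation chain

`segment_nuclei()` composes six steps in a fixed order, each exposed as its
own function:

| step | function | default |
|---|---|---|
| background subtraction | `subtract_background()` | 5th percentile |
| smoothing | `smooth_image()` | Gaussian, sigma 1.2 px |
| thresholding | `binarize()` | exact Otsu (or adaptive local mean) |
| cleaning | `clean_mask()` | fill holes <= 64 px, open with disk r = 1 |
| splitting | `separate_touching()` | distance-transform watershed |
| size gate | `filter_by_size()` | keep 30--5000 px |

Design notes, in order:

* **Percentile estimator.** Sorted-order statistic with linear
  interpolation (`quantile()` type 7), the common convention.
* **Boundary handling.** All convolutions reflect-pad the image. A zero or
  replicate pad darkens the rim, which a *global* Otsu threshold would feel.
* **Exact Otsu.** `otsu_threshold()` maximizes the between-class variance
  over every distinct intensity — no 256-bin histogram — and returns the
  midpoint of the optimal gap, so the threshold lies strictly between the
  two classes and `>` vs `>=` cannot disagree. Intensities are kept on
  their native 8/16-bit scale throughout: every step in the chain is
  covariant under intensity scaling, so no normalization is applied or
  needed.
* **Blank-field guard.** A global Otsu split *always* produces a
  "foreground", even on a field of pure noise, where it simply cuts the
  noise distribution in half. The pipeline therefore checks Otsu's
  separability measure (between-class variance over total variance). A
  unimodal Gaussian cannot exceed 2/pi (about 0.64) on this measure,
  while fields with genuine staining measure near 0.9; below the
  configurable floor (`min_separability`, default 0.75, the midpoint of
  those two regimes) the field is declared blank with a warning and yields
  zero objects. The guard lives in `segment_nuclei()` / `segment_myotubes()`,
  not in `binarize()`, which stays a pure Otsu partition.
* **Cleaning.** Hole filling is area-capped (only holes up to
  `hole_max_area` are closed) so genuinely perforated debris is not
  consolidated; the opening removes single-pixel specks and shaves halo
  spurs. The published chain states only that "morphological operations"
  were used, so the operations, order and structuring element here are
  documented defaults, not reconstructed facts.
* **Watershed.** Seeds are regional maxima of the Euclidean distance
  transform after suppression of maxima shallower than 1 px (h-maxima
  depth 1). The `watershed_min_distance` parameter (default 7 px, an
  expected nucleus radius) is the center-to-center distance below which
  seeds merge; the implementation's maxima-detection neighborhood radius is
  therefore half that distance, since two seeds are distinct exactly when
  neither lies in the other's neighborhood. Ties resolve by deterministic
  scan order; the module contains no randomness.
* **Size gate last.** Filtering runs after the watershed so that debris
  judgments apply to final objects. Whether the original processing
  filtered before or after splitting is not documented; doing it last is
  the conservative choice (a clump that splits into valid nuclei is kept).

## Myotube segmentation and the qualification rule

The published description covers only the nuclear channel; the MHC mask
construction is undocumented. The package's default — smoothing at sigma
2 px, global Otsu, hole filling (myotubes enclose dark nuclei), and a
500 px minimum object area — is an implementation choice, exposed through
`myotube_sigma` and `myotube_min_area`.

"Intersecting" is likewise undefined for nucleus-tube assignment, so two
rules are provided. The default **centroid rule** assigns a nucleus to the
tube under its centroid pixel: insensitive to boundary halo, never
double-counts. The **overlap rule** assigns it to the tube covering at
least `overlap_fraction` (default 0.5) of its area, largest overlap
breaking ties. The rules agree exactly whenever every nucleus is entirely
inside or outside every tube — a property the synthetic generator enforces
on its ground truth, and the test suite checks.

A field with zero detected nuclei raises an error rather than reporting
FI = 0; silently scoring empty fields would bias well means downward.

## Diameter measurement

`tube_diameter()` skeletonizes the tube mask (Zhang--Suen thinning,
implemented in the package) and samples the local diameter at each skeleton
pixel as twice the Euclidean distance to the nearest background pixel.
Two exclusions reduce bias:

* **End trimming.** Skeleton pixels within one local width of a skeleton
  endpoint are dropped; the medial axis bends toward end-cap corners and
  underestimates width there.
* **Clustered nuclei.** Skeleton pixels with two or more nucleus centroids
  within `exclusion_radius` (default 15 px, about 1.5 median nucleus radii)
  are skipped, mirroring the manual protocol's instruction to avoid such
  regions. A cluster changes where the tube is sampled, not the width
  reported — the test suite checks this on a rectangle with an implanted
  cluster.

Reported diameters are exactly covariant with `pixel_size`. On rasterized
ribbons at general orientations the estimator is accurate to well under
1%; an axis-aligned rectangle can pick up at most about one pixel of
rasterization overshoot. Tubes enter the condition summary only when
"long" (skeleton at least `min_skeleton_length`, default 100 px) and
"multinucleated" (at least `diameter_min_nuclei`, default 2).

Percent-change conventions differ across published diameter summaries; when
a printed percentage does not match the control-baseline arithmetic of its
own printed means, `percent_change_both()` reports the control-baseline and
symmetric (mean-baseline) figures side by side rather than guessing.

## SDH optical density and fiber classes

`optical_density()` is plain absorbance, clamped at zero. The blank
reference `I0` defaults to the 99th intensity percentile of the image — a
proxy for unstained background when no blank region is declared; a
measured reference can be passed instead. Classification thresholds the
*per-fiber mean* OD: by default the exact Otsu split of the per-fiber
distribution, or a fixed threshold from the caller. Degenerate unimodal
distributions yield all-oxidative with a warning. Classification is
invariant to a common rescaling of `I` and `I0`, and raising a fixed
threshold can only shrink the oxidative fraction. Fiber boundaries are an
input (a labeled mask): fiber segmentation from membrane staining is a
solved problem with published tools and is out of scope here.

## The synthetic generator

`generate_field()` renders what the pipeline needs to be right about, and
nothing more: Gaussian-blurred disk nuclei of roughly uniform radius,
elongated ribbon myotubes, additive background plus Gaussian read noise on
both channels. Its ground truth is exact by construction:

* `round(true_fi * n_nuclei)` nuclei are placed *fully inside* tube masks,
  each populated tube receiving at least `min_nuclei_per_tube` (3) so the
  qualification rule is actually exercised;
* the remaining nuclei keep a 3 px clearance from every ribbon, so outside
  nuclei share no pixel with any tube and the two intersection rules are
  exact on the truth;
* an optional fraction of the outside nuclei is arranged as touching pairs
  at 1.4 mean radii center distance.

Placement is rejection sampling with bounded retries and a bounded number
of full re-layouts; infeasible geometry raises an error rather than
degrading silently. A master seed expands into per-field sub-seeds through
a fixed counter scheme, so wells are reproducible and fields independent.
Default conditions are a 1024 x 1024 px canvas with about 100 nuclei per
field — large enough for a stable Otsu histogram, small enough that a
four-field well processes in seconds. The default amplitudes
(background 200, noise SD 30, nucleus peak 2000, tube peak 1500 on a
16-bit-like scale) give a signal-to-noise ratio typical of a reasonably
exposed epifluorescence image.

**On touching pairs.** At 1.4 radii separation, two equal disks overlap
deeply; after any realistic point-spread blur, a threshold at the
half-intensity level renders their union as its convex hull (a stadium
shape), leaving *no* distance-transform saddle between the centers. Merged
pairs are therefore a property of the imaging model, not a watershed
defect — the watershed does split true dumbbell geometry, which the test
suite checks directly on analytic masks. At the default 10% touching
fraction the merged pairs amount to exactly the 5% counting-error envelope
the recovery tests allow.

**What the generator does not emulate:** uneven illumination, intensity
gradients within nuclei, chromatin texture, out-of-focus light, myotube
branching, or autofluorescence crosstalk between channels. Passing
recovery tests on this generator demonstrates the pipeline's arithmetic
and its behavior under noise and touching geometry — not robustness to
every artifact of real micrographs.

`generate_sdh_section()` tessellates the canvas into nearest-seed (Voronoi)
fibers, assigns classes with exact counts, draws per-fiber OD from two
well-separated modes (0.8 vs 0.25, within-class SD 0.05), and renders
intensities as `I0 * 10^(-OD)` plus pixel noise.

## Statistics

`students_t_two_tailed()` is the pooled-variance two-sample t;
`choose_and_run_test()` first runs a two-sided F-test of variance equality
at `variance_alpha` (default 0.05; the reporting convention behind it says
only that "variance was tested") and falls back to Welch's t with
Welch--Satterthwaite degrees of freedom when the F-test rejects. Identical
constant samples return t = 0, p = 1 by convention. Headline percentages
round half away from zero, matching how integer percent changes are
typically printed; base R's banker's rounding would turn -43.5 into -43
instead of -44. No multiple-testing correction is applied in this module.

## Numerical choices and degenerate inputs

* Images are matrices indexed `[row, col]`, 1-based as is natural in R;
  result tables report centroids in the same convention.
* Areas are reported in pixels; physical units only ever enter through
  `pixel_size` multiplication, so unit errors cannot compound.
* Otsu on a constant image warns and returns all-background.
* An empty tube mask, an all-excluded skeleton, fewer than two fibers, or
  a zero-nucleus field raise errors with specific messages.
* The watershed label count is non-increasing in `watershed_min_distance`;
  FI is non-increasing in `min_nuclei_per_myotube`. Both are tested as
  properties, not single examples.

## Problem sizes used by the verification suite

The test and acceptance runs use: 100 random images for the Otsu oracle
comparison; isolated-nuclei fields at k = 10/50/200 with five seeds each;
touching-pair fields at k = 100; fusion-index recovery on 20 wells per
true-FI level (0.25 and 0.45, mirroring a control/treated contrast) at the
default four fields of 1024 px; ribbon widths 10/17/24 px with five seeds;
and 100-fiber SDH sections at oxidative fractions 0.5 and 0.7. These sizes
give stable estimates while keeping a full run in the minutes range on one
CPU.

## Known limitations

* The MHC mask construction, the nucleus-tube intersection rule, the
  morphological cleaning details and the SDH binarization threshold are
  documented reconstructions, not published facts; all are configurable.
* Learned segmentation (e.g. cellpose-style models) is out of scope, as is
  anything 3-D or time-resolved.
* The blank-field separability guard assumes roughly Gaussian background
  noise; heavy-tailed noise could sit above the floor.
* Absolute published values (FI 44.4%/25.2%, diameters 17.1/12.6 um,
  oxidative fractions 74.5%/69.9%) depend on the original micrographs and
  are not reproducible from synthetic data; the suite verifies the
  *computations* on inputs with known truth, plus the percent-change
  arithmetic on the printed group means.
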