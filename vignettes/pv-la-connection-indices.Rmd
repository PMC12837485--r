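---
title: "Quantifying the fetal PV-LA connection: methods and design notes"
author: "pvla package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the fetal PV-LA connection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvla)
```

## The problem

In a normal fetal heart the pulmonary veins (PV) drain into the left atrium
(LA); in total anomalous pulmonary venous connection (TAPVC) that junction is
absent and the veins join a confluent channel behind the LA instead. On
prenatal ultrasound the junction is small and hard to see, which is one
reason TAPVC is frequently missed before birth. When the PV and LA have been
segmented on a sweep-scan video - a stack of sequential 2D cross-sections
treated as the depth axis of a 3D label volume - the spatial relationship of
the two labeled structures can be quantified directly, turning "is there a
junction?" into two numbers per video that can be screened with a threshold.

`pvla` implements that quantification: two connection indices (PLD and PLA),
the segmentation-quality metrics used to vet the masks feeding them (Dice,
HD95), a ROC/AUC screening stage over two-group cohorts, and a voxel-phantom
generator so the entire pipeline is testable without clinical data.

## The indices

Volumes are integer label grids in (depth, height, width) order with one
label per voxel: 0 background, 1 LA, 2 PV, 3 confluent vein. Because a voxel
carries exactly one label, PV and LA pixel sets are disjoint by construction.
All computations below are per depth slice, restricted to the *shared-slice
set* $K$: slices containing at least one PV pixel and at least one LA pixel.

**PLD (PV-LA distance, pixels).** For each $k \in K$, let $d_k$ be the
minimum in-plane Euclidean distance over all PV x LA pixel pairs of slice
$k$, giving the distance set $D$. With $t_q$ the bottom-$q\%$ percentile of
$D$, the retained subset is $D_q = \{d \in D : d \le t_q\}$ and

$$\mathrm{PLD} = \frac{1}{|D_q|} \sum_{d \in D_q} d.$$

Disjoint sets on an integer grid are at least 1 px apart, so the index floor
is exactly 1.00 and a PLD of 1.00 means every retained slice contains an
edge-adjacent PV/LA pixel pair - a connection. Larger values mean the
structures diverge. Distances are strictly 2D within a slice (never across
slices) and in isotropic pixel units; voxel-spacing metadata is read but not
applied, so reported values stay in the pixel units the index is defined in.

**PLA (PV-LA angle, degrees).** For each $k \in K$, take the centroids
$G_{P,k}$, $G_{L,k}$ of the PV and LA pixel sets and the major axis of the
moment-equivalent ellipse of the PV (the principal eigenvector of the 2x2
second central-moment matrix of its pixel coordinates). The raw angle
$\theta_k \in [0, 180]$ between the centroid line $G_{P,k}G_{L,k}$ and the
axis is folded as $\tilde\theta_k = \min(\theta_k, 180 - \theta_k)$, because
an axis has no preferred sign. PLA is the mean of $\tilde\theta_k$ over the
non-degenerate slices of $K$ and ranges 0-90. Small values mean the LA sits
along the PV's own direction (the draining geometry); values near 90 mean
the PV lies broadside to the LA.

Both indices are elevated in TAPVC, so both are used with the fixed decision
direction "higher = more likely TAPVC" in the screening stage.

## Tunable parameters

* `q` (percent, default **100**): the bottom-percentage of per-slice
  distances retained by the PLD. The definition leaves $q$ free; 100 - use
  every shared slice - is the least-assuming default and makes the
  "touching in (nearly) all shared slices implies PLD = 1.00" reading exact.
  Every result records the `q` used, so sensitivity analyses are a loop over
  `computePLD(v, q = ...)`.
* `rule` (default **"linear"**): the percentile convention behind both
  $t_q$ and the HD95 percentile, centralized in `pvQuantile()`. "linear" is
  linear interpolation between order statistics (`stats::quantile` type 7);
  "nearest-rank" (type 1) is available as the common alternate. The rule
  name is carried in every result.
* `mergeVein` (default **TRUE**): the confluent-vein label (3) is treated
  as PV-class for index computation, since in TAPVC the confluent vein is
  the PV-side structure; `FALSE` keeps it separate.
* Degeneracy tolerances: a PV region has no unique major axis when the two
  moment eigenvalues agree within a relative 1e-9 (e.g. filled squares or
  circles); centroid coincidence uses the same 1e-9 px tolerance. Cosines
  are clamped to [-1, 1] before `acos`. Degenerate slices are excluded from
  the PLA mean and listed per-slice with reasons; a volume whose every
  shared slice is degenerate raises a distinct error rather than reporting
  a number.

## Segmentation metrics

`diceCoefficient()` is the voxelwise overlap $2TP / (2TP + FP + FN)$ over
the whole volume, per structure or on the PV+LA aggregate mask. A doubly
empty comparison (0/0) raises an undefined-metric error instead of an
arbitrary value. `hd95()` extracts surface voxels (foreground voxels with a
background 6-neighbor; volume borders count out-of-bounds as background),
pools the two directed nearest-surface distance sets $D_{P \to G} \cup
D_{G \to P}$, and takes the 95th percentile of the pooled union - one
percentile of one set, not the max of two per-direction percentiles - which
makes it symmetric by construction and bounded above by the exact Hausdorff
distance (`hausdorffDistance()`, tested as an invariant). Distances are 3D
Euclidean in voxel units. Group summaries report mean Dice two ways, labeled
distinctly: on the aggregate mask (`PV_LA`) and as the mean of the
per-structure values (`PV_LA_structure_mean`), since either reading of a
per-video "mean Dice" is defensible.

## Screening

`rocCurve()` sweeps thresholds over the observed index values with TAPVC as
the positive class. The AUC is the trapezoidal integral of TPR over FPR and
is cross-checked *on every call* against the tie-corrected Mann-Whitney
statistic $U/(n_1 n_2)$ (ties counted one half); disagreement beyond 1e-12
is an internal error. The decision direction is fixed a priori, not
estimated from data, so a model that inverts the clinical relationship
yields AUC < 0.5 rather than being silently flipped. `groupSummary()` gives
the mean +/- sample SD "standard values" per group; `maeVsGroundTruth()`
the per-case mean absolute error of model indices against ground-truth
indices. When several sweep videos map to one case the screening table
aggregates per case by the mean (one screening decision per fetus);
per-video tables are available via `buildScreeningTable(unit = "video")`.
No confidence intervals are attached by default; a seeded stratified
bootstrap is available in `aucBootstrapCI()`.

## The phantom generator

`generatePhantom()` draws, per slice, a filled-ellipse LA and a thin
PV bar whose moment major axis runs along the column direction, with the LA
present in every slice and the PV in a central band of `sharedSlices`
slices. The LA center is chosen by a deterministic lexicographic search
over integer offsets so that (a) the nearest PV-LA pixel distance matches
`gap + 1` - exactly edge-adjacent when `gap = 0`, within +/- 0.45 px
otherwise - and (b) the centroid-line bearing matches `angle`. Because both
shapes are symmetric on the grid, their centroids are exact and the realized
angle equals the bearing of an integer vector of length roughly 20 px, so
discretization error stays below about 1.5 degrees; the tests measure this
rather than assume it. With `vein = TRUE` a confluent-vein blob (label 3)
coaxially extends the PV away from the LA, and gap and angle are realized
for the merged PV-class structure - the same reading the indices use by
default. Boundary jitter flips boundary voxels with the probability that a
normal deviate of scale `jitterSd` exceeds half a pixel, adding or removing
pixels symmetrically so the expected geometry is unbiased; `jitterSd = 0`
is the exact-geometry mode every analytic test uses.

`generateCohort()` draws per-video gap/angle values from stated per-group
distributions. The defaults are the study conditions the package emulates:
normal videos at gap 0 (connection present) with angles around
37.8 +/- 7.72 degrees, TAPVC videos at gaps around 1.64 +/- 0.667 px
(putting PLD near 2.64 +/- 0.667) with angles around 55.1 +/- 14.5 degrees,
truncated to their legal ranges, 6 cases x 2 videos per group. These were
fixed once from the clinical standard values and are not tuning knobs.
Per-video seeds derive deterministically from one master seed, so cohorts
are byte-identical across reruns.

What the phantoms do **not** emulate: grayscale ultrasound appearance,
speckle, shadowing, fetal cardiac motion, anisotropic voxel spacing, or the
error structure of a real segmentation network (handled only coarsely by
`perturbMask()`'s erosion/dilation/translation/slice-dropping). Passing
tests therefore demonstrate that the indices, metrics and screening stage
compute their definitions correctly and recover constructed geometry; they
do not demonstrate clinical screening performance on real videos.

## Numerical and design choices

* **Subset inclusion is $d \le t_q$**, not strict inequality: a strict rule
  would return an empty subset for a constant distance set, which the
  retained-subset-never-empty property forbids.
* **Surface connectivity is 6-neighborhood** (face neighbors), the common
  voxel-surface convention; stated in outputs rather than configurable.
* **Label overlap is rejected, not zeroed**: in the canonical one-label
  encoding PV/LA overlap cannot occur; an input dialect presenting overlap
  fails validation rather than defining a zero distance, which would break
  the PLD floor of 1.00.
* **Axis convention**: NIfTI files map their slowest-varying axis to depth
  (the sweep direction) by default, with an `axes` override; slice `k` of a
  volume equals image `k` of the PNG-directory dialect. Volume shape is not
  constrained to any fixed acquisition size.
* **Errors are classed conditions** (`pvlaValidationError`,
  `pvlaNoSharedSliceError`, `pvlaUndefinedMetricError`, ...), so batch
  drivers can record per-volume failures and continue; undefined metrics
  are never silently coerced to 0.
* Test problem sizes: phantoms of 16 x 96 x 96 voxels (8 shared slices) for
  analytic checks, random masks under 500 voxels for the brute-force oracle
  comparisons, and 50 + 50-video cohorts at 8 x 72 x 72 for the screening
  behavior suite - small enough to run the whole suite in a couple of
  minutes while exercising every code path at meaningful scale.

## A worked run

```{r example, eval = FALSE}
library(pvla)

## a connected (normal) and a diverged (TAPVC-like) phantom
normal <- generatePhantom(phantomConfig(gap = 0, angle = 35, seed = 11))
tapvc  <- generatePhantom(phantomConfig(gap = 4, angle = 60, vein = TRUE,
                                        seed = 12))
computePLD(normal)   # 1.0000 px : junction present
computePLD(tapvc)    # 5.0000 px : 4 px divergence + 1 px adjacency floor
computePLA(tapvc)    # ~58.8 deg : PV broadside behind the LA

## a default 6 + 6-case cohort, indices, and screening
outDir <- tempfile()
res <- generateCohort(cohortSpec(seed = 20260101), outDir = outDir)
idx <- indexCohort(loadCohort(file.path(outDir, "cohort.csv")))
tab <- buildScreeningTable(idx)
groupSummary(tab)
rocCurve(tab, "ground_truth", "PLD")  # AUC 1.0 on this geometry
```

## Known limitations

* The PLA is undefined for isotropic PV regions; real near-circular PV
  cross-sections would be excluded slice-wise, and a video made entirely of
  them raises an error by design.
* Indices are 2D-per-slice by definition; a PV approaching the LA purely
  along the sweep direction is invisible to them.
* Pixel units assume in-plane isotropy; strongly anisotropic acquisitions
  would need the (deliberately unimplemented) spacing-weighted variant.
* The generator's discretization bounds (+/- 0.45 px on gap, ~1.5 degrees
  on angle) are properties of the integer grid, not of the indices; they
  set the resolution at which parameter-recovery tests can assert equality.
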