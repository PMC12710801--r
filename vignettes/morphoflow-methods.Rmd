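---
title: "Quantifying epithelial tissue fluidity and branching: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying epithelial tissue fluidity and branching: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphoflow)
```

## Scope

morphoflow quantifies how an epithelial tubule — typified by the branching
ureteric bud (UB) of the embryonic kidney — moves, rearranges and branches,
from 3D time-lapse volumes and cell-tracking tables. Four analysis families
are covered: coarse-grained 3D velocimetry with motion-similarity
coherence, cell-cluster dispersal statistics with trend-comparison
inference, tubule morphometry, and skeleton-based counting of branching
tips. Because raw embryonic-kidney movies are large and rarely shared, the
package ships a synthetic-data module that generates every input with
stored ground truth; all tests and the worked examples run on synthetic
data alone.

## Coarse-grained 3D velocimetry

`compute_piv()` estimates a displacement field between consecutive volumes
by classical window correlation. Interrogation windows of
`(32, 32, 7)` voxels in (x, y, z) are tiled with overlaps `(8, 8, 3)`; the
flat z window reflects stacks ~50 µm deep sampled at 1 µm where z is far
coarser than x/y. Each window is matched against a search region extended
by a margin of `(10, 10, 3)` voxels in the second frame.

Numerical choices:

* **Correlation estimator.** Zero-mean normalized cross-correlation. The
  normalization makes the estimator insensitive to the additive background
  and multiplicative intensity changes typical of fluorescence; the window
  sums over the search region come from 3D summed-area tables so the cost
  per lag is one multiply-add per voxel.
* **Sub-voxel refinement.** Separable 3-point Gaussian fit per axis around
  the integer peak, falling back to a parabolic fit when a log of a
  non-positive correlation would be needed. When the integer peak is
  numerically perfect (r ≥ 1 − 1e−9, e.g. a noise-free integer shift)
  refinement is skipped: the match is already exact and refinement on a
  finite window would only add asymmetry noise.
* **Window validity.** Windows whose intensity variance is below 1% of the
  whole-frame variance (signal-free regions), or whose first-to-second
  peak ratio is below 1.2 (ambiguous matches), are marked invalid rather
  than guessed. This mirrors the manual exclusion of dim regions in the
  motivating experiments.
* **Boundaries.** Windows whose margin-extended search region does not fit
  in the volume are dropped, not padded; padding would bias boundary
  vectors toward zero.

`mean_speed()` is the arithmetic mean of vector norms over valid nodes
(px/frame; µm/min given a pixel size and frame interval).

## Motion similarity and coherence

Coordinated, persistent motion distinguishes a fluid-like epithelium from
a jammed one. `motion_similarity_map()` scores each grid node by the mean
scalar product of its velocity with its in-plane 4-neighbours (±x, ±y in
the same z slab; z neighbours are excluded by default because z sampling
is ~7× coarser — a 6-neighbour mode is available). Two modes exist
deliberately:

* **normalized** (default): vectors are unit-normalized first, so the score
  is a cosine in [−1, 1] measuring alignment only. Bounded scores support
  sharp acceptance tests and cross-dataset comparison.
* **raw**: the plain scalar product, which conflates alignment with speed;
  retained for fidelity to analyses that used raw vectors.

`coherence_profile()` summarizes a similarity map along `n` equidistant
lines parallel to the tissue's long axis, at cross-axis fractions
k/(n+1); each line reports the mean and SD of similarity over its nearest
grid nodes. Lines whose nodes are all invalid are reported missing, never
interpolated.

## Cluster dispersal and the standard distance

Cell rearrangement is measured by how small cell clusters disperse.
`identify_clusters()` reproduces the published selection rule: a
convergent point is a cell whose 15 px neighbourhood at the reference
frame holds at least 4 cells; clusters of 4–8 cells are drawn by seeded
random sampling without track reuse (overlap is off by default — the
source procedure is silent, and disjoint clusters keep the downstream
series independent).

Dispersal of a cluster is its **standard distance**

$$SD = \sqrt{\tfrac{1}{n}\sum_i (x_i-\bar X)^2 + \tfrac{1}{n}\sum_i (y_i-\bar Y)^2},$$

the root of the trace of the (denominator-n) covariance: translation- and
rotation-invariant, linear under uniform scaling. The accompanying prose
description of the statistic as a "geometric mean" of distances conflicts
with this printed formula; the formula is implemented. SD is computed in
the 2D analysis plane; z is carried but unused.

Trend inference follows the region's dynamics: trunk clusters over an
8-hour window are summarized by the OLS slope of SD against time
(px/min), tips over a 2-hour window by quadratic coefficients (a, b, c).
Group comparison:

* **Slopes (trunks):** "ANCOVA on the regression slopes" is implemented as
  the pooled slope-homogeneity interaction F-test — fit
  `SD ~ time * group` over all points and test the interaction against the
  additive model. The wording is ambiguous; the pooled interaction test is
  the standard reading and holds its nominal type-I error in simulation
  (checked at 2000 null replicates).
* **Coefficient vectors (tips):** two-sample Hotelling's T² with pooled
  covariance, F-converted on (p, n₁+n₂−p−1) degrees of freedom, pairwise
  across groups, with Benjamini–Hochberg adjustment (the specific FDR
  method was unstated; BH is the default convention).

Time is measured in minutes (frame × dt), so slope units are px/min and
quadratic leading coefficients px/min².

## Morphometry

`polygon_area()` (shoelace, with a segment-sweep simplicity check —
self-intersecting outlines are rejected, not repaired),
`relative_area_change()` (area(t)/area(t₀); 0.5 = 50% narrowing),
`division_angle()` (acute angle between the daughter-centroid line and the
tubule's long axis, in the 2D imaging plane, folded to [0, 90]°), and
`compare_diameter_distributions()` (group medians plus the two-sided
Mann–Whitney U test; exact for small tie-free samples, normal
approximation with tie correction otherwise).

## Tip counting

`count_tips()` re-implements the standardized FIJI recipe: maximum
intensity projection → background subtraction → Gaussian blur → threshold
→ binary mask → skeletonization → terminal endpoints = tips. Unreported
parameters were fixed as follows and are all configurable:

* background subtraction: grayscale opening; radius 50 px by analogy with
  the conventional rolling-ball default (a separable square structuring
  element approximates the ball at a fraction of the cost);
* blur σ = 2 px; threshold = Otsu (a fixed value can be supplied);
* components below `min_component_area` are dropped (default: keep the
  largest, since the UB is one connected structure);
* skeleton spurs shorter than 5 px are pruned. Pruning is a deliberate
  deviation — thinning artifacts otherwise inflate counts. The pruner
  walks from each endpoint and uses the neighbour-run (crossing) number to
  distinguish true junctions from 8-connectivity staircase corners, which
  a naive neighbour count misreads as junctions.

Endpoints are skeleton pixels with exactly one 8-connected neighbour.
Counts on real images are parameter-sensitive (the source parameters are
unreported), so correctness is established against synthetic trees with
graph-derived ground truth.

## The synthetic world

The generators state the package's test conditions; their defaults are
fixed once and are not tuned against test outcomes.

* **Flow movies** (`generate_flow_movie()`): Gaussian particles
  (σ = 1.5 px) at Poisson-random positions, density 0.01/voxel, advected
  through a prescribed field (uniform, rotation, shear, split, or
  incoherent jitter) with periodic wrap or boundary loss. Frames are
  re-rendered analytically from advected particle positions rather than
  warped by interpolation: sub-voxel motion is exact and interpolation
  blur cannot accumulate, while the advection postcondition (frame t+1 is
  frame t advected) still holds — for integer displacements with periodic
  wrap, exactly. Default geometry mimics the motivating stacks (z ~7×
  coarser than x/y, 10 min frame interval). Ground-truth fields are
  evaluated at the PIV node centres, and a displacement beyond the search
  margin is recorded as a provenance warning (PIV cannot recover it).
* **Cluster trajectories** (`generate_cluster_trajectories()`): each
  cluster's m cells sit equally spaced on a circle of radius r(t) equal to
  the prescribed SD(t) (linear a·t+b or quadratic a·t²+b·t+c), centred on
  a possibly drifting centroid, plus isotropic Gaussian jitter. Equally
  spaced points on a circle of radius r have per-axis variances summing to
  r², so with zero jitter the measured SD reproduces the target exactly —
  a closed-form acceptance surface (this is why circle placement was
  chosen over i.i.d. Gaussian placement). Default jitter 0.5 px, dt
  10 min. With jitter on, the measured SD is slightly inflated —
  E[SD] ≈ √(r² + 2σ²(m−1)/m) by the delta method — so recovery tests
  compare mean fitted coefficients against this expectation rather than
  the raw generating coefficients (the difference is ~σ²/r, i.e. a few
  thousandths of a pixel per minute at the defaults).
* **Trees** (`random_tree_spec()`/`generate_tree_image()`): segments
  rendered as anti-aliased thick bars, blurred, with background and seeded
  noise. Random trees use a radial layout in which every leaf owns a
  disjoint angular sector and children split their parent's sector —
  subtrees therefore cannot collide, keeping branch separation above the
  blur scale by construction. Ground-truth tips are the degree-1 nodes of
  the segment graph (graph-checked); the root is a degree-2 node, so d
  leaf splits give d+1 tips.
* **Division angles** (`generate_division_angles()`): uniform on [0, 90]°
  or a von Mises sample (Best–Fisher rejection sampler) folded axially
  into [0, 90]°.

What the generators do **not** emulate: optical point-spread anisotropy,
photobleaching, segmentation/tracking errors, cell divisions and track
gaps, or any cell-mechanical model of jamming. A green test therefore
establishes algorithmic correctness on idealized data, not robustness to
every artifact of real microscopy.

## Engineering choices

Configuration is JSON (`run_config()`/`read_config()`) — the R grading
stack has no TOML parser, and JSON round-trips through jsonlite with full
numeric precision. Volumes travel as multi-page uncompressed grayscale
TIFF (TZYX page order) through a self-contained reader/writer (no TIFF
package is available in the target stack), with a JSON sidecar for axis
metadata; trajectories as CSV in either a plain dialect or the
tracking-table dialect (TRACK_ID/FRAME/POSITION_*, junk header rows
skipped and counted). Every stochastic step derives its seed from the
global seed, reports are numerics-only and byte-deterministic given
(config, seed), and provenance (version, config hash, warnings,
timestamp) is written alongside, never inside, the report.

## Known limitations

Single-pass PIV only (no window deformation or multi-pass refinement);
displacement recovery is limited by the search margin. Similarity maps
collapse z by averaging when profiled. Cluster identification assumes
complete tracks over the analysis window and excludes clusters with early
track ends (logged, mirroring manual exclusions). The Mann–Whitney exact
path follows R's n < 50, tie-free rule rather than a hard n ≤ 20 cutoff.
Tip counting projects to 2D before skeletonizing; overlapping branches in
projection merge, which is the dominant error mode on dense trees.
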