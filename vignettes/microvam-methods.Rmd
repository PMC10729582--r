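---
title: "Quantifying microglia, vessels and barrier leakage: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microglia, vessels and barrier leakage: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microvam)
```

# Scope

`microvam` quantifies microglial phenotypes in multi-channel fluorescence
microscopy of brain tissue, the kind of data produced in studies of
hypertensive cerebral small vessel disease: a microglia channel (IBA1-like),
a vessel channel (lectin-like) and optionally a plasma-protein channel (IgG)
recording blood-brain-barrier leakage. The package covers the full chain
from raw channels to group statistics — vessel segmentation, soma and
leakage quantification, single-cell skeleton morphometrics, classification
of vascular-associated microglia (VAM), morphology clustering, and the
statistical tests used for such designs — together with a synthetic
field-of-view (FOV) generator that provides complete ground truth, so every
stage is validated against planted structure rather than against opinion.

# Vessel segmentation

Vessels are enhanced with a multi-scale Frangi filter. At each scale
$\sigma \in \{1,2,3,4,5\}$ pixels, the image is smoothed with a Gaussian of
that width and the Hessian is taken by central differences, multiplied by
$\sigma^2$ (scale-normalized derivatives). With eigenvalues sorted by
magnitude ($|\lambda_1| \le |\lambda_2| \le |\lambda_3|$), the 3D
vesselness of a bright tube on a dark background is

$$V = \left(1 - e^{-R_A^2/2\alpha^2}\right)\,
      e^{-R_B^2/2\beta^2}\,
      \left(1 - e^{-S^2/2\gamma^2}\right),
      \qquad \lambda_2, \lambda_3 < 0,$$

with $R_A = |\lambda_2|/|\lambda_3|$ (plate vs. line),
$R_B = |\lambda_1|/\sqrt{|\lambda_2\lambda_3|}$ (blobness) and
$S = \sqrt{\sum_i \lambda_i^2}$ (structure strength); the per-scale maps
are combined by voxel-wise maximum. Two 2D analogues are used on single
planes.

Design choices worth knowing:

* **Self-tuned contrast sensitivity.** $\gamma$ is not fixed: it is set to
  40% of the image-wide maximum absolute Hessian eigenvalue, taken over all
  voxels *and all scales*, once per image. This makes the background term
  adapt to each image's intensity distribution. The 40% fraction, the scale
  set and $\alpha = \beta = 0.5$ are defaults of `frangi_params()` and can
  be changed.
* **Self-tuned thresholds.** The segmentation thresholds come from the
  vesselness distribution itself: a three-class Otsu search over all pairs
  of cut points of a 256-bin equal-width histogram (zeros included, ties
  broken toward the lexicographically smallest pair) yields `(low, high)`,
  and hysteresis keeps every connected component of
  $\{V > \mathrm{low}\}$ that contains at least one voxel with
  $V \ge \mathrm{high}$. Connectivity defaults to the full neighbourhood
  (8 in 2D, 26 in 3D) and is configurable.
* **Scales are in pixels, isotropic in pixel units.** The acquisition this
  emulates has near-isotropic voxels (1.25 × 1.25 × 1 µm³), and the filter
  scales are conventionally quoted in pixels. We evaluated a variant that
  makes the smoothing isotropic in physical units on anisotropic stacks; it
  performed slightly worse on the synthetic networks and is not the
  default.
* **Volumetric by default.** On z-stacks the filter runs in 3D; 2D
  (slice-type) inputs are handled by the 2D filter. Whether the original
  analyses ran slice-wise or volumetrically is not documented for this kind
  of pipeline; we treat the volumetric route as the default because the
  structures are 3D tubes, and the 2D path remains available for planar
  images.

Degenerate inputs are defined away rather than special-cased: a constant
image has zero vesselness everywhere and yields an empty mask; a
distribution with fewer than three distinct values raises a
degenerate-distribution error in the Otsu step.

# Soma detection, single cells and leakage

**Somata** are detected by automatic global thresholding of the microglia
channel (Otsu by default; Triangle is provided for inverted bright-field
material, where that method is conventional), connected components, and a
strict physical size filter: components with area > 60 µm² are kept. In 3D
the component "area" is its cross-section footprint in the z-slice nearest
the component centroid — a convention chosen to match what a 2D soma-size
measurement sees; it is documented here because other reasonable
conventions (full projection, maximum slice) give systematically larger
values.

**Single-cell masks** assign each thresholded component to the soma it
contains. Components holding two or more somata are flagged "touching" and
excluded from single-cell morphometrics — overlapping cells cannot be
measured individually. In the 2D mode a strict > 2000 pixel size filter
removes fragments. Within each cell, the soma is then re-delineated from
the cell's own intensity histogram: the bright core above the cell-wise
Otsu cut that contains the distance-transform maximum of the mask. This
deterministic surrogate replaces the manual outlining used in practice and
is an approximation, not a claim about manual measurements; the soma size
filter (60 µm²) belongs to the low-magnification counting stage, and
high-resolution single-cell work should pass a permissive
`soma_min_area`.

**Leakage** is quantified with a fixed display threshold: binarize at
intensity > 25 (8-bit scale), drop components with area ≤ 5 µm² (strict),
and report 100 × retained area / FOV area. The fixed threshold — rather
than an automatic one — is deliberate: leakage intensity varies between
individuals, and an adaptive threshold would erase exactly the differences
being measured. Z-stacks are processed slice-wise so the area convention
matches the 2D definition exactly.

All size filters use strict inequalities; boundary cases (a component of
exactly 60 µm², a blob of exactly 4 µm² above threshold) are covered by
tests.

# Skeleton morphometrics

Each retained cell mask is thinned to a one-voxel curve skeleton by
sequential directional thinning: border voxels are deleted when they are
*simple points* — deletable without changing local topology, tested by
counting foreground components in the 26-neighbourhood and background
components in the 18-neighbourhood (the standard digital-topology
criterion) — and are never deleted when they are curve endpoints. A graph
is built over skeleton voxels with edges between neighbouring voxels and
edge lengths equal to the physical distance between voxel centres under
the anisotropic spacing. Three cleanup steps precede measurement:

1. **Diagonal-shortcut removal**: the longest edge of every adjacency
   triangle is dropped, which removes the spurious diagonal of L-shaped
   voxel corners while preserving connectivity.
2. **Chain smoothing**: interior (degree-2) node coordinates are relaxed a
   few Laplacian iterations toward their chain neighbours before edge
   lengths are fixed. Voxel paths zigzag around the true curve, inflating
   summed lengths by several percent; smoothing removes most of that bias.
   Junctions and endpoints do not move.
3. **Soma contraction and spur pruning**: skeleton nodes inside the soma
   mask collapse to a single soma node — edges crossing the boundary keep
   their lengths — so processes are measured from the soma surface outward,
   and terminal spurs shorter than `prune_um` (default 1 µm) are removed.
   Thinning thick, bumpy unions of soma and process bases creates short
   artifact spurs; pruning is the standard remedy, and the threshold is a
   parameter precisely because the artifact scale grows with soma size and
   voxel coarseness.

Branches are maximal paths between nodes of degree ≠ 2 (plus isolated
cycles); their lengths are sums of edge lengths. The 8-feature vector per
cell is: soma area (µm²), endpoint count, branch-point count, maximum
branch length (µm), total branch length (µm), cell volume (µm³; area in
2D), convex-hull ("territorial") volume, and the ramification index
RI = cell volume / hull volume — the 3D analogue of 2D solidity
(branching area / convex hull area), with lower values indicating more
ramified cells. The hull is taken over the *corner points* of the
foreground voxels, i.e. each voxel contributes its full physical extent.
This guarantees RI ∈ (0, 1] (a hull over voxel centres is smaller than the
voxelized body and pushes RI above 1 for convex solids) and reproduces the
exact solidity of polyomino shapes — a plus-sign of five unit squares has
hull area 7 and RI = 5/7. The price is a surface-layer excess on curved
bodies: a voxelized ellipsoid scores RI ≈ 0.85–0.9 rather than 1, shrinking
as resolution grows. Since clustering standardizes features, this shared
offset is harmless downstream, but absolute RI values should be compared
only between equally-sampled cells.

# Vascular-associated microglia

A cell is a VAM when its soma touches a labeled vessel. "Touching" is
operationalized as: minimum Euclidean distance from soma voxels to the
vessel mask (via an exact anisotropic distance transform) at most one voxel
diagonal — direct contact up to discretization. The distance is exposed as
`attach_distance` because the biological definition carries no tolerance;
VAM frequency is non-decreasing in it, so reported frequencies should
always quote the distance used. Soma contact (not process contact) is used
in both 2D and 3D modes, matching the histological definition; process
contact would classify nearly every microglia as vascular-associated at
typical capillary densities. Densities are standardized to the xy footprint
of the FOV in mm², the convention used for cell counts in tissue sections.

# Morphology clustering

Features are z-scored per column (constant columns are an error — they
carry no information and silently break Ward distances), clustered by
agglomerative Ward linkage on Euclidean distances, and cut at *k* clusters.
The default *k* = 4 reflects the cluster count such analyses typically
report, but because microglial morphology is a continuum rather than a set
of discrete classes, `ward_cluster()` always returns the dendrogram and
mean silhouette widths over a range of *k*, and the choice should be
reviewed per dataset. A 2D UMAP embedding (defaults: 15 neighbours,
min_dist 0.1, seed 42, single-threaded so results are reproducible)
supports visual assessment; clustering happens in feature space, never in
the embedding. Frequencies per cluster are tabulated within strata (group,
region, stage) and sum to one per stratum. Pooled and per-stratum runs are
both possible; clustering pooled data and tabulating frequencies per
stratum keeps cluster identities comparable across strata and is what the
pipeline does.

# Statistics

The statistical layer mirrors the tests used in this literature:
Shapiro–Wilk normality screening; the two-tailed Welch *t*-test
(Welch–Satterthwaite degrees of freedom); two-way ANOVA on group × age
with partial (type III) sums of squares under sum-to-zero contrasts —
the SS type is stated because it matters for unbalanced designs — followed
by pairwise cell-mean comparisons on the pooled residual variance with
Holm–Šídák step-down adjustment: with the raw p-values sorted ascending,
$p^{adj}_{(i)} = \max_{j \le i}\, 1-(1-p_{(j)})^{m-j+1}$, capped at 1. The
post-hoc family defaults to the comparisons such studies display
(hypertensive vs. control within age, and ages within group) and is
configurable, since the family definition is a modelling choice.
Spearman correlation matrices use average ranks; p-values come from the
*t* approximation for n > 10 and from the exact permutation distribution
(full enumeration) for n ≤ 10. Relative qPCR quantification follows the
comparative $2^{-\Delta\Delta C_t}$ method: per sample,
$\Delta C_t = \overline{C_t}(\text{target}) - \overline{C_t}(\text{reference})$
over replicates; $\Delta\Delta C_t$ subtracts the control-group mean
$\Delta C_t$; fold change is $2^{-\Delta\Delta C_t}$, so the control group
averages a fold change of 1 when its $\Delta C_t$ values are identical.

Whether single-cell morphology comparisons should treat cells or animals
as the unit of analysis is a genuine design question; the feature tables
carry FOV and group identifiers so both aggregations are one `aggregate()`
away, and the package deliberately does not hide that choice.

# The synthetic-data generator

`simulate_fov()` renders what the validation needs and nothing more:

* **Vessels**: smooth random-walk centerlines entering at a random face and
  aimed through the central region of the FOV, rendered as tubes from the
  exact point-to-segment distance in µm (sub-voxel accurate), with a filled
  intensity profile and a one-voxel soft edge. The truth mask is
  distance ≤ radius.
* **Microglia**: ellipsoidal somata plus explicit polyline trees of
  tapering branches — truth (per-branch lengths, endpoint counts) is
  defined on the generated tree, not re-measured from voxels. Branch tips
  may bifurcate once. Because merging processes fuse in a rendered mask,
  each cell records a `well_separated` flag (all branch pairs keep a
  clearance larger than two process diameters plus two voxels away from
  shared junctions); endpoint-exact recovery is only claimed for flagged
  cells. A per-cell Bernoulli draw with probability `vam_fraction` plants
  somata in contact with the vessel mask, so FOV-level VAM frequencies
  carry realistic sampling variability; non-planted somata keep a 5 µm
  clearance so planted labels are unambiguous.
* **Leakage**: Gaussian-profile perivascular blobs are stamped just outside
  the vessel wall until the fraction of the FOV above the fixed threshold
  reaches the target; the achieved fraction is recomputed from the
  composed clean channel and recorded as truth. Unreachable targets warn
  and record what was achieved.
* **Noise**: optional Poisson shot noise on the clean intensity followed by
  Gaussian read noise (default σ = 5 on the 8-bit scale), rounded and
  clipped. The emulated acquisition does not document its noise model;
  these defaults are conventions and are stated as such.
* **Resolution realism**: everything is generated in µm and rasterized with
  the per-axis voxel size, so the same model serves the coarse counting
  grid (1.25 × 1.25 × 1 µm³) and the high-resolution single-cell grid
  (0.16 × 0.16 × 0.3 µm³). At the coarse grid, sub-voxel processes are
  dimmed by their partial-volume fraction — which is why soma counting by
  global threshold works there, exactly as it does in real 20× material.

What the generator does **not** emulate: optics beyond the soft edge (no
PSF convolution), photobleaching, tissue autofluorescence structure,
vessel branching topology, or biological covariance between morphology
features and VAM status. Passing recovery tests on these FOVs therefore
demonstrates that the measurement chain is correct and unbiased on known
geometry — not that it is robust to every artifact of real tissue.

# Validation problem sizes

The shipped tests and the acceptance script validate at sizes chosen to
make every run complete quickly while keeping each estimate meaningful:
vessel recovery is reported as the mean Dice over 8 noise-free
128 × 128 × 24 FOVs; soma counting over 4 FOVs (48 somata); skeleton
recovery over 30 single cells on a 0.32 × 0.32 × 0.6 µm grid (a 2×-binned
version of the high-resolution acquisition; branch lengths 10–20 µm and a
3 µm prune so that true branches and thinning artifacts occupy disjoint
length scales, making "endpoint-exact" well defined); clustering recovery
over 120 archetype cells; Welch calibration over 10,000 null replicates;
and the end-to-end effect detection over 16 FOVs in two groups with
planted VAM fractions 0.1 vs. 0.5. The archetype cells are feature-space
draws from four regimes (amoeboid, hypertrophic, transitional, ramified)
with distinct soma-size/endpoint/RI distributions — they validate the
clustering stage in isolation from the imaging stages.

# Known limitations

* Sequential thinning is order-dependent: rotating a mask by 90° can flip
  borderline spur decisions, so endpoint counts are guaranteed stable under
  rotation only up to pruning (exact for clean shapes, ±1 for rendered
  cells with borderline spurs).
* The corner-based hull overstates the territorial volume of curved cells
  by a surface layer (one voxel thick), biasing RI slightly downward at
  coarse resolutions; comparisons across different voxel sizes should be
  avoided.
* The Frangi + hysteresis chain, with thresholds taken from the vesselness
  distribution, over-segments a thin shell around sub-5-pixel-radius tubes;
  Dice against planted tubes plateaus around 0.8–0.87 at capillary calibre
  regardless of implementation details. This is a property of the method,
  shared with the reference implementations of the same chain.
* The IgG percentage is a display-threshold measurement; it is only
  comparable between images acquired and scaled identically, which is why
  the generator works on a fixed 8-bit convention.
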