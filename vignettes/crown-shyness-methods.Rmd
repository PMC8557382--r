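---
title: "Measuring crown shyness as 3-D surface complementarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring crown shyness as 3-D surface complementarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crownshy)
```

## The problem

Crown shyness is the tendency of neighbouring tree crowns to avoid
growing into one another, leaving channel-like gaps and a puzzle-like
canopy in which adjacent crowns *complement* each other's shape.
Classical metrics of crown shyness (canopy cover, inter-crown distance)
are essentially 2-D.  With terrestrial laser scanning (TLS) producing
dense 3-D point clouds of individual trees, the complementarity of two
facing crown *surfaces* can be measured directly, borrowing the shape
complementarity statistic developed for protein-protein interfaces.

`crownshy` implements that measurement as a pipeline over per-tree
point clouds (coordinates in metres throughout; no unit detection is
attempted):

1. **Crown/bole separation** — `segment_crown()`
2. **Interaction-zone extraction** — `two_way_nn()`, `oriented_box()`,
   `clip_to_region()`
3. **Surface reconstruction** — `alpha_shape()` (regularized 3-D
   alpha shape on an internal Bowyer-Watson Delaunay
   tetrahedralization)
4. **Scoring** — `match_faces()` and `sc_score()`, composed end to end
   by `pair_sc()`

plus tree-pair slenderness allometry and the cross-pair statistics
(`pair_slenderness()`, `regress_sc_on_slenderness()`,
`compare_overlap_groups()`, `normality_check()`), and a synthetic
crown-pair generator (`make_tree()`, `make_pair()`, `make_cohort()`)
with known ground truth.

## The complementarity statistic

Let $U$ and $V$ be the facing parts of the two crown surfaces, each a
triangle mesh with outward unit normals.  For a point $x$ on $U$ with
outward normal $n_x$, let $x'$ be the nearest point of $V$ with
*inward-directed* unit normal $n_{x'}$ (the negated outward normal of
$V$).  The directional sample is the dot product

$$S(x, U, V) = n_x \cdot n_{x'},$$

evaluated here at the matched triangle centroids ($j$ samples from $U$
toward $V$, $k$ samples the other way), and the score is the average
of the two arithmetic means:

$$S_c = \tfrac12\Big(\tfrac1j\sum S(x, U, V) +
  \tfrac1k\sum S(x, V, U)\Big).$$

Each sample is a dot product of unit vectors, so $S_c \in [-1, 1]$:

* $+1$ — perfectly mating surfaces (a convex bulge nested in a matching
  concavity, or two parallel sheets facing each other);
* $0 \ldots 1$ — convex-convex or concave-concave coincidence;
* $< 0$ — interpenetrating surfaces.

Two sign-convention details are deliberate.  First, "inward-directed"
is realised as the *negated outward* normal of the partner surface;
this is the only reading that makes mating plates score exactly $+1$
and interpenetrating configurations negative, and it matches the
protein-docking original.  `plate_mesh()` exists precisely to keep
this calibration executable: two facing plates score $S_c = 1$, and
flipping one plate's normals scores $-1$.  Second, the original
protein statistic attenuates samples with a distance-decay weight
$e^{-w d^2}$; the crown formulation drops the weight, so no weight is
applied here either.

Sampling density is one sample per selected face: $j$ and $k$ are the
sizes of the two matched-face selections.  This is the densest
deterministic choice available from the meshes and avoids a sampling
rate parameter.

## Stage details and the parameters that matter

### Crown/bole separation

The vertical profile is a histogram of point heights with bin width
equal to the voxel size (default **0.05 m**), normalized to fractions
of the total point count.  The crown base is the lower edge of the
first bin whose fraction is *strictly greater* than the threshold
**P = 0.015** (ties at exactly the threshold do not trigger; the
comparison is documented, not configurable).  All points with
$z \ge$ base are crown — the partition is exhaustive and exclusive.
Normalizing by total points is what makes the unitless 0.015 portable
across clouds of different size.  The profile is computed on points,
not occupied voxels, matching how the profile is drawn and read in
practice; `voxelize()` is provided for density diagnostics.  The
threshold has no objective selection criterion — it is a visual
choice — so `plot()` on a `height_histogram` draws the profile with
the threshold line for inspection, and the value is exposed
everywhere.

### Interaction zone

A two-way nearest-neighbour search between the two crown point sets
collects, in each direction, the *targets* of the nearest-neighbour
map; no distance cutoff is applied by default (an optional `max_dist`
exists for distant pairs).  The bounding box is oriented along the
horizontal line joining the xy centroids of the two *entire* crowns
(first axis), with the horizontal perpendicular and the vertical as
the other two axes.  Extents fit the near set tightly in that frame;
only the orientation and the vertical span (the near set's exact z
range) are prescribed by the method, so tightness is the
least-assumption completion, with `padding` exposed for the two
horizontal axes.  Containment uses closed intervals — a point exactly
on a box face is kept — and nearest-neighbour ties are resolved
deterministically by the spatial index, so reruns are identical.

### Alpha-shape surfaces

The surface of each clipped point set is the *regularized* 3-D alpha
shape: the boundary of the union of Delaunay tetrahedra with
circumradius $\le \alpha$.  Singular (dangling) faces of the full
alpha complex are excluded because the score needs faces with a
well-defined solid side and outward normal.  Face normals are
oriented away from the owning tetrahedron; `orient_outward()` offers
a reference-point fallback for meshes from other sources.

Since no 3-D Delaunay tetrahedralization was available to build on,
the package implements the Bowyer-Watson incremental algorithm in
C++ with tolerance-based predicates, a cavity-repair step for
near-cospherical inputs, and a deterministic insertion order (fixed
xorshift permutation), making results platform-stable.  The
triangulation is validated in the test suite against brute-force
enumeration oracles (empty-circumsphere definition, convex-hull
facets, 4-subset alpha-shape enumeration).

Numerical choices: the circumradius comparison is closed
(`<= alpha + 1e-12`); tetrahedra with volume below $10^{-12}\,
\mathrm{m}^3$ are treated as degenerate and never kept, because their
circumradii are numerically unstable; coordinates are internally
rescaled to a unit box so predicate tolerances act at a uniform
magnitude.

The default **alpha = 1 m** sits in the stable band (roughly 1-2 m
for metre-scale crowns): below it, surfaces hug individual returns
and the score degrades toward noise; far above it, concave detail is
lost as the surface approaches the convex hull and complementarity is
systematically under-estimated.  `alpha_sweep()` recomputes the
surface and scoring stages over a grid (default 0.2, 0.4, 0.6, 1, 2,
3, 5, 10 m — segmentation and zone are computed once) so this
sensitivity can be examined per dataset; `sweep_summary()` aggregates
mean and median across pairs, the median being the more robust of the
two at extreme alphas.

### Pair statistics

Slenderness of a tree is height (m) over DBH (cm) — deliberately not
an SI-dimensionless ratio; it is the convention in which mature trees
fall around 0.4-0.9 — and pair slenderness is the mean of the two.
Slenderness is always recomputed from DBH and height rather than
trusted from a printed column: the bundled Guyana field table
contains one transcription artefact (tree 40_06, printed 0.67 where
height/DBH gives 0.699), and recomputation reproduces every
pair-level value that does not involve that tree, plus the 40_06
pairs themselves.

The overlap-group comparison is an independent two-sample t-test,
pooled-variance by default with a Welch option (the report names the
variant); overlap labels are user-supplied from visual inspection —
they are never inferred from $S_c$, which would be circular.  The
regression of $S_c$ on pair slenderness is ordinary least squares
with the two-sided slope t-test reported at full precision, and
adjusted $R^2 = 1 - (1 - R^2)(n-1)/(n-2)$.  Normality checks use
Shapiro-Wilk.

## The synthetic generator: what it emulates and what it does not

Real crown-shyness point clouds of *adjacent* tree pairs are scarce,
so every stage is exercised against simulated pairs with known ground
truth.  A synthetic tree is:

* a bole: a cylinder of radius 0.15 m sampled sparsely (default 800
  points) from 0 to `stem_height` (default 12 m);
* a crown: an ellipsoidal shell (default semi-axes 3, 3, 1.2 m — a
  broad, moderately shallow canopy crown) whose lowest point sits
  exactly at the stem top, sampled with Gaussian radial noise
  (default sd 0.02 m, a typical TLS range-noise magnitude), with 10 %
  of crown points placed uniformly inside the envelope to emulate
  interior branch returns;
* branch spurs: straight outward segments (default 20 spurs of 0.4 m)
  that give the surface the local convex/concave relief that makes
  complementarity discriminative;
* an underside sampling bias: shell directions are weighted linearly
  in the polar cosine toward the lower hemisphere, emulating a
  ground-based scanner that sees the crown underside far better than
  its occluded top.  This also reproduces the sharp density onset at
  the crown base that the vertical-profile segmentation relies on in
  real scans (with uniform shell sampling a 0.05 m bin of a
  metre-scale crown holds well under 1.5 % of the points and the
  profile method would have nothing to detect).

`make_pair()` places two such trees along the x axis so the
horizontal clearance between the *nominal* envelopes equals `gap`
(positive = shyness channel, negative = interpenetration depth; the
boundary `gap = 0` is labelled non-overlapping).  Noise and spurs are
ignored by the placement, so audits in the tests allow for them
explicitly.  `make_cohort()` alternates the two labels and draws gaps
uniformly from per-label ranges (defaults 0.15-0.9 m for shy pairs —
the decimetre-scale channels typical of crown shyness — and 0.3-2 m
of interpenetration for overlapping pairs).

What the simulator does *not* emulate: real branch architecture
(no L-systems or space colonization), foliage clumping, occlusion
shadows cast by one crown on the other, registration error between
scan positions, or wind-blurred returns.  Passing the simulated
checks therefore demonstrates that the pipeline measures what it
claims on geometrically controlled inputs — not that any particular
field value is reproduced.  Field-scale behaviour enters the test
suite only through the bundled DBH/height/Sc table, whose regression
and slenderness values are desk-reproducible.

Two simulator regimes deserve a note.  Deeply interpenetrating
ellipsoid shells (1-2 m) score clearly negative $S_c$ — more negative
than field values for "overlapping" crowns, which interdigitate only
at their peripheries.  A shallow overlap (a few decimetres) reproduces
the field-like regime, including the rising limb of $S_c$ over
$\alpha = 0.2 \ldots 1$ that peripheral contact produces.  The tests
use deep overlaps where a strong, unambiguous ordering is wanted
(group separation) and shallow overlaps where the peripheral-contact
regime itself is under test.

## Problem sizes and runtime choices

The defaults above (about 13&nbsp;000 points per tree) keep a full
14-pair cohort — segmentation, zone, two alpha shapes and scoring per
pair — under ten seconds on one core, which is the scale the test
suite and the acceptance script use.  Clouds one or two orders of
magnitude denser work unchanged (the Delaunay core handles
10^5-point clips in seconds); they are simply not needed to validate
the method.  Oracle comparisons that enumerate all 4-subsets of the
input are restricted to 45-60 points, where exhaustive enumeration
is exact and fast.

## Known limitations

* Pairwise only: interaction zones among three or more mutually
  touching crowns are not modelled.
* The crown-base rule assumes a single dominant crown; multi-stem or
  strongly layered trees can trigger on the wrong bin.
* Low point density in the contact zone makes the alpha shape
  spuriously concave and biases $S_c$ downward; the package emits the
  per-stage counts (`j`, `k`, clip sizes) so such pairs can be
  flagged, but it does not correct for them.
* PLY support covers ASCII and binary little-endian vertex data;
  scanner-native formats (LAS/LAZ) are out of scope.
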