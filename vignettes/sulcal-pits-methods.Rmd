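---
title: "Sulcal pits morphometry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sulcal pits morphometry: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sulcalpits)
```

This vignette is the package's account of the science it implements: the
models and their assumptions, the parameters that matter, what the
synthetic cohort generator does and does not emulate, and the numerical
and design choices made where the method left room.

## The depth model

Cortical depth is estimated per vertex by the depth potential function
(DPF), the solution $d$ of

$$(\alpha M + K)\,d = M\,s, \qquad s = 2\,(H - \bar H),$$

with $K$ the cotangent stiffness matrix, $M$ the lumped (barycentric)
mass matrix, $H$ the signed mean curvature and $\bar H$ its
area-weighted mean. The construction combines curvature (the local
source) with convexity (the solution spreads by a screened-Poisson
kernel of decay length $1/\sqrt{\alpha}$, about 5.8 mm at the default
$\alpha$), so a vertex is "deep" if it sits in a concave region that is
also globally buried. Centering $H$ makes the DPF invariant to additive
curvature offsets and forces its area-weighted mean to zero; on a
constant-curvature surface the source vanishes and the DPF is
identically zero.

Assumptions: the mesh is an oriented 2-manifold triangle surface with
outward normals; curvature sign is fixed so concave (sulcal) regions are
positive, which makes "deepest" equal "maximal" everywhere downstream.

Parameters:

* `alpha` (dimensionless per mm$^2$, default 0.03) — regularization
  weight. Small values emphasize large-scale convexity, large values
  reduce the DPF to a rescaled curvature map (the package tests both
  limits). The default follows the reference implementation of the DPF
  lineage; the depth literature gives no universal value.
* Source scaling 2 and mean centering are fixed, not tunable: they set
  the DPF's conventional scale.

## Pit extraction

The filtered watershed floods the DPF map in decreasing depth order.
Each local maximum seeds a basin whose deepest vertex is its *pit*. Two
basins meeting at a ridge vertex merge when the ridge height
$R = d_{\text{shallower pit}} - d_{\text{ridge}}$ is below `ThR` **and**
the graph-geodesic distance $D$ between the two pits is below `ThD`
(both conditions, implemented literally as a conjunction); the merged
basin keeps the deeper pit. After flooding, basins with area below `ThA`
are merged into the neighbour sharing the longest boundary, iterating
until none remains.

Defaults `(ThR, ThD, ThA) = (1.5, 20 mm, 50 mm^2)`, calibrated in the
method's lineage on healthy adults. Per subject, `ThD` and `ThA` scale
with brain size, `ThD' = ThD \cdot FL/G(FL)` and
`ThA' = ThA \cdot SA/G(SA)`; `ThR` is a depth contrast and is not
size-normalized. The Fiedler length `FL` is the geodesic distance
between the extrema of the first nontrivial eigenvector of the
mass-normalized Laplace operator — an elongation proxy that grows with
head size but is insensitive to folding detail.

Numerical choices (the method is silent on all of these; each is a
deterministic convention, applied identically in the package and in the
brute-force test oracle):

* Geodesics are Dijkstra shortest paths on the edge graph with Euclidean
  edge weights, not exact polyhedral geodesics. On the meshes used here
  the graph metric overestimates great-circle distances by up to ~6%,
  which is immaterial for thresholding decisions at the 20 mm scale.
* Flooding ties break to the lower vertex index. Equal-depth plateaus
  are processed as a unit: plateau vertices adjacent to existing basins
  are absorbed first (iterated sweeps in index order), then each
  remaining connected plateau component seeds exactly one basin at its
  lowest-index vertex. This makes a constant depth map yield a single
  basin and, crucially, lets the exactly-zero background of group
  density maps drain into the genuine clusters instead of seeding
  spurious ones.
* Ridge height uses the pit depths current at the moment of contact;
  merged basins keep the deeper pit. At a vertex touching more than two
  basins, each shallower basin is tested against the deepest adjacent
  one, and the vertex joins the deepest.
* Basin-area merging processes the smallest basin first; boundary-length
  ties break to the deeper-pit neighbour, then the lower label.
* The Fiedler vector is computed by ARPACK in shift-inverted symmetric
  form. Near-spherical test surfaces have a nearly threefold-degenerate
  first eigenvalue; Lanczos handles the cluster robustly where plain
  inverse iteration stalls. Extrema ties break to the lowest vertex
  index. For the elongated default cohort sheets the eigenvalue is
  simple and the length is stable to ~1%.
* A basin whose pit has non-positive DPF sits on a crown or flat
  background, not in a fold; the pipeline's counting and depth tables
  treat only positive-depth basins as sulcal pits
  (`min_pit_depth = 0`, exposed in the configuration). Extraction
  itself still returns the full partition.

## Group parcellation

Subject pit textures (1 at pits, 0 elsewhere) are smoothed by explicit
heat-equation steps of the lumped-mass Laplacian. The FWHM is converted
to diffusion time by $\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$,
$t = \sigma^2/2$, split into `n_iter` (default 60) steps; steps
exceeding the explicit-stability bound are subdivided automatically with
a warning. Negative undershoots are clamped to zero and the result is
rescaled so the global maximum is one. Renormalization is global, not
per-blob: the method's "peak maintained at one" wording is ambiguous,
and the global choice keeps the texture a relative density (per-blob
renormalization would erase the distinction between reliable and
unreliable pit locations).

Smoothed textures are projected to the template through precomputed
vertex correspondences — real spherical or interhemispheric registration
is an external preprocessing step and is *not* implemented; synthetic
cohorts use the identity map on shared topology. When several source
vertices map to one target the maximum is taken, preserving the unit
peak. Projected textures are averaged into a density map (values in
[0, 1]; a pit probability per location), and the same watershed
machinery with `(gThR, gThD, gThA) = (2, 15, 100)` — in density units,
unscaled — produces connected clusters covering the template. Smoothing
is applied on the subject mesh before projection, following the stated
order of operations in the method's lineage.

## Classification and statistics

Cluster mean depths (mean over subjects of the deepest-pit DPF, missing
subjects excluded) are classified by one-dimensional k-means with
k = 3 and 100 seeded restarts, best within-class sum of squares kept;
classes are named primary/secondary/dimple by descending centroid. The
"average DPF of all subjects for each cluster" is interpreted as the
mean of per-subject deepest-pit DPF — the same measurement the depth
analyses use — rather than a basin-wide vertex average.

All group comparisons are two-tailed OLS with a case/control dummy and
age in years as covariate; age effects on counts use simple
regressions. Per-cluster depth tests exclude, cluster-wise, subjects
without a pit there (no imputation); clusters with fewer than three
subjects per group are skipped but still count in the
Benjamini–Hochberg family, so the correction is never weakened by
skipping. The left and right parcellations form one FDR family for the
depth tests; the symmetric parcellation forms its own family for the AI
tests and for each group's hemisphere RM-ANOVA. IQ is deliberately not a
covariate. The asymmetry index is computed from deepest-pit DPF per
symmetric cluster; subject-clusters with $L + R \le 0$ are dropped. The
RM-ANOVA with one within-subject factor of two levels is fitted with
`aov` and an `Error(subject)` stratum and equals the squared paired t;
zero within-subject variance is flagged degenerate rather than reported
as an F statistic.

## The synthetic cohort generator

The generator emulates what the pipeline needs from a cohort of
hemispheres: shared mesh topology, folds in three depth tiers, group
effects on shallow-fold presence and on per-cluster depth, a linear age
trend in fold counts, and mirrored hemispheres with an exact
interhemispheric correspondence.

Each hemisphere is a flat rectangular sheet with folds imprinted as
inward Gaussian displacements ($\text{depth} \cdot e^{-g^2/2w^2}$ along
the vertex normals, $g$ the geodesic distance to the fold center). A
flat sheet has exactly zero discrete mean curvature everywhere, so the
designed folds are the only curvature sources — the synthetic analogue
of a cortex having no "unfolded" territory. Fold sites form a fully
tiled grid chosen so that three geometric constraints hold at once:
sites are at least $3w$ apart (folds do not interact), the spacing
exceeds `ThD` (designed basins never merge with each other), and every
sheet point lies within `ThD` of a site (any shallow spurious catchment
on the background contacts a designed basin at a low ridge and is
absorbed by the R/D rule during flooding). The default layout is a
single-row strip: its Fiedler length is pinned by the long axis and
varies by only ~1% across subjects, keeping the normalized `ThD` safely
below the fold spacing. On compact near-square sheets the Fiedler
extremum can jump to a corner and inflate `ThD` past the spacing — the
reason the strip is the default.

Default study conditions: ages uniform on 7–14 years; per hemisphere
3 primary folds (depth 8 mm, always present in both groups, as primary
sulci are), 4 secondary folds (5 mm; presence 0.9 in controls vs 0.7 in
cases — the count channel of the group effect, about 1.6 fewer pits per
case over both hemispheres), 2 dimples (2.5 mm; presence 0.6 in both
groups); fold width 6 mm; depth noise sd 0.5 mm; count-age slope −0.1
folds/year spread over the variable-presence folds; case subtypes drawn
65/35 combined/inattentive. Per-fold case-control depth shifts are
configurable for recovery studies. Everything is deterministic given the
seed.

What the generator does **not** emulate, hence what passing tests do not
show about real data: real gyral geometry (background here is flat, not
convex), registration error (correspondences are exact identities),
scanner/site effects, spatially correlated noise, and biomechanically
realistic fold shapes. One known limitation: when a variable fold is
absent in a subject, its territory occasionally forms a shallow
catchment whose "pit" has near-zero or negative DPF. The pipeline's
positive-depth rule removes these phantoms from counts and depth tables;
geometry-level recovery tests additionally use all-present cohorts so
that ground truth is unambiguous.

Statistical calibration and power checks run on the generator's
measurement-level channels (`simulate_pit_counts`,
`simulate_cluster_depths`), which draw from the same presence/noise
model without building geometry; this is what makes 2000-replicate
null calibrations affordable.

## Problem sizes used in the tests

Module tests use sheets and spheres of 42–900 vertices; the
oracle-equivalence checks run 50 random meshes of up to 162 vertices;
pit-recovery runs 20 seeded surfaces of 300–700 vertices; the end-to-end
pipeline tests use cohorts of 6–16 subjects on 532-vertex hemispheres;
calibration uses 2000 simulated datasets of 120 subjects at the
measurement level. These sizes were chosen so the full suite documents
the method's behaviour in minutes while still exercising every code
path at cohort scale in the analysis scripts.

## Known limitations

* Graph geodesics, not exact polyhedral geodesics; distances carry a
  small mesh-dependent overestimate.
* Discrete mean curvature does not converge pointwise at irregular
  vertices (the valence-5 ripple of subdivided icospheres, ~14% there);
  the DPF inherits a small background ripple on such meshes. The
  vertex-transitive icosahedral sphere, where curvature is exactly
  constant, is used when a machine-precision zero-DPF reference is
  needed.
* Registration quality is out of scope: all template-space results are
  conditional on the supplied correspondences.
* The watershed's behaviour on large flat plateaus is convention-driven
  (documented above); real cortical surfaces do not present such
  plateaus, synthetic density maps do.
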