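# sulcalpits

Sulcal pits are the locally deepest points of cortical folds on the
white-matter surface. Because they appear early in development and vary
little between individuals, they make stable anatomical landmarks for
comparing cortical folding between groups — for example between a
clinical cohort and matched controls. This package implements the full
sulcal-pits morphometry pipeline as reusable, tested R functions, plus a
synthetic folded-surface cohort generator so that every stage can be
exercised and validated without any imaging data.

It is aimed at researchers doing surface-based morphometry who want a
transparent, scriptable implementation of the pit-extraction and
group-analysis machinery, and at methodologists who want to study the
behaviour of the algorithms themselves under controlled ground truth.

## The method

**Depth.** Per-vertex depth is the depth potential function (DPF): the
solution of the regularized Poisson problem

    (alpha * M + K) d = M * s,     s = 2 (H - Hbar),

where K and M are the cotangent stiffness and lumped mass operators of
the triangle mesh, H is the signed mean curvature (concave positive) and
Hbar its area-weighted mean. Sulcal fundi get positive DPF, gyral crowns
negative; `alpha = 0.03` by default.

**Pits and basins.** A filtered watershed floods the DPF map from the
deepest vertices down. When two basins meet at a ridge vertex they merge
if the ridge height `R` (shallower pit depth minus ridge depth) is below
`ThR` **and** the geodesic distance `D` between the pits is below `ThD`;
after flooding, basins smaller than `ThA` are absorbed into their
longest-boundary neighbour. Defaults `(ThR, ThD, ThA) = (1.5, 20, 50)`,
with `ThD` and `ThA` rescaled per subject by brain size:
`ThD' = ThD * FL / G(FL)` and `ThA' = ThA * SA / G(SA)`, where `FL` is
the mesh Fiedler length, `SA` the surface area and `G(.)` the group
means.

**Group clusters.** Each subject's binary pit texture is smoothed by
heat diffusion (FWHM 5 mm, 60 iterations, peak renormalized to 1),
projected to a common template, and averaged into a density map — the
probability of a pit at each location. The same watershed, with group
thresholds `(gThR, gThD, gThA) = (2, 15, 100)`, divides the density map
into clusters. A symmetric variant pools both hemispheres on one
template side for asymmetry analyses.

**Classification and statistics.** Clusters are classified into primary
sulci, secondary sulci and dimples by 1-D k-means (k = 3, 100 restarts)
on their mean depths. Group differences in pit counts and per-cluster
deepest-pit depth use OLS with a group dummy and age as covariate,
two-tailed, with Benjamini–Hochberg FDR across the cluster family.
Hemispheric lateralization uses the asymmetry index
`AI = (L - R)/(L + R)` (−1 fully right-, +1 fully left-lateralized) and
within-group repeated-measures ANOVA (numerically the squared paired t).

## Worked example

The `analysis/` scripts run the whole study on a synthetic cohort
(10 cases, 10 controls, nine folds per hemisphere in three depth tiers;
secondary folds present with probability 0.9 in controls vs 0.7 in
cases):

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_extract_pits.R
Rscript analysis/03_group_parcellation.R
Rscript analysis/04_classify_and_count.R
Rscript analysis/05_depth_asymmetry_stats.R
```

which prints, among other things:

```
group means: FL left 229.4 / right 229.3 mm, SA left 4457 / right 4446 mm^2
extracted 299 sulcal pits over 40 hemispheres (median 7 per hemisphere)
parcellation: 9 clusters left, 9 right, 9 symmetric
  primary secondary    dimple
        6         8         4
centroids: primary=3.74, secondary=2.09, dimple=0.728

pit-number group effects (case - control, age-adjusted):
      class estimate     t      p  n     note
1   primary    0.000  0.00 1.0000 20 constant
2 secondary   -0.799 -2.23 0.0398 20
3    dimple    0.495  1.08 0.2941 20
4     total   -0.304 -0.51 0.6168 20
```

Reading: the parcellation recovers exactly the nine designed folds per
hemisphere; k-means splits the 18 clusters into the designed
6 primary / 8 secondary / 4 dimple tiers; the injected secondary-fold
presence deficit shows up as a negative, significant secondary count
effect while the always-present primary folds give a constant count
(flagged); the per-cluster depth and asymmetry comparisons (stage 5) are
null, as no depth effect was injected. All tables land under `results/`.

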