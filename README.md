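# potmorph

Outline-based morphometrics of how wheel-thrown vessel shapes develop —
from the preform left by centering and opening to the final form — and of
how that development differs among individual potters and communities of
practice. The package is aimed at archaeologists and cultural-evolution
researchers working with digitized vessel profiles (one half-profile per
fashioning gesture), and at anyone who needs a tested, seeded pipeline
from raw 2-D profile tables to permutation-level inference.

## What it computes

**Shape descriptors.** Each closed outline (the right half-profile
mirrored about the wheel axis) is expanded in elliptical Fourier series
under chord-length parameterization,

```
x(t) = A0 + Σ aₙ cos(2πnt/T) + bₙ sin(2πnt/T)
y(t) = C0 + Σ cₙ cos(2πnt/T) + dₙ sin(2πnt/T),   n = 1..30
```

Bilateral symmetry with the fixed on-axis start point makes aₙ and dₙ
vanish; the surviving 30 pairs (bₙ, cₙ), divided by the norm of the first
pair, give a scale-invariant 60-D pure-shape vector.

**Shape space and trajectories.** A pooled PCA of all vectors defines the
shape space (typically > 90 % of variance in the first three axes); each
trial becomes a trajectory of PC scores against percent time (0 =
preform, 100 = final form).

**Morphogenetic-path similarity.** Each trial's own 60-D sequence gets a
PCA; with V1 the variance captured by its own top-3 axes and V2 the
variance captured by another trial's axes, the symmetrized ratio
S = (V2/V1 + V2′/V1′)/2 ∈ [0, 1] measures path similarity and D = 1 − S
builds the trial-by-trial dissimilarity matrix.

**Inference.** Nested permutation MANOVA (individual potters nested within
communities; pseudo-F from Gower-centered sums of squares; whole-potter
permutations for the community test, within-community permutations for the
individual test), stage-wise multivariate dispersion (PCoA distance to
group centroid at preform / middle / final), UPGMA dendrograms with Newick
export, and hierarchical smooth trajectory models (global G,
community-specific S, community + potter SI; mgcv P-splines, REML)
compared by AIC and by held-out deviance under an odd/even trial split.

A seeded synthetic generator (`generate_study()`, `generate_null()`)
emulates the field design — 3 communities, 9/6/6 potters, 5 trials per
vessel type, 6–14 outlines per trial — with community-level mean paths,
potter-level offsets, and trial/measurement noise, so every stage is
testable without field data.

## Worked example

```r
library(potmorph)

cfg    <- generator_config(seed = 42)        # 9/6/6 potters, vase, 2.25 kg
trials <- generate_study(cfg)                # 105 trials, ~1000 outlines
tab    <- efa_table(trials)                  # 60-D shape vector per outline

space <- fit_shape_space(tab)
print(space)
#> Shape space: 1038 samples, 60 axes
#>   PC1-3 variance: 68.9%, 22.2%, 3.3% (cumulative 94.4%)

fin <- stage_table(tab, "final")
nested_permanova(distance_matrix(fin, "altGower"), fin$community,
                 paste0(fin$community, "_", fin$potter_id),
                 n_perm = 999, seed = 42)
#> Nested permutation MANOVA (potters within communities)
#>   n = 105 observations, 999 community permutations, 999 individual permutations, seed 42
#>      factor df         SS         MS      F     p
#>   community  2 1.5352e-04 7.6759e-05  7.799 0.001
#>  individual 18 1.7715e-04 9.8418e-06 15.800 0.001
#>    residual 84 5.2335e-05 6.2304e-07     NA    NA
```

Final shapes vary more among communities than within (F = 7.8 on 2 and 18
df) and more among potters than within (F = 15.8): both signatures are
detected at p = 0.001 (the smallest value 999 permutations can report).
The same test on the morphogenetic-space matrix `D = 1 − S`
(`subspace_dissimilarity(tab)`) gives F = 66.9 / 90.5 — path signatures
are even stronger than final-shape ones. Dispersion narrows toward the
final form (stage medians 0.0075 → 0.0057 → 0.0017; permutation p =
0.005), and the trajectory-model comparison ranks SI < S < G both by
training AIC (−10288 < −8063 < −6020, summed over PC1–PC3) and by held-out
deviance (0.57 < 1.22 < 6.84): morphogenetic paths carry community- and
potter-specific structure beyond a shared global curve.

The full pipeline — coefficients, shape space, trajectories, both
dissimilarity matrices, permutation tables, dispersion, model comparison,
dendrograms, plus a hashed JSON run manifest with per-stage caching — runs
from one config:

```r
run_pipeline(list(seed = 42), "out/")        # or a YAML path
```

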