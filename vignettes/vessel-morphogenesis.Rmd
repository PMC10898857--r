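---
title: "Quantifying vessel morphogenesis: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying vessel morphogenesis: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(potmorph)
```

## The problem

Wheel-thrown pottery offers an unusually clean window on how motor habits
shape artifacts: after every fashioning gesture the clay body has a
well-defined axisymmetric profile, so a single trial — one vessel, thrown
once — is an ordered sequence of shapes running from the *preform* (the
profile right after centering and opening) to the final form. potmorph
quantifies such sequences and asks two questions at the heart of
cross-cultural craft studies: do potters carry individual and
community-level signatures in the *final shapes* they produce, and do they
carry them in the *way* shapes develop (the morphogenetic path)?

The pipeline has five stages, each exposed as ordinary functions:

1. **Outlines.** Digitized right half-profiles are calibrated to cm,
   resampled to 256 points on a regular vertical grid, low-pass smoothed,
   and mirrored about the wheel axis into closed outlines
   (`read_trials()`, `resample_profile()`, `smooth_profile()`,
   `close_outline()`).
2. **Shape descriptors.** Each closed outline is reduced to elliptical
   Fourier coefficients; bilateral symmetry leaves 30 informative
   coefficient pairs, which are size-normalized into a 60-D pure-shape
   vector (`efa_vector()`).
3. **Shape space.** A pooled PCA of all vectors yields a low-dimensional
   shape space; each trial becomes a trajectory of PC scores against
   percent time (`fit_shape_space()`, `trajectory_table()`).
4. **Group structure.** Final-shape and path dissimilarities feed nested
   permutation MANOVAs (potters within communities), stage-wise dispersion
   analysis, and UPGMA dendrograms (`nested_permanova()`,
   `dispersion_analysis()`, `upgma()`).
5. **Trajectory models.** PC trajectories are modeled by hierarchical
   smooths of increasing structure — global (G), community-specific (S),
   community plus potter-level (SI) — compared by AIC and by held-out
   deviance under an odd/even trial split (`compare_models()`).

## Elliptical Fourier descriptors

A closed contour is traversed from the on-axis rim point, clockwise through
the right edge. With chord-length parameterization `t` over perimeter `T`,
the Kuhl–Giardina expansion writes each coordinate as a Fourier series,

$$x(t) = A_0 + \sum_n a_n \cos\tfrac{2\pi n t}{T} + b_n \sin\tfrac{2\pi n t}{T},
\qquad
y(t) = C_0 + \sum_n c_n \cos\tfrac{2\pi n t}{T} + d_n \sin\tfrac{2\pi n t}{T}.$$

Because the start point sits on the symmetry axis and traversal is
clockwise, $x(t)$ is odd and $y(t)$ even in the contour parameter, so for a
bilaterally symmetric outline $a_n$ and $d_n$ vanish identically. The
implementation computes all four coefficients and *asserts* the suppressed
half is numerically zero (QC metric; a warning fires above $10^{-3}$
relative), rather than assuming symmetry. The surviving pairs
$(b_n, c_n)$, $n = 1..30$, are divided by the Euclidean norm of the first
pair, giving a strictly scale-invariant 60-D vector; division by the first
harmonic's semi-major axis is available via
`size_normalize(convention = "semi_major")` since the normalization
convention in prior outline-morphometrics software varies. No rotation or
phase normalization is applied: all outlines share the vertical wheel axis
by construction, so orientation is already standardized.

One numerical subtlety: under chord-length parameterization only curves
traversed at constant speed are single-harmonic, so a circle is exactly a
one-harmonic shape but an ellipse is not. `elliptic_fourier()` therefore
also offers `param = "uniform"` (equal parameter steps per vertex), under
which an ellipse sampled at equal angles reduces exactly to its first
harmonic — useful for validation; the chord-length default is what the
analysis uses.

## Shape space and trajectories

The pooled PCA is computed on the covariance (not correlation) of the 60-D
vectors: after size normalization all coefficients share one scale, and
standardizing would inflate the noise-dominated high harmonics. Axis signs
follow a deterministic convention (largest-magnitude loading element
positive) so scores are bit-reproducible. On synthetic studies with default
settings the first three axes carry well over 90 % of the variance, which
is why trajectories are drawn in 3-D.

Percent time maps each trial onto [0, 100] linearly in elapsed seconds.
Stage snapshots take the preform (gesture 0), the final gesture, and a
*middle* outline at the gesture-count midpoint `round((n-1)/2)` with
half-up rounding — the gesture index is robust to irregular gesture
timing; an elapsed-time midpoint would jump with pauses. A trial with only
two outlines has no distinct middle; the preform-adjacent outline is
returned with a degeneracy warning.

## Cross-projection subspace similarity

Each trial's own coefficient sequence gets its own PCA; `V1` is the
variance captured by its top three axes. Projecting trial A's data onto
trial B's axes captures `V2 <= V1` (PCA optimality), and
`S = (V2/V1 + V2'/V1')/2` symmetrizes the two directions; `D = 1 - S` is
the path dissimilarity. Two choices deserve note:

* **Centering.** A's data are centered by A's *own* mean before projecting
  onto B's axes — B contributes directions only. "Variance explained" is a
  property of A's scatter; centering by B's mean would mix location and
  orientation differences into one number. (The alternative is a
  one-line change and was deliberately not exposed, to keep `D` a pure
  orientation comparison.)
* **Variance convention.** Population variances (divide by n) throughout,
  so ratios are free of sample-size corrections when trials have different
  gesture counts.

Trials with fewer than four outlines cannot support a rank-3 subspace and
are excluded with a warning. `D` is symmetric with zero diagonal but need
not satisfy the triangle inequality — it is a dissimilarity, not a metric,
which is fine for the permutation tests and UPGMA but would matter for
metric embeddings.

## Nested permutation MANOVA

Sums of squares are partitioned from the Gower-centered matrix
$G = -\tfrac12 J D^{(2)} J$: `SS(community)` and `SS(potter within
community)` are traces of `G` under the corresponding group projections,
and the partition conserves `SS(total) = tr(G)` exactly (asserted to 1e-8
in tests). The community pseudo-F uses the potter mean square as its
denominator; the individual pseudo-F uses the residual. Degrees of freedom
derive from the design (communities − 1; potters − communities;
observations − potters) — e.g. 2 and 18 for a 9/6/6-potter study.

Permutation schemes respect exchangeability under each null: the community
test permutes *whole potters* across communities preserving community
sizes; the individual test permutes observations among potters within each
community. P-values use the `(exceedances + 1)/(n_perm + 1)` estimator, so
the observed statistic is always a member of its own null and p = 0 is
never reported. For tiny designs `exhaustive = TRUE` enumerates all potter
assignments and returns the exact p. One practical caveat the test suite
documents: the community permutation null is discrete with as many atoms as
distinct potter partitions, so designs with very few potters (say 2 per
community: 15 partitions) cannot reach p ≤ 0.05 at all; calibration
studies here use at least 10 potters (~2100 partitions).

## Dispersion, dendrograms

Stage-wise heterogeneity uses the principal-coordinates construction:
eigendecomposition of `G`, coordinates split into real and imaginary parts,
and squared distances to group centroids computed as the real contribution
minus the imaginary one; rare negative squared distances are clipped to
zero with a diagnostic. For Euclidean input this equals the direct distance
to the group mean (tested to 1e-8, and cross-checked against an independent
implementation of the same construction). Homogeneity is tested by a
one-way F on the distances with label permutation. The default metric is
the alternative Gower — mean absolute difference over columns not zero in
both observations; with signed Fourier coefficients double zeros
essentially never occur, so it acts as a scaled city-block distance.

Potter-level dissimilarities are the arithmetic mean over all cross pairs
of two potters' trials. UPGMA dendrograms come from average-linkage
`hclust`; reported heights are on the cophenetic/2 scale so the tree is
ultrametric with leaf-to-root depths equal to half the cophenetic distance,
and Newick export carries branch lengths on that scale.

## Hierarchical trajectory models

Models are fitted with mgcv (REML), cubic P-splines with second-order
difference penalties, basis dimension 10 per smoother:

* **G** — one global smoother of percent time;
* **S** — community-specific smoothers sharing one smoothing parameter
  (`id = 1`), plus community intercepts; no additional global term, the
  simpler of the two standard readings of "group-specific smoothers";
* **SI** — S plus potter-level factor smoothers (`bs = "fs"`, shared
  smoothing parameter) whose penalized null space carries the potter
  intercepts.

Each PC is modeled independently. AIC is mgcv's conditional AIC.
Out-of-sample performance uses the odd/even trial split (train 1, 3, 5;
test 2, 4) and the Gaussian *family* deviance of held-out data — the sum of
squared prediction errors, i.e. twice the saturated-minus-model
log-likelihood at a common scale. An earlier variant that divided each
model's test error by its own training scale was rejected: it mechanically
inflates the deviance of better-fitting models and can invert the ranking
even when their predictions are uniformly closer.

## The synthetic generator

Real video-derived profile data are not shipped; `generate_study()` stands
in with a seeded simulacrum of the study design: 3 communities with 9/6/6
potters, 5 trials per potter and vessel type, 6–14 outlines per trial, 256
points per profile. Vessels are monotone-height radius profiles with six
control points, spanning cylinder-, bowl-, sphere- and vase-like
silhouettes, with clay mass scaling linear dimensions as mass^(1/3).

A trial interpolates control points from a community-styled preform to the
vessel-type template along a potter-specific monotone schedule, with a
mid-path waypoint: one community style overshoots in height before
shortening (tall-barrel paths), one moves gradually, one starts from flat
disk-like preforms with wide bottoms. All community-level structure scales
with `sigma_community` and all potter-level structure with `sigma_potter`,
so zeroing either removes that level exactly — this is what
`generate_null()` exploits. Trial-level control-point noise
(`sigma_trial`) and per-point measurement noise on x (`sigma_measurement`)
are always present. The `stage_scale` schedule (default 2, 1, 0.6 at
preform, middle, final) multiplies effect and noise magnitudes along the
path, so variation narrows toward the final shape — the regime expected
when potters converge on an intended form from idiosyncratic preforms. Defaults (0.6, 0.35, 0.15, 0.02 cm) were fixed once to give
strong community and potter structure against small trial noise.

Every random draw flows from one seed through deterministic per-potter and
per-trial sub-seeds, so identical configs give bitwise-identical data and
any subset is reproducible in isolation. `ground_truth()` returns the
exact offsets used, for recovery tests. Three small frozen studies
(coordinates rounded to 4 decimals) ship under `inst/extdata/` as
pipeline-input fixtures.

What the generator does *not* emulate: clay mechanics (wall thinning,
collapse risk), left–right asymmetries, digitization artifacts beyond
Gaussian noise, gesture-level temporal structure, or the absolute
dimensions of any real assemblage. Passing tests therefore demonstrate
that the statistical machinery detects and calibrates the kinds of
structure the design postulates — not that any particular real-world
dataset contains them.

## Problem sizes and runtime choices

Simulation-based tests use deliberately small designs so the whole suite
runs in minutes: null-calibration studies use 4/3/3 potters x 2 trials
with 199 permutations per dataset (1,000 datasets), power and dispersion
studies 3/2/2 or 7 potters x 3–4 trials (50 runs), and model-selection
studies 20 seeds of a 9-potter trajectory simulation. Final-shape-only
questions run only each trial's last outline through the pipeline. The
analysis defaults (10,000 permutations, 30 harmonics, 256 points) remain
the package defaults.

## Known limitations

* Resampling on a regular vertical grid assumes x is single-valued in y;
  overhanging (necked) profiles fall back to arc-length parameterization
  and are flagged, but the two parameterizations are not mixed within one
  analysis automatically.
* The alternative-Gower double-zero rule is inert on signed coefficients;
  it is retained for fidelity to field practice, not because it changes
  anything relative to city-block/60.
* `D = 1 - S` compares 3-D subspace orientations; trials whose variation
  is genuinely lower-rank are excluded rather than padded.
* The community permutation test is granular in small designs (see above);
  report exact enumeration (`exhaustive = TRUE`) when feasible.
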