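---
title: "Archetypal analysis of visual-field loss across stimulus sizes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Archetypal analysis of visual-field loss across stimulus sizes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vfarchetypes)
```

## The problem

Standard automated perimetry measures differential light sensitivity (dB) at
52 usable locations of the 24-2 grid. The Goldmann size III stimulus is the
clinical default, but its useful dynamic range collapses in eyes with
moderate-to-severe loss; the larger size V stimulus is more reliable in
damaged fields. Whether the *patterns* of loss seen through the two stimuli
agree is the question this package's pipeline answers: decompose each
cohort's fields into archetypal loss patterns, fit each stimulus
independently, and measure how well the two archetype sets match.

## The model

Archetypal analysis (AA) approximates the `n x 52` total-deviation matrix
`X` by `A Z` with `Z = B X`, where rows of `A` (one per field) and rows of
`B` (one per archetype) lie on the probability simplex. Archetypes are
therefore convex combinations of observed fields and every field is a
convex combination of archetypes: AA finds *extremal* patterns — the pure
defects — rather than central tendencies, which is what makes it suited to
visual fields, where clinically meaningful classes (altitudinal loss,
arcuate scotoma, nasal step, ...) are the extreme presentations.

The fit alternates two exact steps:

* **A-step** — for each field, simplex-constrained least squares against
  the current archetypes (an active-set quadratic program, solved exactly).
* **B-step** — for each archetype `j` in turn, the objective restricted to
  `z_j = B_j X` is `||a_j||^2 ||z_j - z*_j||^2 + const` with
  `z*_j = R_j' a_j / ||a_j||^2`, so projecting the ideal archetype `z*_j`
  onto the convex hull of the data (again a simplex-constrained least
  squares) minimizes the true residual exactly.

Both steps are exact coordinate-descent moves, so the training RSS is
non-increasing at every iteration — the package asserts this invariant in
its tests. AA is non-convex; fits restart from `n_restarts` furthest-sum
initializations (default 5) and keep the best RSS. Convergence is declared
at a relative RSS improvement below `tol = 1e-6` or 500 iterations,
comfortable for 52-dimensional problems with a few thousand rows.

## Preprocessing

Raw sensitivities pass through a fixed chain, in this order:

1. **Canonicalization** — left eyes are mirrored about the vertical
   midline onto right-eye orientation (a pure index permutation: rows of
   the grid reverse). Pooling eyes without anatomic alignment would blur
   nasal/temporal structure; the step can be disabled.
2. **Quality exclusion** — fields with false-positive rate strictly above
   20% are dropped. Spuriously high sensitivities create positive TD
   outliers, and AA builds archetypes from the edges of the data cloud,
   so unreliable extremes are disproportionately harmful.
3. **Censoring** — sensitivities strictly below 21 dB (size III) or 24 dB
   (size V) are replaced by the threshold. Below these levels perimetric
   responses are noise-dominated and unrepeatable; the thresholds are the
   values that equate the two stimuli in moderate-to-severe disease.
   Values exactly at threshold are untouched; the operation is idempotent
   and monotone. An uncensored pathway (`censor_values = FALSE`)
   supports sensitivity analyses.
4. **Total deviation** — TD = sensitivity minus the age-matched normal
   sensitivity per location, per stimulus. Proprietary normative
   databases cannot be redistributed, so the package uses a declared
   parametric normative model (per-location intercept at age 50 plus a
   linear age slope; the synthetic default puts size V about 3 dB higher
   with a flatter eccentricity profile). Plain subtraction, no
   eccentricity-dependent correction beyond the normative profile itself.

`to_td()` refuses uncensored input unless explicitly overridden, freezing
the censor-then-standardize order.

## Model selection

`cv_rss_curve()` computes RSS against the number of archetypes (default
2–20) under 10-fold cross-validation. Held-out error is the only subtle
choice: the fold's archetypes are frozen and the held-out fields are
*decomposed* onto them (weights refit), which is the meaningful
out-of-sample residual for AA. Both train and test curves are returned
because published RSS-versus-k displays do not always say which is shown.
Fold assignment shuffles with the seed and can be grouped (both stimuli of
a patient in the same fold) to prevent leakage between paired fields.

`select_k()` automates the elbow as the point of maximum perpendicular
distance to the chord joining the curve's endpoints (ties break toward
smaller k, so a flat curve gives the smallest k). The published analyses
chose k = 14 by judgment — balancing parsimony against residual error —
so manual override is first-class and merely warns when the manual choice
sits more than 10% above the curve's minimum.

## Comparing archetype maps

Archetypes are ordered by relative weight (RW, the archetype's share of
total decomposition mass, normalized to 100%). Two maps are compared by
cosine similarity — the normalized dot product over the 52 locations,
intensity-invariant, so it scores the *shape* of a defect, not its depth —
and paired greedily: the globally most similar pair is assigned and both
members removed, repeating until exhaustion, exact ties broken toward the
lowest indices. Greedy pairing is the published procedure; the Hungarian
optimum is available as `optimal_pair()` for diagnostics only, and the
tests include adversarial matrices where the two disagree. Pairs with
similarity at or above 0.8 are counted as concordant.

`combined_analysis()` pools both stimuli, fits one map, decomposes each
stimulus onto it, and compares per-archetype RWs with two-sided Wilcoxon
signed-rank tests on the paired per-field weights at alpha = 0.05. Zero
differences are dropped before ranking (the classical convention); a
column with no nonzero differences is reported untestable rather than
given a p-value. No multiple-testing correction is applied by default,
matching the per-test alpha of the published analysis; Holm adjustment is
available.

Cosine similarity treats the field as a flat 52-vector and ignores the
spatial adjacency of locations; two patterns differing by a small spatial
shift score lower than visual inspection would suggest. This limitation
affects both stimuli equally, so cross-stimulus comparisons remain
meaningful.

## The synthetic generator

No clinical perimetry datasets ship with the package; `simulate_vf_dataset()`
generates cohorts with the statistical structure the analysis assumes.
Per patient: age uniform on 45–85 years (matching the cohort means of the
motivating studies), mixture weights from a symmetric Dirichlet, and a true
TD pattern equal to the convex mixture of ground-truth archetypes. The
*same* TD pattern generates both stimuli of a pair — the generator encodes
the hypothesis the pipeline is designed to test. Sensitivity = normative
value + TD + Gaussian noise, floored at 0 dB.

Defaults, chosen once as the study conditions:

* `noise_sd = 1.0` dB — test–retest variability of sensitivities in the
  preserved (above-censoring) range is roughly 1–2 dB; censoring removes
  the highly variable low range where variability is far larger. A
  sensitivity-dependent option doubles the SD below 25 dB to mimic the
  signal-to-noise collapse at low sensitivities.
* `weight_concentration = 0.3` — clinical fields are typically dominated
  by one or two patterns; sub-unit concentration produces that sparsity.
* `fp_contamination = 0.013` — about the fraction of fields the
  motivating analyses excluded for false-positive rates above 20%.
* `n_patients = 500` — the scale used throughout the package's own
  experiments; large enough for stable archetypes, small enough that the
  full pipeline runs in minutes on one CPU.

The ground-truth library (`make_default_archetypes()`) contains 16 fixed
patterns — near-normal, uniform severe loss, altitudinal, arcuate, nasal
step, central, ring, wedge and quadrant defects — with pairwise cosine
similarity at most 0.9 and values in [-20, 5] dB.

What the generator does *not* emulate: staircase quantization and
test–retest asymmetries of real thresholding algorithms, fixation losses,
spatially correlated noise, longitudinal progression, and floor effects
beyond the 0 dB clip. Passing recovery tests therefore show that the
pipeline's numerics are sound under its stated model, not that archetypes
of real cohorts are recoverable at these accuracies.

### Corner coverage in recovery experiments

AA can only identify an archetype whose corner of the weight simplex is
approached by data. A symmetric Dirichlet(0.3) at n = 500 essentially
never produces a near-pure field (the probability of a weight above 0.9 is
about 1.6e-5 per draw at k = 14), and a weak-norm pattern like the
near-normal archetype is displaced by even a 5% admixture of strong
defects. Real cohorts do contain pure presentations — fully normal eyes,
textbook altitudinal defects — so the recovery experiments use
`recovery_weights()`: Dirichlet draws with 5% of rows replaced by exact
unit vectors spread equally over the archetypes. Recovery of the
near-normal archetype remains the hardest case (its norm is comparable to
the noise), which is why recovery fits use 10 restarts.

## Numerical choices

* Simplex-constrained least squares is solved exactly by a primal
  active-set method on the normal equations (supports never exceed the
  ambient dimension plus one, so the KKT systems stay small even when
  projecting onto the hull of thousands of points); a tiny ridge
  (1e-12 relative) guards duplicated-point degeneracies.
* Weights are fractions internally and percentages at reporting surfaces.
* RW sorting breaks ties by original index; greedy pairing breaks exact
  similarity ties by lowest (row, column) index — both purely for
  determinism.
* `fit_aa(k = 1)` recovers the column mean (the simplex forces unit
  weights and the mean lies in the hull); `k = n` interpolates exactly.
  Both serve as analytic anchors in the tests.
* All randomness (initialization, folds, the generator) is governed by
  explicit integer seeds; RNG state is restored on exit.

## Worked example

```{r example, eval = FALSE}
cfg <- synthetic_config(k_true = 14, n_patients = 500, seed = 1)
sim <- simulate_vf_dataset(cfg)

cc  <- censoring_config()            # 21 dB (III), 24 dB (V), FP > 20% out
td3 <- preprocess_vf(sim$vf_III, cfg = cc)$td
td5 <- preprocess_vf(sim$vf_V,   cfg = cc)$td

m3 <- fit_aa(td_matrix(td3), k = 14, seed = 2)
m5 <- fit_aa(td_matrix(td5), k = 14, seed = 3)

pr <- greedy_pair(build_map(m3, "III"), build_map(m5, "V"))
pr$n_above     # pairs with cosine similarity >= 0.8 (out of 14)

comb <- combined_analysis(td_matrix(td3), td_matrix(td5), k = 14, seed = 4)
comb$mean_abs_diff   # mean |RW(III) - RW(V)| in percent
```

## Known limitations

* The normative model is synthetic; absolute TD levels are not comparable
  to values computed against instrument databases.
* Archetype numbering depends on the optimizer's restarts and the data;
  only similarity-based pairing, not index identity, is meaningful across
  runs or against published maps.
* Greedy pairing is order-dependent by design (it reproduces the
  published procedure); one poor early match can cascade. The optimal
  assignment is available for diagnosis but is not the pipeline's output.
* The Wilcoxon comparison treats fields as exchangeable; repeated visits
  of one patient are not modelled (per-field pairing is the default).
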