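---
title: "Dynamic functional subgraphs: model, estimator choices, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic functional subgraphs: model, estimator choices, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`dynsubgraphs` decomposes dynamic functional connectivity into a small set
of overlapping network *subgraphs* and per-window *expression
coefficients*, then asks how strongly and how flexibly each subgraph is
expressed in each subject. This vignette is the package's own account of
the method: the model and its assumptions, the tunable parameters and why
their defaults are what they are, what the synthetic-cohort generator does
and does not emulate, and the numerical conventions that make results
reproducible.

## 1. From time series to the cohort matrix

Each subject contributes an `N x n_samples` matrix of region time series.
The pipeline proceeds:

1. **Sliding windows.** Windows of `window_len = 20` samples advance by
   `round(window_len * (1 - overlap_frac))` samples; at 90% overlap the
   step is 2 samples, and a 120-sample series yields T = 51 windows.
   Trailing samples that do not fill a window are dropped.
2. **Wavelet coherence.** The edge weight `A[i, j, l]` is the
   magnitude-squared wavelet coherence between regions i and j, averaged
   over the 0.02-0.08 Hz band and the samples of window l. The estimator
   is a complex Morlet continuous wavelet transform (center frequency
   `omega0 = 6`, scale resolution `dj = 1/12`) with Grinsted-style
   smoothing: a Gaussian in time whose width matches the scale, and a
   0.6-octave boxcar across scales. Smoothing is what makes the coherence
   ratio informative; without it the ratio is identically one. The
   transform is computed once on the full-length series and averaged
   within windows: at a 3 s sampling interval the slowest in-band period
   (50 s) is longer than a 20-sample window, so per-window transforms
   would be ill-posed. The estimator sits behind a single function
   (`wavelet_coherence()`) and can be swapped without touching anything
   downstream.
3. **Layer normalization.** Each `N x N` layer is divided by the mean of
   its upper-triangle entries (the structurally zero diagonal is excluded,
   since including it would bias the mean). The operation is idempotent
   and makes layers comparable across windows and subjects.
4. **Unfolding.** The upper triangle of each layer is stacked as a column,
   using the fixed lexicographic pair order (1,2), (1,3), ..., (2,3), ...
   — a stated convention, so fold/unfold is a bijection.
5. **Motion regression.** For each (edge, window) cell, edge values are
   regressed on a per-subject scalar motion covariate across subjects;
   the fitted slope component is removed and the intercept retained.
   Retaining the intercept is deliberate: pure residuals would center
   every edge at zero and destroy the nonnegative scale the factorization
   needs. The few resulting negative values are clipped to zero.
6. **Concatenation.** Per-subject `E x T` matrices are concatenated
   column-wise into the cohort matrix `X` (`E x T*S`), with an invertible
   column-to-(subject, window) map.

**Sampling interval.** The package default is `tr_seconds = 3`. A roughly
six-minute resting acquisition at that interval yields about 120 usable
samples, which is exactly what produces the canonical T = 51 windows under
the 20-sample / 90% geometry.

## 2. The factorization

The cohort matrix is factorized as `X ~ W H` with both factors
nonnegative, by minimizing

```
0.5 * ||X - W H||_F^2  +  eta * ||W||_F^2  +  beta * sum_j (sum_i H[i, j])^2
```

`W` (`E x k`) collects k subgraphs — nonnegative edge-weight patterns —
and `H` (`k x T*S`) their expression coefficients per window and subject.
The `beta` term is the squared L1 norm of each coefficient column
(column-wise sparsity); the `eta` ridge bounds subgraph edge strengths.
Because the decomposition is parts-based, subgraphs act as additive parts
rather than signed contrasts.

* **Initialization** is the deterministic NNDSVD (plain variant: zero
  blocks kept, no mean filling — the alternating solver tolerates zeros,
  and determinism is worth keeping). The sign ambiguity of each
  singular-vector pair is resolved toward the section with the larger
  positive-part mass, ties to positive.
* **Optimization** is alternating nonnegativity-constrained least squares
  (ANLS): each factor update solves its convex subproblem *exactly*, via
  block principal pivoting on the normal equations with a Lawson-Hanson
  active-set fallback for pathological columns. The augmentations
  `[W; sqrt(2 beta) 1']` and `[H'; sqrt(2 eta) I]` make the subproblem
  stationary points coincide with those of the printed objective, so the
  objective trace is non-increasing by construction — this is asserted on
  every test run. Exactness of the subproblem solutions is the reason the
  inner solver is a pivoting method rather than a multiplicative update.
* **Stopping**: relative objective change below `tol = 1e-6`, or
  `max_iter = 200` sweeps. Both are exposed; the defaults are practical
  rather than principled, and tight tolerances (1e-9, 500 sweeps) are used
  where tests require near-exact recovery.
* **Identifiability of reporting.** NMF is permutation- and
  scale-invariant, so subgraphs are reported sorted by descending total
  coefficient mass (row sums of H).
* `eta` defaults to `max(X)^2`, a standard scaling that ties the ridge to
  the data's dynamic range. Recovery-style analyses may prefer
  `eta = 0`; both appear in the tests.

**Choosing k and beta.** Training error is monotone in k, so it cannot
pick a rank. The default selector masks 10% of the entries of X, replaces
them by their column means (computed from the retained entries) during
fitting, and reports mean-squared error on the masked entries; the
minimizer over the `(k, beta)` grid is returned. A single imputation round
is used deliberately: EM-style re-imputation of the masked entries leaks
the held-out information back into the fit through the imputation loop
and, in our checks, overfit the rank upward. An `elbow` alternative
(maximum discrete curvature of training error in k) is retained for
comparison. The objective evaluation inside the solver uses the direct
residual rather than the expanded trace identity — the identity cancels
catastrophically once the fit is tight and would make a genuinely
monotone trace look non-monotone.

**Projection.** New subjects are scored against a fixed basis by solving
the same augmented nonnegative least-squares problem for their coefficient
columns with W held fixed (the ridge on W plays no role in that
subproblem). Projecting a training subject's own block reproduces its H
block.

## 3. System mapping

Subgraphs are summarized over an a-priori node-to-system partition. With
`P_s` the node set of system s:

* within-system connectivity: `R_s = sum_{i, j in P_s} V[i, j] / |P_s|^2`
  — the denominator is `|P_s|^2` *as printed*, with the zero diagonal
  inside the index set, so an all-ones system of size n attains
  `1 - 1/n`, not 1; this ceiling is a documented property of the formula,
  not a bug.
* between-system connectivity:
  `I_st = sum_{i in P_s, j in P_t} V[i, j] / (|P_s| |P_t|)`.

The m x m system matrix collapses an `N x N` subgraph to system
resolution. *Locality skewness* is the bias-uncorrected sample skewness of
its off-diagonal upper-triangle entries: localized subgraphs concentrate
mass in few system pairs and are strongly right-skewed.

Which systems dominate a subgraph is assessed by label permutation: the
per-system statistic is the column sum of the full symmetric system matrix
(diagonal included — the statistic is read literally as a column sum);
the null shuffles node labels uniformly (system sizes preserved), and a
system is flagged above the one-sided 95th percentile of its own null,
uncorrected for multiple comparisons. Flags are for reporting which
systems carry a subgraph; matrices themselves are never thresholded.

## 4. Expression dynamics

For each (subject, subgraph) coefficient series `S_n` of length L:

* **energy** `sum S_n^2` — total expression magnitude;
* **entropy** — Shannon entropy (natural log) of the series binned into
  `n_bins = 10` equal-width bins over its own `[min, max]`; a constant
  series is defined to have entropy 0 (the limiting value). The bin count
  and base are estimator choices, exposed in every signature; all
  cross-group comparisons use one setting. Range-adaptive binning makes
  the estimator affine-invariant: it measures switching, not scale.
* **temporal derivative** — mean |first difference|, a near-synonym of
  entropy for switching-type dynamics.

**Standardization** divides each (subject, subgraph) series by its own
mean, making comparisons relative rather than absolute. The
per-subject-and-subgraph convention is the primary one; a
per-subject-only variant (pooling subgraphs) is available behind the
`per_subject_only` flag, because the two conventions are both defensible
readings and the choice matters.

Statistical procedures:

* the **energy-entropy relation**: Pearson correlation between log mean
  energy and mean entropy across subgraphs (means taken over subjects),
  with an element-shuffle permutation null — all entries of H are shuffled
  jointly, shape preserved, and the correlation recomputed; p values use
  add-one smoothing `(1 + #{|r*| >= |r|}) / (n_perm + 1)`.
* **group comparisons**: two-sided Wilcoxon rank-sum. The z statistic is
  always the tie-corrected normal approximation with continuity
  correction, signed so that z is negative when the second-listed group
  has larger ranks; the p value uses the exact rank-sum distribution when
  samples are small and untied. Group medians are reported alongside so
  the direction is never ambiguous.
* **motion checks**: Pearson correlations of energy and entropy against
  the motion covariate, as a negative control after motion regression.
* **behavior association**: flexibility (entropy of projected
  effect-subgraph weights by default; mean absolute derivative as the
  alternative — both are implemented because the construct admits either
  operationalization) and behavior are each residualized on age by
  ordinary least squares, the residuals correlated, and significance
  assessed by permuting the residualized behavior.

## 5. The synthetic cohort: what it emulates, and what it does not

Real data for this design are access-restricted, so validation rests on a
generator with known ground truth. It plants:

* `k_true` nonnegative subgraphs, each supported on one or two systems of
  the partition. Regions of a system claimed by several subgraphs are
  split among them, so region supports are **disjoint across subgraphs**.
* coefficients as **two-state (high/low) Markov chains** per (subject,
  subgraph): the state levels (`low_state = 0.3`, `high_state = 1`) set
  the energy; the toggle probability (`switching_prob = 0.10`) sets the
  entropy. The two dials are separate on purpose — the scientific claims
  concern expression level versus switching, and a Gaussian coefficient
  model would entangle them.
* a **fixed count of silent windows** (6% of T, random positions) per
  series, set exactly to zero.
* a designated "executive-like" effect subgraph spanning two systems: in
  the adult group its high state is scaled by `energy_ratio = 1.5` and
  its toggle probability raised by `switching_increment = 0.20`, so both
  planted energy and planted entropy are larger in adults.
* optionally, region time series realizing the coefficients (band-limited
  latent oscillators shared within subgraphs, per-sample amplitude
  proportional to the square root of the coefficient), a nonnegative
  motion confound added linearly to all edges, and a behavior score
  `z(flexibility) + 0.5 * z(age) + noise` with unit noise
  (signal-to-noise 1).

**Why silent windows and disjoint supports.** With strictly positive
coefficients and disjoint basis supports, the planted factorization is
provably non-unique: for any pair of subgraphs, mixing
`W[, j] + e * W[, i]` with `e <= low_state / high_state` keeps both
factors nonnegative after the inverse mixing of H. In that regime the
solver reaches exact reconstruction while landing on a mixed solution,
and "recovery" is not a meaningful test. A few exact zeros per
coefficient row anchor the factorization. The silent count is fixed
rather than Bernoulli because a random silent mass adds between-subject
entropy variance that dilutes the planted entropy effect.

**Default magnitudes.** The state levels, switching probabilities and
group increments were fixed by a design simulation at the study's scale
(two groups of 50, T = 51, 200 replicate cohorts) before any validation
was written: standardized energy reaches power ~1.0, standardized entropy
~0.9 at the 5% level, and the no-effect configuration rejects at ~5%.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: hemodynamics and scanner artifacts; spatial
geometry of a real parcellation; spatially overlapping subgraphs;
continuous (non-discrete) coefficient distributions; realistic coupling
between subgraph scale and switching across subgraphs (only the effect
subgraph couples them). Tests demonstrate that the estimators recover
what was planted under this model, not that the model is true of brains.

## 6. Numerical conventions and degenerate inputs

* Coherence of a constant (zero-power) series is defined as 0 and
  flagged; coherence values are clipped to [0, 1].
* A zero-mean layer cannot be normalized and is an error naming the
  layer; zero-variance motion skips regression with a warning (identity
  transform); a zero-mean coefficient series is reported and left
  unstandardized rather than divided.
* Negative values produced by noise or motion regression are clipped to
  zero — the same one-line rule everywhere.
* Zero-variance skewness and constant-series entropy are defined as 0.
* NNDSVD components beyond the numerical rank are zero-padded with a
  warning. NNLS tie-breaks and the NNDSVD sign rule are deterministic, so
  every fit is reproducible from its inputs alone.
* Permutation p values are never exactly zero (add-one smoothing).

## 7. Problem sizes used in validation

The validation suite runs at desk scale, chosen as the package's standard
test geometry: cohorts of 40 regions / 4 systems / 4 subgraphs / T = 51,
with 20-40 subjects for factorization checks, 24 subjects across 10
replicates for rank selection, 100 subjects (50 per group) across 200
replicate cohorts for the group-effect power analysis, 200 subjects for
confound-removal checks, and 500 replicates for permutation calibration.
The full 264-region, 200-subject geometry is a linear scale-up of the
same code paths.

## 8. Known limitations

* **Motion regression injects estimation noise.** Removing a
  covariate whose slope is estimated across S subjects perturbs every
  edge by roughly `sd(slope error) * motion`; at small S this is not
  negligible. Because the histogram entropy of a near-discrete series is
  exquisitely sensitive to such smearing (it spreads mass across bins,
  and relatively more so for series with smaller dynamic range), the
  planted *entropy* group effect can be attenuated or even inverted after
  the full pipeline at desk scale, while the energy effect survives
  comfortably. On real, continuous-valued data this sensitivity is far
  milder; it is a property of the discrete synthetic coefficients.
* The coherence estimator's smoothing choices (Gaussian time kernel,
  0.6-octave scale boxcar) are standard but not canonical; other
  smoothers change absolute coherence levels, though layer normalization
  absorbs much of that.
* The holdout selector assumes entries are missing at random within
  columns; structured missingness would need a weighted factorization.
* The two-state coefficient model cannot represent graded expression
  levels; entropy contrasts between groups are driven by occupancy
  variability, which is one of several mechanisms real data might use.
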