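---
title: "Feature-weighted random forests for monitoring data: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature-weighted random forests for monitoring data: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asvrf)
```

## The problem

Continuous patient monitoring — glucose sensors being the canonical example —
produces tabular streams of repeated readings per subject: a handful of
continuous channels, many gaps (dropped transmissions, sensor detachment),
and a clinical state to be recognized per reading ("normal" versus
"alarming"). Plain random forests cope badly here: with a shallow feature
space and heavy missingness, uniformly random feature subsampling frequently
hands a tree nothing but noise. This package implements a classification
stack built around a forest whose feature subsampling is *biased by
chi-squared feature–class association*, with the surrounding stages
(normalization, discriminant projection, swarm-based tuning, a metric suite,
and a synthetic cohort generator) needed to use and to test it end to end.

## The pipeline, stage by stage

### Min–max normalization with median imputation

Each feature is affinely mapped from its observed training range
$[d_{\min}, d_{\max}]$ onto $[\mathrm{new_{\min}}, \mathrm{new_{\max}}]$
(defaults $[0,1]$):

$$x' = \frac{x - d_{\min}}{d_{\max} - d_{\min}}
  (\mathrm{new_{\max}} - \mathrm{new_{\min}}) + \mathrm{new_{\min}}.$$

Decisions where the formula is silent:

* **Missing values.** Entries are kept as an explicit `NA` mask, never a
  sentinel number (a sentinel silently corrupts scatter matrices and
  contingency counts). Before scaling, missing cells are imputed with the
  per-feature **training median** (mean optional) — simple, robust to the
  skew typical of physiological measurements, and order-independent. C4.5's
  fractional-instance routing of missing values is deliberately not used;
  handling missingness once, ahead of the ensemble, keeps every downstream
  stage total.
* **Constant features** ($d_{\max} = d_{\min}$) map to
  $\mathrm{new_{\min}}$; anything else propagates NaN.
* **Out-of-range test values** are clipped into the target range, keeping
  test data inside the range the discretization bins were calibrated on.
* Fitting only ever sees training data — the transform is estimated once and
  applied everywhere, so no test-set statistics leak into the model.

### Linear discriminant feature extraction

With between-class scatter $S_C = \sum_k M_k (\mu_k - \mu)(\mu_k - \mu)^T$
and within-class scatter
$S_V = \sum_k \sum_{x \in X_k} (x - \mu_k)(x - \mu_k)^T$, the basis vectors
maximize the Rayleigh quotient $w^T S_C w / w^T S_V w$, i.e. solve the
generalized eigenproblem $S_C w = \psi S_V w$. At most $a - 1$ eigenvalues
are non-zero for $a$ classes, so $L \le \min(n, a-1)$.

* $S_V$ can be singular (few rows, collinear channels). We solve
  $S_C w = \psi (S_V + \lambda I) w$ with a Tikhonov ridge, default
  $\lambda = 10^{-6}\,\mathrm{tr}(S_V)/n$ — the standard fix, leaving
  well-conditioned problems essentially untouched.
* Eigenvector signs are arbitrary; we fix them (largest-magnitude component
  positive) so serialized models are reproducible byte for byte.
* The stage is **optional**. For binary labels it projects to a single
  dimension, which is the right thing for a compact deployed model but makes
  the forest's weighted feature subsampling vacuous (one feature, nothing to
  weight). The default pipeline keeps the canonical
  normalize → extract → classify order; ablation studies of the forest
  itself should disable it (`pipeline_config(lda = FALSE)`), and the
  package's own ensemble benchmarks do exactly that.

### Chi-squared feature weighting

Each feature's association with the class label is scored by the
contingency statistic

$$\chi^2 = \sum_{i=1}^{m}\sum_{j=1}^{a} \frac{(O_{ij} - e_{ij})^2}{e_{ij}},
\qquad e_{ij} = \frac{\#(A = a_i)\,\#(C = c_j)}{N},$$

computed over $m$ feature levels and all $a$ classes (the binary case is
recovered exactly). Continuous features are discretized by
**equal-frequency binning** (default 5 bins, edges fitted on training data
only) — robust to skew and leakage-safe. Cells with $e_{ij} = 0$ contribute
zero rather than NaN: such cells arise when a level or class is absent from
a bootstrap sample, and continuity there matters more than pedantry.
Weights are computed **once** on the full (post-projection, when enabled)
training set, before the tree loop — not per bootstrap.

The top $n' = \max(1, \mathrm{round}(\beta n))$ features by weight (ties:
lower index) form the candidate space for all trees.

### C4.5 base trees

The base learner is a binary-threshold C4.5-style tree: candidate
thresholds are midpoints between consecutive distinct sorted values, scored
by **gain ratio** (information gain over split entropy), requiring strictly
positive information gain. All features are continuous after normalization
or projection, so multiway categorical splits never arise. Values equal to
a threshold route left ($\le$). Ties in gain ratio (within $10^{-12}$,
which also de-flakes floating-point comparisons between algebraically equal
splits) are broken by lower feature index, then lower threshold — the split
search is fully deterministic.

Leaves store **Laplace-smoothed** class frequencies
$(c_i + 1)/(n + a)$: the ensemble averages probabilities, and smoothing
keeps single-observation leaves from casting degenerate 0/1 votes. Trees
are grown unpruned by default (`max_depth`, `min_samples_leaf`,
`min_gain_ratio` are exposed) — low-bias trees are the conventional choice
inside an ensemble.

### The ensemble

For each of $k$ trees (default 50, a conventional desk-scale ensemble
size): draw a bootstrap sample of the rows; draw
$t = \lfloor \log_2 n' \rfloor + 1$ **distinct** features from the selected
pool, sequentially without replacement with probability proportional to
their chi-squared weights (an $\varepsilon = 10^{-12}$ floor keeps
zero-weight features selectable); grow a tree restricted to those features.
Two points where the procedure needed a decision:

* The $t$ features are drawn **once per tree**, not per node (a per-node
  mode exists as an ablation flag).
* Weighted sampling *with* replacement would yield duplicate features,
  which are vacuous for tree induction; sampling is therefore without
  replacement.
* The subset-size rule is applied to $n'$, the post-selection pool — the
  selection stage precedes the tree loop.

Prediction is the soft vote
$P(c_i \mid x) = \frac{1}{k} \sum_{j=1}^{k} P(c_i \mid x, h_j)$, a convex
combination of leaf distributions; the label is the argmax, ties to the
lowest class index. Out-of-bag accuracy is computed during training as a
free internal error estimate.

### Particle swarm tuning

The swarm minimizer is the canonical global-best PSO with a **linearly
decaying inertia weight**

$$v \leftarrow w\,v + c_1\,r_1\,(p_{best} - x) + c_2\,r_2\,(g_{best} - x),
\qquad x \leftarrow x + v,$$
$$w(\mathrm{iter}) = w_{\max} -
  \frac{w_{\max} - w_{\min}}{\mathrm{iter}_{\max}}\,\mathrm{iter},$$

defaults $c_1 = c_2 = 2$, $w_{\max} = 0.9$, $w_{\min} = 0.4$ — the
canonical settings. Velocities are clamped to 50% of each dimension's
range; positions leaving the box are reflected and the offending velocity
component flips sign (under the clamp a single reflection always lands
inside). Personal/global bests update only on strict improvement, making
tie behavior deterministic; non-finite objective values are recorded as
$+\infty$ and the particle keeps moving.

What does the swarm tune? The training algorithm exposes exactly two free
knobs, $\beta$ and $k$, so `tune_asvrf()` minimizes their stratified
cross-validated misclassification rate. Particles live in a continuous 2-D
box; at evaluation $\beta$ is clipped into $(0,1]$ and $k$ rounded — the
velocity/position updates stay verbatim in continuous space. Fold
assignment is seeded once, making the objective a deterministic function of
position, and decoded configurations are memoized.

### Evaluation

The metric suite derives from the binary confusion matrix (one-vs-rest per
class beyond two): accuracy, precision, sensitivity, specificity, F1, TP/FP
rates, proper/improper classified fractions, Cohen's kappa
$(p_o - p_e)/(1 - p_e)$ with chance agreement from the marginal products,
and MAE/RMSE between the positive-class probability and the 0/1 truth (the
only probability the pipeline produces). Two conventions worth stating:

* **Sensitivity and recall are the same quantity**, $TP/(TP+FN)$, and are
  emitted as two equal fields for table-format compatibility with the
  e-health literature, where both columns conventionally appear.
* Zero-denominator ratios are reported as 0 with a warning and a flag in
  the report's `undefined` field rather than as an error — degenerate CV
  folds must not abort a tuning run.

## The synthetic cohort generator

No suitable public cohort exists at the shape this stack targets, so the
generator *is* the test bed, with planted ground truth. It emulates a
monitoring study of 62 patients contributing ~200 readings each (~12.6k
rows): `n_informative = 5` correlated Gaussian channels (equicorrelation
0.2, chosen once as a mild, realistic sensor correlation) whose class means
differ by `class_separation = 1.5` standard deviations per feature,
`n_noise = 15` independent standard-normal distractors, a balanced binary
"normal"/"alarming" label per reading, and 20% missing-completely-at-random
cells. An optional per-patient random intercept (default sd 0) emulates
repeated-measures structure without complicating the i.i.d. analyses.

Because the generative model is known, the **Bayes error** is available in
closed form: with Mahalanobis separation $\Delta$ between the class means
(for the equicorrelated model,
$\Delta^2 = s^2 f / (1 - \rho + f\rho)$, patient variance added when
present) and priors $\pi_0, \pi_1$, the optimal error is
$\pi_1 \Phi(c/\Delta - \Delta/2) + \pi_0 \Phi(-c/\Delta - \Delta/2)$ with
$c = \log(\pi_0/\pi_1)$, reducing to $\Phi(-\Delta/2)$ at balance. Since
MCAR missingness only destroys information, $1 - $ Bayes error bounds any
classifier's achievable accuracy — the test suite uses this as a guard
against leakage bugs (no classifier may beat the bound beyond sampling
slack).

What the generator does *not* emulate: physiological glucose dynamics
(meals, insulin), informative missingness, sensor drift, label noise, or
class imbalance beyond a Bernoulli prior. Passing tests therefore certify
the algorithmic machinery under a clean generative model, not clinical
performance.

## Problem sizes in the test suite

The package's benchmark experiments run at desk scale, chosen once: 20
seeded cohorts of 62 patients × 16 readings (992 rows; all generative
parameters at the defaults above), 70/30 stratified splits, forest
$k = 50$, $\beta = 0.5$ against a single unpruned C4.5 tree. At this scale
the ensemble's mean test accuracy exceeds the single tree's by a wide
margin while remaining below the Bayes bound, and the chi-squared ranking
recovers all five planted channels essentially always. The swarm benchmark
is the 5-D sphere ($N_p = 30$, 200 iterations). The
`scripts/acceptance.R` entry point re-runs these computations from scratch
and writes the resulting numbers as JSON.

## Numerical and reproducibility conventions

* Every random stage draws its seed from the single global seed through
  named sub-streams (`derive_seed`), so stages are independently
  reproducible and uncoupled.
* Split-search ties and eigenvector signs are fixed deterministically (see
  above); identical config + seed yields byte-identical serialized models.
* Model bundles serialize to versioned JSON with doubles at 17 significant
  digits — enough to round-trip IEEE doubles exactly, hence bit-identical
  reloaded predictions, while staying human-inspectable and
  language-portable.
* Class labels are encoded as dense integer codes in first-seen order;
  predictions are reported as the original label strings.

## Known limitations

* The split search is exact but $O(t \cdot N \log N)$ per node in plain R;
  very large cohorts (millions of rows) would want a compiled backend.
* The discriminant stage assumes roughly Gaussian classes with shared
  covariance; heavy-tailed channels should be transformed first.
* Chi-squared weighting scores features marginally; jointly informative
  but marginally flat features (XOR-style) will be under-weighted — an
  inherent property of the weighting scheme, not of the implementation.
* Missingness is handled by imputation only; informative missingness
  patterns are neither modeled nor detected.
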