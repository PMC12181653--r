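---
title: "Methods: cross-lagged panel networks and the construct-level path model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-lagged panel networks and the construct-level path model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(clpnet)
```

This vignette is the package's own account of the models it fits, the
choices behind their defaults, and the limits of what its tests establish.

## The two levels of analysis

Comorbidity questions in two-wave panel studies can be asked at two
resolutions. At the **construct level**, composite scale scores (here:
CPTSD via the 12-item ITQ, depression via the PHQ-9, anxiety via the GAD-7)
enter a cross-lagged path model whose parameters answer "does CPTSD at
baseline predict anxiety six months later more strongly than the reverse?".
At the **symptom level**, each of the 28 items is a node in a directed
network whose edge `i → j` is the regularized regression coefficient of
wave-2 symptom *j* on wave-1 symptom *i*; the network answers "which
specific symptoms drive, and which are driven by, the rest of the system?".
`clpnet` implements both on the same preprocessed data, because the two
levels are complementary: path models borrow power by aggregation, networks
localize the dynamics.

## The cross-lagged panel network estimator

For each wave-2 outcome (z-scored within wave), the predictor block is all
28 z-scored wave-1 items plus gender and age. The fit minimizes

$$\frac{1}{2n}\lVert y - \beta_0 - X\beta \rVert^2 + \lambda \sum_{j \in \text{penalized}} |\beta_j|$$

by cyclic coordinate descent in covariance (Gram) form, with the intercept
and the covariate columns unpenalized — covariates are controls, and
penalizing them would let symptom edges absorb demographic variance.
Assumptions worth stating: ordinal item responses are treated as numeric
(the convention of the applied CLPN literature), effects are linear, and
each outcome's regression conditions on all wave-1 items, so an edge is a
*unique* prediction above and beyond every other baseline symptom.

Standardizing both sides makes `B[i, j]` a fully standardized regression
weight. That choice (rather than raw-scale coefficients) is what makes
expected-influence sums meaningful across instruments whose response ranges
differ (0–4 ITQ items vs 0–3 PHQ/GAD items).

### Penalty selection and the two CV rules

λ is chosen per outcome by 10-fold cross-validation over a 50-point
log-spaced grid from the data-derived `λ_max` (the smallest penalty zeroing
every penalized coefficient, computed from the residual after fitting the
unpenalized block) down to `λ_max · 10^{-3}`. One seeded row permutation
assigns folds, shared across all 28 node regressions, so the whole network
is a deterministic function of (data, seed).

Two selection rules are exposed:

- `lambda_rule = "min"` (default): the λ minimizing mean held-out squared
  error. This is the prediction-optimal choice and the common default of
  glmnet-based workflows; it is what `estimate_network()` uses unless told
  otherwise, and edge *weights* reported under it are the least shrunken.
- `lambda_rule = "1se"`: the largest λ within one standard error of that
  minimum.

The two rules answer different questions, and the package deliberately uses
them for different purposes. Prediction-optimal CV is known to over-select:
on sparse truths it retains many small spurious coefficients, because the
held-out error is nearly flat between the true model and mildly overfitted
ones. The package's own recovery experiments show exactly this pattern
(`recovery_experiment()` with each rule), and the behaviour reproduces with
an independent implementation (glmnet) on identical data, so it is a
property of the rule, not of this solver. Consequently, every analysis in
the package whose target is the *support* of the network — which edges
exist, how many false edges a null network yields — is run under the `1se`
rule, the standard sparsity-oriented convention. The acceptance script and
the support-recovery tests follow this convention; weight-focused analyses
keep the `min` default.

### Numerical details

- Coordinate descent converges when the largest scale-weighted coefficient
  change in a sweep falls below `tol` (default `1e-8`); non-convergence at
  `maxit` sweeps (default `1e5`) is an error, never a silent result.
- The λ grid's top point is set to `λ_max` exactly (not `exp(log(λ_max))`,
  which can land one ulp below the zeroing bound and produce spurious
  ~1e-17 coefficients).
- Zero-variance columns are reported by node label and abort the fit.
- Exact zeros in `B` are genuine soft-threshold zeros, so "edge present"
  is `B[i, j] != 0` with no epsilon.
- Ties in the strongest-edge ranking are broken by (source, target) label
  order; centrality rankings warn when ties affect the reported head.

## Expected influence and its bootstrap tests

`Out-EI(i) = Σ_{j≠i} B[i, j]` and `In-EI(j) = Σ_{i≠j} B[i, j]` are *signed*
sums — a protective (negative) edge reduces a node's expected influence,
which is the point of the EI family as against absolute-strength
centralities. Autoregressive paths are excluded entirely (they live in a
separate vector and never enter the sums), as are covariate coefficients.

Centrality and edge uncertainty use the nonparametric bootstrap: resample
participants with replacement, re-estimate the entire network (including
fresh CV), recompute the statistic. Intervals are percentile intervals with
order-statistic quantiles (so a 2-resample bootstrap yields min/max bounds,
and no normality is assumed); a difference is "significant" when the 95%
interval of the difference excludes zero. The percentile convention is a
documented package choice — difference-test machinery is rarely spelled
out in applied reports, and no claim is made that it matches any particular
published analysis. Each replicate draws its resample under a seed derived
from (seed, replicate index), so results are independent of how replicates
are partitioned across workers or sessions.

## Case-dropping stability and the CS-coefficient

For each drop proportion `p` in a grid (default `0.05–0.75`), `n_boot`
subsamples of size `(1−p)·N` are drawn without replacement, the network and
the chosen centrality re-estimated, and the Pearson correlation with the
full-sample centrality recorded (Spearman by flag). The CS-coefficient is
the largest `p` such that at *every* proportion up to `p`, at least 95% of
subsample correlations are ≥ 0.7; the conventional reading labels values
above 0.5 "very stable" and above 0.25 "moderately stable" (strictly
above — a CS of exactly 0.25 is not yet moderate). The 0.7 threshold, 0.95
retention, and the grid are all exposed as parameters; none is sacred.
Subsamples smaller than 10 rows per node are skipped with a warning rather
than estimated unreliably.

## The construct-level path model

The path model is deliberately **manifest**: composites, not latent
variables. A latent-variable formulation needs defensible loadings and a
measurement model, which composite-level analysis does not require; the
scientific content exercised here — asymmetric cross-lagged prediction with
fit assessment — is fully present at the manifest level. Latent SEM,
measurement invariance, and multi-group comparisons are out of scope.

All variables are z-scored, so estimates are standardized coefficients.
With the full path set (all nine construct paths plus covariate paths, free
wave-1 covariances, free wave-2 residual covariances) the model is
saturated: equation-wise least squares is the maximum-likelihood solution,
the implied covariance equals the sample covariance identically, and
`χ² = 0`, `CFI = TLI = 1`, `RMSEA = 0`, `SRMR ≈ 0` hold to machine
precision — a property the tests pin exactly. Dropping paths (the `paths`
argument) yields a testable model: each equation is then estimated by least
squares on its included regressors (a limited-information estimator;
residual covariances are estimated from the residuals), and the fit
function `F_ML = log|Σ̂| − log|S| + tr(SΣ̂^{-1}) − p` is evaluated at those
estimates with `χ² = (n−1)·F_ML`. CFI/TLI use the diagonal (independence)
baseline; TLI is capped at 1; `RMSEA = sqrt(max(χ²−df, 0)/(df·(n−1)))`;
SRMR is the root mean square of the residual correlations including the
diagonal.

The Wald asymmetry test reports `b(reverse) − b(forward)` with the standard
error from the joint coefficient covariance
(`Cov(b_i, b_j) = Ψ_ij (X_i'X_i)^{-1} X_i'X_j (X_j'X_j)^{-1}`), so a
stronger forward path yields a negative difference. Covariates predict the
wave-2 constructs only.

Fit labels follow the conventional cutoffs: CFI/TLI above 0.95 good, above
0.90 acceptable; RMSEA/SRMR acceptable at 0.08 or lower (boundary
inclusive).

## The synthetic-data generator

The generator exists so that every estimator in the package can be tested
against known truth without access to clinical data. It emulates:

- two waves about six months apart, with a sparse directed truth network
  `B_true` (off-diagonal) and autoregressions `a_true` (diagonal, stored
  separately) constrained to spectral radius < 1;
- within-wave dependence via an equicorrelation of latent scores
  (default 0.3 — a moderate value typical of symptom inventories; no
  published magnitude exists to copy, so it is a free parameter chosen
  once);
- ordinal responses by fixed equiprobable normal-quantile thresholds
  (5 levels for ITQ-style items, 4 for PHQ/GAD-style), so wave-1 marginal
  level frequencies are calibrated to `1/(K)` each — a property the tests
  check within 2 percentage points at n = 10 000;
- wave-2 residual variances budgeted so wave-2 latents are approximately
  unit variance, keeping estimated standardized effects on the scale of
  the truth;
- covariate effects (default 0.1 per node on gender and age — present
  enough that covariate control is exercised, small enough not to dominate);
- survey screening: ~22% of respondents report no victimization, ~7% fail
  the control questions, and ~2% of wave-1 item responses are missing
  completely at random (wave 2 complete, as with an enforced online
  follow-up) — rates of the order seen in large school-based bullying
  surveys;
- `discretize = FALSE` emits the continuous latent scores, used by the
  construct-level recovery experiments to separate path-model behaviour
  from ordinal attenuation.

What the generator does **not** emulate — and therefore what passing
recovery tests do *not* establish about real data: non-normal latent
processes, informative missingness, item-level measurement error structure
(e.g. correlated residuals within subscales beyond the global
equicorrelation), floor effects stronger than the equiprobable thresholds,
attrition between waves, and clustering by school or classroom. Ordinal
discretization attenuates correlations, so estimated standardized edges sit
below their generating values (≈ 0.22 recovered from a 0.3 truth in the
README example); recovery metrics are therefore about support and ordering
more than about absolute magnitudes.

## Preprocessing choices

- **Screening before imputation**: participants are screened first ("at
  least once" on the victimization scale — any response strictly above the
  scale's "never" anchor, 0 for the 0–4 screen and 1 for the 1–6 screen —
  and correct control questions), and item means for imputation are
  computed on the screened sample only, so invalid responders cannot
  contaminate the means. The original order of these two steps in applied
  workflows is typically unstated; this package fixes one and documents it.
- **Item-mean (series-mean) imputation**, the SPSS default; the
  alternative, person-mean imputation, is not implemented. Imputed values
  are not rounded back to the ordinal grid: regressions treat responses as
  numeric anyway, and unrounded imputation preserves each item's observed
  mean exactly (to 1e-12, a tested invariant).
- Composite scores are plain sums, with subscale sums where declared; no
  diagnostic cutoffs or caseness algorithms.

## Reproducibility machinery

Every stochastic function takes an explicit seed and consumes randomness
inside `withr::with_seed`, leaving global RNG state untouched. The pipeline
derives per-stage seeds from one global seed by stage-name hashing, so
stages re-run in isolation reproduce the composed run; bootstrap replicates
derive per-replicate seeds, so results do not depend on scheduling. Data
artifacts contain no timestamps (the log does), making pipeline outputs
byte-identical across reruns — a tested property.

## Problem sizes used in the tests

The test suite exercises estimators at sizes chosen to make the properties
sharp but the suite quick: oracle comparisons at n = 50, p = 4;
recovery and null calibration at n = 2000 (10 and 28 nodes); path-model
recovery at n = 3000 with 20-replicate null calibrations; bootstrap
behaviour on 4–6-node networks with 50–500 resamples; the demo pipeline at
n = 2000 with 200 edge-bootstrap resamples and a 4-point case-drop grid of
25 subsamples. The acceptance script uses the same sizes. Full-scale
applied analyses (28 nodes, 1000 resamples, a 15-point case-drop grid)
use the same code paths with larger `n_boot` and `proportions`.

## Known limitations

- Two waves only; no three-wave designs, no random-intercept decompositions
  separating within- from between-person variance.
- Ordinal items treated as numeric throughout; no polychoric or ordinal
  regression variants.
- MCAR mean imputation only; no FIML or multiple imputation.
- The restricted path model's χ² is evaluated at limited-information
  estimates, slightly conservative relative to full-information ML.
- No within-wave (contemporaneous) network, no moderated or mixed graphical
  models, and no plotting-layout algorithm — exports (CSV, GraphML) feed
  dedicated network viewers.
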