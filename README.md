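# clpnet

Two-level analysis of longitudinal symptom comorbidity in two-wave panel
data, built around the cross-lagged panel network (CLPN) and the classic
cross-lagged panel path model. The motivating application is the comorbidity
of complex post-traumatic stress disorder (CPTSD, measured by the 12-item
ITQ), depression (PHQ-9), and anxiety (GAD-7) in cohorts screened for
bullying victimization, but every component works for any two-wave ordinal
panel with a known node set.

The package is written for applied psychometric and epidemiological
researchers: tibbles in, tibbles out, pipe-friendly verbs, `tidy()` /
`glance()` methods for fitted objects, and `autoplot()` methods for every
result type.

## What it computes

**Symptom level — the CLPN.** For each of the `p` wave-2 symptoms
`y_j^(2)`, a LASSO regression on all `p` wave-1 symptoms plus covariates:

    y_j^(2) = b0 + sum_i B[i, j] * y_i^(1) + c_g * gender + c_a * age + e

minimizing `(1/2n)·||y − Xβ||² + λ·Σ|β_i|` with the covariates unpenalized
and λ chosen per outcome by 10-fold cross-validation (one seeded fold
permutation shared across outcomes). Items are z-scored per wave, so
`B[i, j]` is the standardized cross-lagged effect of symptom *i* on symptom
*j* six months later; each node's self-prediction is kept separately as its
autoregressive path. The coordinate-descent solver lives in `src/` and
operates on the Gram matrix, so node-wise estimation is fast enough to sit
inside bootstrap loops.

From the estimated network the package derives:

- **Expected influence**: `Out-EI(i) = Σ_{j≠i} B[i, j]` (how much a symptom
  predicts others) and `In-EI(j) = Σ_{i≠j} B[i, j]` (how much it is
  predicted), with autoregressive paths set to 0 and signed — not
  absolute — sums.
- **Accuracy**: percentile bootstrap confidence intervals for every edge
  (resampling participants, re-estimating the network), plus an
  interval-overlap matrix.
- **Stability**: the case-dropping bootstrap and the CS-coefficient — the
  largest fraction of participants that can be dropped while subsample
  centralities correlate ≥ 0.7 with the full-sample centralities in ≥ 95%
  of subsamples. Values above 0.5 indicate a very stable network, above
  0.25 moderate stability.

**Construct level — the cross-lagged path model.** Composite ITQ / PHQ-9 /
GAD-7 scores at both waves enter a manifest path model: all nine
wave-1 → wave-2 construct paths (three autoregressive, six cross-lagged)
plus gender/age covariate paths, free wave-1 covariances, and free wave-2
residual covariances. Estimates are standardized coefficients with
maximum-likelihood fit indices (χ², CFI, TLI, RMSEA, SRMR against the Hu &
Bentler cutoffs) and Wald tests for path asymmetry (is CPTSD → anxiety
stronger than anxiety → CPTSD?).

**Synthetic data.** Because item-level clinical panel data are rarely
shareable, the package ships a seeded generator: latent wave-1 scores from
a correlated Gaussian, wave-2 scores through a known ground-truth network,
equiprobable-quantile discretization to each instrument's ordinal range,
MCAR wave-1 missingness, and victimization-screening fields. Every estimator
can therefore be exercised in parameter-recovery experiments
(`recovery_experiment()`) with known truth.

## Worked example

```r
library(clpnet)

truth <- make_truth(paste0("n", sprintf("%02d", 1:10)),
                    edge_density = 8 / 90, effect_size = 0.3,
                    autoregression = 0.3, seed = 7)
panel <- simulate_panel(truth, generator_config(n = 2000, seed = 7))

screened <- screen_participants(panel)
screening_summary(screened)
#> <screening> 2000 assessed; 1578 victimized at least once; 104 excluded (control questions); 1474 retained

clean <- impute_missing(screened)
net <- estimate_network(clean, estimator_settings(seed = 7, lambda_rule = "1se"))
net
#> <clpn> 10 nodes, 9 cross-lagged edges (non-zero), n = 1474, 10-fold CV (1se rule)

threshold_for_display(net, threshold = 0.05) |> head(5)
#> # A tibble: 5 × 3
#>   from  to    weight
#>   <chr> <chr>  <dbl>
#> 1 n04   n05    0.237
#> 2 n04   n08    0.228
#> 3 n02   n10    0.224
#> 4 n07   n05    0.219
#> 5 n03   n08    0.215

rank_report(expected_influence(net), k = 3)
#> # A tibble: 6 × 4
#>   index   rank node  value
#>   <chr>  <int> <chr> <dbl>
#> 1 out_ei     1 n04   0.465
#> 2 out_ei     2 n02   0.224
#> 3 out_ei     3 n03   0.215
#> 4 in_ei      1 n05   0.456
#> 5 in_ei      2 n08   0.443
#> 6 in_ei      3 n10   0.232

cd <- case_drop_bootstrap(clean, estimator_settings(seed = 7, lambda_rule = "1se"),
                          index = "in_ei", proportions = c(0.1, 0.3, 0.5, 0.75),
                          n_boot = 25, seed = 7)
cs <- cs_coefficient(cd)
cat(sprintf("CS(in_ei) = %.2f (%s)\n", cs, cs_label(cs)))
#> CS(in_ei) = 0.75 (very stable)
```

Reading the output: of the 2000 simulated respondents, 1474 pass the
victimization and control-question screens. The 1se-rule network keeps 9
edges; its five strongest standardized cross-lagged effects (all ≈ 0.22 —
the generating value 0.3 attenuated by ordinal discretization and
shrinkage) correctly identify generated edges. Node `n04` has the highest
Out-EI (it carries several outgoing true edges) and the In-EI ranking is
stable under case dropping up to the 75% maximum of the grid.

The same analysis runs from a single YAML config, in R via
`run_pipeline("inst/extdata/demo_config.yaml")` or from a shell via the
thin wrapper `inst/scripts/clpnet.R` (subcommands `simulate`, `screen`,
`score`, `clpn`, `centrality`, `stability`, `panel`, `all`).

For 28-symptom panels carrying the full ITQ/PHQ-9/GAD-7 node set, the
pipeline additionally scores the construct composites and fits the
cross-lagged path model:

```r
fit <- fit_path_model(construct_scores(clean))
glance(fit)                                    # chisq, CFI, TLI, RMSEA, SRMR
wald_path_difference(fit, "cptsd->anx", "anx->cptsd")
evaluate_fit(fit)                              # cutoff labels
```

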