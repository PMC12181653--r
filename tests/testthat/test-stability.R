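test_that("a two-resample bootstrap stores min/max bounds per edge", {
  tr <- demo_truth(p = 4, n_edges = 3, seed = 1)
  d <- impute_missing(screen_participants(
    simulate_panel(tr, clean_config(250, 2))))
  eb <- bootstrap_edges(d, estimator_settings(seed = 1), n_boot = 2, seed = 5)
  expect_equal(nrow(eb$replicates), 2)
  expect_equal(eb$edges$lower,
               pmin(eb$replicates[1, ], eb$replicates[2, ]))
  expect_equal(eb$edges$upper,
               pmax(eb$replicates[1, ], eb$replicates[2, ]))
  expect_true(all(eb$edges$lower <= eb$edges$boot_mean + 1e-12))
  expect_true(all(eb$edges$boot_mean <= eb$edges$upper + 1e-12))
  expect_error(bootstrap_edges(d, n_boot = 1), ">= 2")
})

test_that("edge bootstraps are seed-deterministic", {
  tr <- demo_truth(p = 4, n_edges = 2, seed = 2)
  d <- impute_missing(screen_participants(
    simulate_panel(tr, clean_config(250, 3))))
  s <- estimator_settings(seed = 2)
  e1 <- bootstrap_edges(d, s, n_boot = 5, seed = 7)
  e2 <- bootstrap_edges(d, s, n_boot = 5, seed = 7)
  expect_identical(e1$replicates, e2$replicates)
  expect_identical(e1$edges, e2$edges)
})

test_that("a strong edge's interval excludes zero; null intervals cover it", {
  labels <- paste0("n", 1:6)
  tr <- make_truth(labels, 0, 0.5, 0.2, seed = 1)
  tr$B_true["n2", "n5"] <- 0.5
  d <- impute_missing(screen_participants(
    simulate_panel(tr, clean_config(1200, 4))))
  eb <- bootstrap_edges(d, estimator_settings(seed = 3), n_boot = 60,
                        seed = 8)
  strong <- eb$edges[eb$edges$from == "n2" & eb$edges$to == "n5", ]
  expect_gt(strong$lower, 0)

  ov <- edge_ci_overlap(eb)
  expect_true(isSymmetric(ov))
  expect_true(all(diag(ov)))

  tr0 <- make_truth(labels, 0, 0.3, 0.2, seed = 2)
  d0 <- impute_missing(screen_participants(
    simulate_panel(tr0, clean_config(600, 5))))
  eb0 <- bootstrap_edges(d0, estimator_settings(seed = 4), n_boot = 50,
                         seed = 9)
  covers0 <- mean(eb0$edges$lower <= 0 & eb0$edges$upper >= 0)
  expect_gte(covers0, 0.9)
})

test_that("case-dropping curves are deterministic and validate their grid", {
  tr <- demo_truth(p = 5, n_edges = 4, seed = 3)
  d <- impute_missing(screen_participants(
    simulate_panel(tr, clean_config(700, 6))))
  s <- estimator_settings(seed = 5)
  cd1 <- case_drop_bootstrap(d, s, "out_ei", proportions = c(0.1, 0.3),
                             n_boot = 6, seed = 11)
  cd2 <- case_drop_bootstrap(d, s, "out_ei", proportions = c(0.1, 0.3),
                             n_boot = 6, seed = 11)
  expect_identical(cd1$correlations, cd2$correlations)
  expect_error(case_drop_bootstrap(d, s, proportions = numeric(0)), "empty")
  expect_error(case_drop_bootstrap(d, s, proportions = 0.9), "0.75")

  # dropping almost nothing from a strong structure leaves centralities put
  big <- impute_missing(screen_participants(
    simulate_panel(demo_truth(p = 6, n_edges = 6, effect = 0.4, seed = 4),
                   clean_config(2000, 7))))
  cd <- case_drop_bootstrap(big, estimator_settings(seed = 6,
                                                    lambda_rule = "1se"),
                            "out_ei", proportions = 0.05, n_boot = 12,
                            seed = 12)
  expect_gte(median(cd$correlations$correlation), 0.99)
})

test_that("undersized subsamples are skipped with a warning", {
  tr <- demo_truth(p = 5, n_edges = 3, seed = 5)
  d <- impute_missing(screen_participants(
    simulate_panel(tr, clean_config(90, 8))))
  expect_warning(
    cd <- case_drop_bootstrap(d, estimator_settings(seed = 1), "in_ei",
                              proportions = c(0.1, 0.75), n_boot = 3,
                              seed = 1),
    "below 10 x node count")
  expect_equal(unique(cd$correlations$proportion), 0.1)
})

test_that("the CS-coefficient follows its retention definition exactly", {
  grid <- c(0.05, 0.1, 0.25, 0.28, 0.5, 0.75)
  build <- function(retained_fraction_by_prop, n_rep = 100) {
    dplyr::bind_rows(lapply(seq_along(grid), function(i) {
      n_ok <- round(retained_fraction_by_prop[i] * n_rep)
      tibble::tibble(proportion = grid[i], replicate = seq_len(n_rep),
                     correlation = c(rep(1, n_ok), rep(0, n_rep - n_ok)))
    }))
  }
  # perfect stability across the whole conventional grid
  expect_equal(cs_coefficient(build(rep(1, 6))), 0.75)
  # no stability at all
  expect_equal(cs_coefficient(build(rep(0, 6))), 0)
  # retention holds exactly through 0.25 and fails at 0.28
  expect_equal(cs_coefficient(build(c(1, 1, 0.95, 0.90, 0.5, 0.2))), 0.25)
  # a later recovery cannot resurrect the coefficient
  expect_equal(cs_coefficient(build(c(1, 0.5, 1, 1, 1, 1))), 0.05)

  expect_error(cs_coefficient(tibble::tibble(x = 1)), "malformed")
  expect_error(cs_coefficient(tibble::tibble(proportion = numeric(),
                                             correlation = numeric())),
               "no recorded")
})

test_that("interpretive labels follow the 0.25/0.5 conventions", {
  expect_equal(cs_label(c(0.75, 0.51, 0.5, 0.283, 0.25, 0.1)),
               c("very stable", "very stable", "moderately stable",
                 "moderately stable", "unstable", "unstable"))
})

test_that("raising the retention bar never raises the CS-coefficient", {
  set.seed(20)
  grid <- seq(0.05, 0.75, by = 0.1)
  cors <- dplyr::bind_rows(lapply(grid, function(p) {
    tibble::tibble(proportion = p, replicate = 1:60,
                   correlation = pmin(1, rnorm(60, mean = 1 - p, sd = 0.15)))
  }))
  for (thr in c(0.5, 0.7, 0.9)) {
    cs_lo <- cs_coefficient(cors, cor_threshold = thr, retain_prob = 0.8)
    cs_hi <- cs_coefficient(cors, cor_threshold = thr, retain_prob = 0.95)
    expect_gte(cs_lo, cs_hi)
  }
  for (rp in c(0.8, 0.95)) {
    cs_lo <- cs_coefficient(cors, cor_threshold = 0.5, retain_prob = rp)
    cs_hi <- cs_coefficient(cors, cor_threshold = 0.9, retain_prob = rp)
    expect_gte(cs_lo, cs_hi)
  }
})

# pinned seed pair: the bootstrap mean of the largest edge drifts toward
# the point estimate as the number of resamples grows (regression property;
# the residual gap is the bootstrap bias, so this is a fixed-seed check,
# not a theorem for every seed)
test_that("bootstrap means approach the point estimate as resamples grow", {
  tr <- demo_truth(p = 4, n_edges = 3, effect = 0.4, seed = 6)
  d <- impute_missing(screen_participants(
    simulate_panel(tr, clean_config(400, 9))))
  s <- estimator_settings(seed = 7)
  e_small <- bootstrap_edges(d, s, n_boot = 100, seed = 21)
  e_large <- bootstrap_edges(d, s, n_boot = 500, seed = 21)
  i_big <- which.max(abs(e_small$edges$estimate))
  point <- e_small$edges$estimate[i_big]
  expect_lte(abs(e_large$edges$boot_mean[i_big] - point),
             abs(e_small$edges$boot_mean[i_big] - point))
})
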