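test_that("standardization is exact, idempotent, and names bad columns", {
  d <- tibble::tibble(id = 1:3, t1_a = c(0, 2, 4), t1_b = c(1, 0, 2),
                      t2_a = c(1, 2, 3), t2_b = c(0, 0, 1))
  z <- standardize(d)
  expect_equal(z$t1_a, c(-1, 0, 1) * 2 / sd(c(0, 2, 4)) / 1, tolerance = 1e-12)
  expect_equal(z$t1_a, (c(0, 2, 4) - 2) / 2)  # sd with denominator n-1 is 2
  expect_equal(mean(z$t2_b), 0)
  expect_equal(sd(z$t2_b), 1)

  # idempotent on the values (the recorded means/SDs become 0/1)
  z2 <- standardize(z)
  expect_equal(as.data.frame(z2), as.data.frame(z), tolerance = 1e-12,
               ignore_attr = "standardization")

  params <- attr(z, "standardization")
  restored <- z$t1_a * params$sd[params$column == "t1_a"] +
    params$mean[params$column == "t1_a"]
  expect_equal(restored, d$t1_a)

  d$t1_a <- 5
  expect_error(standardize(d), "t1_a")
  expect_error(standardize(tibble::tibble(x = 1)), "no item columns")
})

test_that("the estimated network stores autoregressions off the zero diagonal", {
  tr <- demo_truth(p = 6, n_edges = 4, seed = 2)
  d <- impute_missing(screen_participants(
    simulate_panel(tr, generator_config(500, seed = 3))))
  net <- estimate_network(d, estimator_settings(seed = 1))
  expect_s3_class(net, "clpn")
  expect_true(all(diag(net$B) == 0))
  expect_equal(dim(net$B), c(6, 6))
  expect_equal(length(net$a), 6)
  expect_equal(length(net$lambda), 6)
  expect_equal(dim(net$covariate_coefs), c(6, 2))
  # autoregression of 0.3 should be picked up as positive self-prediction
  expect_gt(mean(net$a), 0)
})

test_that("a single strong cross-lagged effect is the largest estimated edge", {
  labels <- paste0("n", 1:6)
  tr <- make_truth(labels, 0, 0.5, 0.2, seed = 1)
  tr$B_true["n2", "n5"] <- 0.5
  d <- impute_missing(screen_participants(
    simulate_panel(tr, clean_config(2000, 4))))
  net <- estimate_network(d, estimator_settings(seed = 2))
  expect_equal(which(abs(net$B) == max(abs(net$B)), arr.ind = TRUE)[1, ],
               c(row = 2L, col = 5L))
  top <- threshold_for_display(net, 0.05)
  expect_equal(top$from[1], "n2")
  expect_equal(top$to[1], "n5")
})

test_that("node-set mismatches and unimputed inputs are rejected", {
  tr <- demo_truth(p = 5, n_edges = 2, seed = 3)
  d <- simulate_panel(tr, clean_config(100, 5))
  expect_error(estimate_network(d[setdiff(names(d), "t2_n05")]),
               "node-set mismatch")
  d_na <- simulate_panel(tr, generator_config(100, seed = 5,
                                              missing_rate = 0.1))
  expect_error(estimate_network(d_na), "impute")
  expect_error(estimate_network(d, covariates = "income"), "income")
})

test_that("flipping one wave-1 predictor flips exactly its outgoing row", {
  tr <- demo_truth(p = 5, n_edges = 4, effect = 0.35, seed = 6)
  d <- impute_missing(screen_participants(
    simulate_panel(tr, clean_config(800, 7))))
  s <- estimator_settings(seed = 3)
  net <- estimate_network(d, s)
  flipped <- d
  flipped$t1_n02 <- -flipped$t1_n02
  net_f <- estimate_network(flipped, s)
  expect_equal(net_f$B[2, ], -net$B[2, ], tolerance = 1e-9)
  expect_equal(net_f$B[-2, ], net$B[-2, ], tolerance = 1e-9)
  expect_equal(net_f$a[["n02"]], -net$a[["n02"]], tolerance = 1e-9)
})

test_that("moderate covariate effects leave the cross-lagged support unchanged", {
  labels <- paste0("n", 1:6)
  base <- make_truth(labels, 6 / 30, 0.35, 0.3, seed = 9,
                     covariate_effects = 0)
  with_cov <- base
  with_cov$covariate_effects <- matrix(0.2, 6, 2,
                                       dimnames = list(labels,
                                                       c("gender", "age")))
  s <- estimator_settings(seed = 4, lambda_rule = "1se")
  net0 <- estimate_network(impute_missing(screen_participants(
    simulate_panel(base, clean_config(2000, 10)))), s)
  net1 <- estimate_network(impute_missing(screen_participants(
    simulate_panel(with_cov, clean_config(2000, 10)))), s)
  expect_equal(net0$B != 0, net1$B != 0)
  expect_gt(mean(abs(net1$covariate_coefs)), mean(abs(net0$covariate_coefs)))
})

test_that("display thresholding filters and orders but never mutates", {
  B <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  B["a", "b"] <- 0.30
  B["b", "c"] <- -0.06
  B["c", "a"] <- 0.04
  edges <- threshold_for_display(B, 0.05)
  expect_equal(nrow(edges), 2)
  expect_equal(edges$weight, c(0.30, -0.06))
  expect_equal(nrow(threshold_for_display(B, 0)), 3)
  expect_equal(nrow(threshold_for_display(B, Inf)), 0)
  expect_error(threshold_for_display(B, -0.1), "non-negative")
})

test_that("network exports round-trip edges and load as valid GraphML", {
  tr <- demo_truth(p = 5, n_edges = 4, seed = 11)
  d <- impute_missing(screen_participants(
    simulate_panel(tr, clean_config(500, 12))))
  net <- estimate_network(d, estimator_settings(seed = 5))

  csv <- withr::local_tempfile(fileext = ".csv")
  write_network_csv(net, csv)
  tab <- readr::read_csv(csv, show_col_types = FALSE)
  expect_setequal(unique(tab$kind),
                  c("cross_lagged", "autoregressive", "covariate"))
  expect_equal(sum(tab$kind == "autoregressive"), 5)
  expect_equal(sum(tab$kind == "covariate"), 10)
  cl <- tab[tab$kind == "cross_lagged", ]
  expect_equal(nrow(cl), sum(net$B != 0))

  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(net, gml, threshold = 0)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), 5)
  expect_equal(igraph::ecount(g), sum(net$B != 0))

  expect_s3_class(tidy(net), "tbl_df")
  expect_equal(glance(net)$n_edges, sum(net$B != 0))
})
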