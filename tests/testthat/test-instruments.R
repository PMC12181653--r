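test_that("instrument specs validate their structure", {
  expect_error(instrument_spec("x", c("a", "a"), 0, 3), "duplicate")
  expect_error(instrument_spec("x", c("a", "b"), 3, 3), "strictly less")
  expect_error(instrument_spec("x", c("a", "b"), 0, 3,
                               subscales = list(s1 = "a", s2 = "a")),
               "at most one subscale")
  expect_error(instrument_spec("x", c("a", "b"), 0, 3,
                               subscales = list(s1 = "c")),
               "not in the item set")
})

test_that("built-in instruments match the published scale structures", {
  ins <- default_instruments()
  expect_equal(length(ins$itq$items), 12)
  expect_equal(c(ins$itq$response_min, ins$itq$response_max), c(0, 4))
  expect_equal(length(ins$itq$subscales), 6)
  expect_equal(length(ins$phq9$items), 9)
  expect_equal(c(ins$phq9$response_min, ins$phq9$response_max), c(0, 3))
  expect_equal(length(ins$gad7$items), 7)
  expect_equal(length(ins$bpbq_victim$items), 10)
  expect_equal(length(ins$delaware_victim$items), 17)
  expect_equal(c(ins$delaware_victim$response_min,
                 ins$delaware_victim$response_max), c(1, 6))
  expect_equal(length(symptom_nodes()), 28)
})

test_that("screening keeps exactly the victimized, valid responders", {
  base <- tibble::tibble(
    id = 1:4, control_ok = c(TRUE, TRUE, FALSE, TRUE),
    screen_v1 = c(0, 1, 2, 0), screen_v2 = c(0, 0, 0, 0)
  )
  kept <- screen_participants(base)
  # all-minimum responses drop a participant; a single "once" keeps them
  expect_equal(kept$id, 2L)
  s <- screening_summary(kept)
  expect_equal(s$n_input, 4)
  expect_equal(s$n_victimized, 2)
  expect_equal(s$n_excluded_invalid, 1)
  expect_equal(s$n_final, s$n_victimized - s$n_excluded_invalid)
  expect_equal(s$n_final, length(s$kept_ids))

  # Delaware-style screen: "never" anchor is 1
  dw <- tibble::tibble(id = 1:2, control_ok = TRUE,
                       screen_v1 = c(1, 2))
  expect_equal(screen_participants(dw, never_value = 1)$id, 2L)
  expect_error(screen_participants(tibble::tibble(id = 1)), "screening")
})

test_that("screening counts match a brute-force re-filter of the CSV", {
  tr <- demo_truth(p = 5, n_edges = 3, seed = 2)
  cfg <- generator_config(1000, seed = 3, screen_negative_rate = 0.3,
                          control_fail_rate = 0.1)
  d <- simulate_panel(tr, cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_panel_csv(d, path)

  raw <- utils::read.csv(path)
  brute <- sum(rowSums(raw[paste0("screen_v", 1:10)] > 0) > 0 &
                 raw$control_ok == "TRUE")
  expect_equal(screening_summary(screen_participants(d))$n_final, brute)
})

test_that("mean imputation fills with observed item means and nothing else", {
  d <- tibble::tibble(id = 1:3, t1_a = c(1, 3, NA), t1_b = c(2, 2, 2),
                      t2_a = c(0, 1, 2), t2_b = c(NA, NA, 5))
  out <- impute_missing(d)
  expect_equal(out$t1_a, c(1, 3, 2))
  expect_equal(out$t2_b, c(5, 5, 5))
  expect_equal(out$t1_b, d$t1_b)
  expect_equal(out$t2_a, d$t2_a)

  # identity on complete data
  expect_identical(impute_missing(out), out)

  # an entirely missing item column is an error
  d$t1_a <- NA_real_
  expect_error(impute_missing(d), "entirely missing")
})

test_that("imputation preserves every item's observed mean exactly", {
  tr <- demo_truth(p = 8, n_edges = 4, seed = 5)
  d <- simulate_panel(tr, generator_config(500, seed = 6,
                                           missing_rate = 0.05))
  out <- impute_missing(d)
  for (col in grep("^t1_", names(d), value = TRUE)) {
    expect_equal(mean(out[[col]]), mean(d[[col]], na.rm = TRUE),
                 tolerance = 1e-12)
  }
})

test_that("composite scores sum items and subscales", {
  ins <- default_instruments()
  n <- 3
  d <- tibble::tibble(id = 1:n)
  for (it in ins$phq9$items) d[[paste0("t1_", it)]] <- rep(3, n)
  for (it in ins$phq9$items) d[[paste0("t2_", it)]] <- rep(0, n)
  s <- composite_scores(d, ins$phq9)
  expect_equal(s$phq9_t1, rep(27, n))  # 9 items x 3
  expect_equal(s$phq9_t2, rep(0, n))

  d2 <- tibble::tibble(id = 1)
  resp <- c(3, 2, 3, 1, 0, 2, 2)
  for (i in seq_along(ins$gad7$items)) {
    d2[[paste0("t1_", ins$gad7$items[i])]] <- resp[i]
    d2[[paste0("t2_", ins$gad7$items[i])]] <- 0
  }
  expect_equal(composite_scores(d2, ins$gad7)$gad7_t1, 13)

  d3 <- tibble::tibble(id = 1:2)
  for (it in ins$itq$items) {
    d3[[paste0("t1_", it)]] <- c(0, 4)
    d3[[paste0("t2_", it)]] <- c(0, 4)
  }
  s3 <- composite_scores(d3, ins$itq)
  expect_equal(s3$itq_t1, c(0, 48))
  expect_equal(s3$itq_re_experiencing_t1, c(0, 8))

  expect_error(composite_scores(d3, "itq"), "instrument_spec")
  d3$t1_RE1 <- 99
  expect_error(composite_scores(d3, ins$itq), "out-of-range")
})

test_that("scoring is permutation-invariant and commutes with screening subsets", {
  tr <- make_truth(symptom_nodes(), edge_density = 10 / (28 * 27),
                   effect_size = 0.3, autoregression = 0.3, seed = 8)
  d <- simulate_panel(tr, generator_config(400, seed = 9,
                                           missing_rate = 0.03))
  chain <- function(x) {
    construct_scores(impute_missing(screen_participants(x)))
  }
  full <- chain(d)

  # restricting the input to the kept participants changes nothing
  kept <- screening_summary(screen_participants(d))$kept_ids
  expect_equal(chain(d[d$id %in% kept, ]), full)

  # permuting participants permutes the scores
  perm <- withr::with_seed(1, sample(nrow(d)))
  scrambled <- chain(d[perm, ])
  expect_equal(dplyr::arrange(scrambled, id), dplyr::arrange(full, id))
})

test_that("Cronbach's alpha matches its defining identities", {
  # perfectly parallel items
  expect_equal(cronbach_alpha(cbind(c(1, 2, 3), c(1, 2, 3))), 1)
  expect_equal(cronbach_alpha(cbind(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5))), 1)

  # independent items: alpha near 0
  x <- withr::with_seed(11, matrix(rnorm(20000), 10000, 2))
  expect_lt(abs(cronbach_alpha(x)), 0.05)

  expect_error(cronbach_alpha(cbind(1:3)), "2 items")
  expect_error(cronbach_alpha(cbind(c(1, 1), c(2, 2))), "variance")
})
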