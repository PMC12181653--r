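# Independent oracles and small fixture builders used across the suite.

# Brute-force solve of the lasso objective by smooth box-constrained
# optimization of the split formulation b = u - v, u, v >= 0 (the objective
# is then a smooth quadratic plus a linear term, which L-BFGS-B minimizes
# to high precision). Independent of the coordinate-descent code path.
lasso_oracle <- function(y, X, lambda, pf = rep(1, ncol(X))) {
  p <- ncol(X)
  n <- length(y)
  fn <- function(par) {
    b <- par[2:(p + 1)] - par[(p + 2):(2 * p + 1)]
    0.5 * mean((y - par[1] - X %*% b)^2) +
      lambda * sum(pf * (par[2:(p + 1)] + par[(p + 2):(2 * p + 1)]))
  }
  gr <- function(par) {
    b <- par[2:(p + 1)] - par[(p + 2):(2 * p + 1)]
    r <- as.numeric(y - par[1] - X %*% b)
    gb <- -as.numeric(crossprod(X, r)) / n
    c(-mean(r), gb + lambda * pf, -gb + lambda * pf)
  }
  opt <- stats::optim(rep(0, 2 * p + 1), fn, gr, method = "L-BFGS-B",
                      lower = c(-Inf, rep(0, 2 * p)),
                      control = list(maxit = 5000, factr = 10))
  c(opt$par[1], opt$par[2:(p + 1)] - opt$par[(p + 2):(2 * p + 1)])
}

# Expected influence by explicit double loop (independent of colSums/rowSums
# vectorization in the package).
ei_oracle <- function(B) {
  p <- nrow(B)
  in_ei <- numeric(p)
  out_ei <- numeric(p)
  for (j in seq_len(p)) {
    for (i in seq_len(p)) {
      if (i != j) {
        in_ei[j] <- in_ei[j] + B[i, j]
        out_ei[i] <- out_ei[i] + B[i, j]
      }
    }
  }
  list(in_ei = in_ei, out_ei = out_ei)
}

# Population-standardized columns (denominator n), under which the
# univariate lasso has the exact soft-threshold closed form.
pop_standardize <- function(X) {
  Xc <- sweep(as.matrix(X), 2, colMeans(X))
  sweep(Xc, 2, sqrt(colMeans(Xc^2)), `/`)
}

# Clean generator settings: no screening attrition or missingness, for
# tests that target the estimator rather than the preprocessing.
clean_config <- function(n, seed, ...) {
  generator_config(n, seed = seed, missing_rate = 0,
                   screen_negative_rate = 0, control_fail_rate = 0, ...)
}

# Small sparse truth reused by several estimator tests.
demo_truth <- function(p = 10, n_edges = 8, effect = 0.3, auto = 0.3,
                       seed = 7) {
  make_truth(paste0("n", sprintf("%02d", seq_len(p))),
             edge_density = n_edges / (p * (p - 1)),
             effect_size = effect, autoregression = auto, seed = seed)
}

# Construct-level (continuous) score generator for the path model tests:
# three constructs with chosen forward/reverse coupling.
construct_sim <- function(b_fwd, b_rev, n, seed, auto = 0.4) {
  tr <- make_truth(c("cptsd", "dep", "anx"), 0, 0.3, auto, seed = 1)
  tr$B_true["cptsd", "anx"] <- b_fwd
  tr$B_true["anx", "cptsd"] <- b_rev
  d <- simulate_panel(tr, clean_config(n, seed, discretize = FALSE))
  names(d) <- sub("^t([12])_([a-z]+)$", "\\2_t\\1", names(d))
  d
}
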