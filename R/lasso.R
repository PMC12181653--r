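#' Estimator settings for the cross-lagged panel network
#'
#' @param n_folds Number of cross-validation folds (default 10).
#' @param lambda_rule `"min"` selects the penalty minimizing mean held-out
#'   squared error; `"1se"` the largest penalty within one standard error of
#'   that minimum.
#' @param n_lambda Size of the log-spaced penalty grid.
#' @param lambda_min_ratio Smallest grid penalty as a fraction of the
#'   data-derived `lambda_max`.
#' @param tol Coordinate-descent convergence tolerance (maximum
#'   scaled coefficient change per sweep).
#' @param maxit Maximum coordinate-descent sweeps per penalty value.
#' @param seed Seed for the fold-assignment permutation; one permutation is
#'   shared across all node-wise regressions so the estimated network is a
#'   deterministic function of (data, seed).
#' @return An object of class `estimator_settings`.
#' @export
estimator_settings <- function(n_folds = 10, lambda_rule = c("min", "1se"),
                               n_lambda = 50, lambda_min_ratio = 1e-3,
                               tol = 1e-8, maxit = 100000L, seed = 1) {
  lambda_rule <- match.arg(lambda_rule)
  if (!is_scalar_number(n_folds) || n_folds < 2) {
    abort_clpnet("`n_folds` must be >= 2")
  }
  if (!is_scalar_number(tol) || tol <= 0) abort_clpnet("`tol` must be > 0")
  structure(
    list(n_folds = as.integer(n_folds), lambda_rule = lambda_rule,
         n_lambda = as.integer(n_lambda),
         lambda_min_ratio = lambda_min_ratio,
         tol = tol, maxit = as.integer(maxit), seed = as.integer(seed)),
    class = "estimator_settings"
  )
}

# Covariance-form coordinate descent over a decreasing lambda grid.
# Returns the (p x nlambda) slope matrix plus intercepts.
cd_lasso <- function(y, X, lambda, penalty_factor, tol, maxit) {
  n <- length(y)
  xm <- colMeans(X)
  ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  yc <- y - ym
  G <- crossprod(Xc) / n
  cvec <- drop(crossprod(Xc, yc)) / n
  ord <- order(lambda, decreasing = TRUE)
  beta <- cd_lasso_path_cpp(G, cvec, lambda[ord], penalty_factor, tol, maxit)
  beta <- beta[, order(ord), drop = FALSE]
  intercept <- ym - drop(xm %*% beta)
  list(beta = beta, intercept = intercept)
}

#' LASSO solution path by cyclic coordinate descent
#'
#' Minimizes `(1/2n) * ||y - b0 - X b||^2 + lambda * sum_{penalized j} |b_j|`
#' over a given penalty (or penalty vector). The intercept is always
#' unpenalized; further columns can be exempted from the penalty via
#' `unpenalized` (used for the gender/age covariates in the network).
#' Columns are used as supplied — standardize beforehand if coefficients
#' should be comparable across predictors.
#'
#' @param y Numeric outcome vector.
#' @param X Numeric predictor matrix with column names.
#' @param lambda A penalty value or vector of values (any order).
#' @param unpenalized Column names or indices of `X` carrying no penalty.
#' @param tol,maxit Convergence controls, see [estimator_settings()].
#' @return For a single `lambda`, a named coefficient vector headed by
#'   `(Intercept)`; for several, a coefficient matrix with one column per
#'   penalty value (in the order supplied).
#' @export
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("x", 1:4)))
#' y <- X %*% c(1, 0, 0.5, 0) + rnorm(50, sd = 0.1)
#' round(lasso_path(y, X, lambda = 0.1), 3)
lasso_path <- function(y, X, lambda, unpenalized = NULL,
                       tol = 1e-8, maxit = 100000L) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  if (!all(is.finite(y)) || !all(is.finite(X))) {
    abort_clpnet("non-finite values in `y` or `X`")
  }
  if (any(lambda < 0)) abort_clpnet("`lambda` must be >= 0")
  pf <- rep(1, ncol(X))
  if (!is.null(unpenalized)) {
    idx <- if (is.character(unpenalized)) match(unpenalized, colnames(X))
           else as.integer(unpenalized)
    if (anyNA(idx)) abort_clpnet("`unpenalized` names not found in `X`")
    pf[idx] <- 0
  }
  fit <- cd_lasso(y, X, lambda, pf, tol, maxit)
  coefs <- rbind(`(Intercept)` = fit$intercept, fit$beta)
  rownames(coefs) <- c("(Intercept)", colnames(X))
  if (length(lambda) == 1L) coefs[, 1] else coefs
}

# lambda_max: the smallest penalty at which all penalized coefficients are
# zero, accounting for unpenalized columns (KKT at the all-zero penalized
# solution: residual of y on intercept + unpenalized columns).
lambda_max_value <- function(y, X, pf) {
  n <- length(y)
  unpen <- which(pf == 0)
  if (length(unpen)) {
    fit <- stats::lm.fit(cbind(1, X[, unpen, drop = FALSE]), y)
    r <- fit$residuals
  } else {
    r <- y - mean(y)
  }
  Xc <- sweep(X, 2, colMeans(X))
  max(abs(drop(crossprod(Xc[, pf > 0, drop = FALSE], r))) / n)
}

#' Select the LASSO penalty by k-fold cross-validation
#'
#' Folds are assigned by a single seeded permutation of the rows; the
#' penalty grid is log-spaced from the data-derived `lambda_max` (smallest
#' penalty zeroing all penalized coefficients) down to
#' `lambda_max * lambda_min_ratio`. The selected penalty minimizes mean
#' held-out squared error, or applies the one-standard-error rule if
#' configured. Deterministic given `settings$seed`.
#'
#' @inheritParams lasso_path
#' @param settings An [estimator_settings()].
#' @param foldid Optional integer fold assignment (overrides the seeded
#'   permutation; used internally to share folds across node regressions).
#' @return An object of class `cv_lasso`: `lambda` (selected), `rule`,
#'   `lambda_grid`, `cv_mean`, `cv_se`, `foldid`.
#' @export
cv_select_lambda <- function(y, X, settings = estimator_settings(),
                             unpenalized = NULL, foldid = NULL) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  k <- settings$n_folds
  if (n < k) abort_clpnet("fewer rows than folds")
  pf <- rep(1, ncol(X))
  if (!is.null(unpenalized)) {
    idx <- if (is.character(unpenalized)) match(unpenalized, colnames(X))
           else as.integer(unpenalized)
    pf[idx] <- 0
  }
  if (is.null(foldid)) {
    foldid <- withr::with_seed(settings$seed, sample(rep_len(seq_len(k), n)))
  }
  lam_max <- max(lambda_max_value(y, X, pf), 1e-6)
  grid <- exp(seq(log(lam_max), log(lam_max * settings$lambda_min_ratio),
                  length.out = settings$n_lambda))
  grid[1] <- lam_max  # exp(log(x)) can sit one ulp below the zeroing bound
  err <- matrix(NA_real_, k, length(grid))
  for (f in seq_len(k)) {
    tr <- foldid != f
    fit <- cd_lasso(y[tr], X[tr, , drop = FALSE], grid, pf,
                    settings$tol, settings$maxit)
    pred <- sweep(X[!tr, , drop = FALSE] %*% fit$beta, 2, fit$intercept, `+`)
    err[f, ] <- colMeans((y[!tr] - pred)^2)
  }
  cv_mean <- colMeans(err)
  cv_se <- apply(err, 2, stats::sd) / sqrt(k)
  i_min <- which.min(cv_mean)
  lambda <- if (settings$lambda_rule == "1se") {
    grid[min(which(cv_mean <= cv_mean[i_min] + cv_se[i_min]))]
  } else {
    grid[i_min]
  }
  structure(
    list(lambda = lambda, rule = settings$lambda_rule, lambda_grid = grid,
         cv_mean = cv_mean, cv_se = cv_se, foldid = foldid),
    class = "cv_lasso"
  )
}

#' @export
print.cv_lasso <- function(x, ...) {
  cat(sprintf("<cv_lasso> selected lambda = %.5f (%s rule) over %d grid points\n",
              x$lambda, x$rule, length(x$lambda_grid)))
  invisible(x)
}
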