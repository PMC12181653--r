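#' Fit the construct-level cross-lagged path model
#'
#' Manifest (composite-score) cross-lagged path model among the wave-1 and
#' wave-2 construct composites: every wave-2 construct is regressed on the
#' wave-1 constructs (cross-lagged and autoregressive paths) plus the
#' covariates, wave-1 covariances and wave-2 residual covariances are free
#' (concurrent covariance), and all variables are z-scored first so the
#' reported paths are standardized coefficients. With all paths free the
#' equation-wise least-squares estimates are the maximum-likelihood
#' solution and the model is saturated (`df = 0`); dropping paths via
#' `paths` yields a testable model whose fit is summarized by
#' `chisq = (n - 1) * F_ML` against the saturated model, with CFI/TLI
#' against the independence baseline,
#' `RMSEA = sqrt(max(chisq - df, 0) / (df * (n - 1)))`, and SRMR as the
#' root-mean-square residual correlation.
#'
#' @param scores Tibble of composite scores, e.g. from [construct_scores()]:
#'   columns `<construct>_t1`, `<construct>_t2` for every construct, plus
#'   the covariate columns.
#' @param constructs Construct name stems (default
#'   `c("cptsd", "dep", "anx")`).
#' @param covariates Covariate columns predicting the wave-2 constructs
#'   (default `c("gender", "age")`); `NULL` for none.
#' @param paths Optional character vector of construct paths to keep, each
#'   `"from->to"` in construct stems (e.g. `"cptsd->anx"`); `NULL` keeps
#'   all cross-lagged and autoregressive paths. Covariate paths are always
#'   kept.
#' @return An object of class `clpm`: `paths` tibble (`from`, `to`,
#'   `estimate`, `se`, `z`, `p_value`), `wave1_cor` and `wave2_resid_cor`
#'   matrices, `fit` (chisq, df, p, cfi, tli, rmsea, srmr), `vcov` of the
#'   path estimates, `n`.
#' @export
#' @examples
#' tr <- make_truth(c("cptsd", "dep", "anx"), 0, 0.3, 0.4, seed = 1)
#' tr$B_true["cptsd", "anx"] <- 0.25
#' d <- simulate_panel(tr, generator_config(500, seed = 2, discretize = FALSE,
#'                                          missing_rate = 0,
#'                                          screen_negative_rate = 0,
#'                                          control_fail_rate = 0))
#' names(d) <- sub("^t([12])_(\\w+)$", "\\2_t\\1", names(d))
#' fit <- fit_path_model(d)
#' glance(fit)
fit_path_model <- function(scores, constructs = c("cptsd", "dep", "anx"),
                           covariates = c("gender", "age"), paths = NULL) {
  exo_cols <- c(paste0(constructs, "_t1"), covariates)
  endo_cols <- paste0(constructs, "_t2")
  need <- c(exo_cols, endo_cols)
  missing_cols <- setdiff(need, names(scores))
  if (length(missing_cols)) {
    abort_clpnet(sprintf("missing score columns: %s",
                         paste(missing_cols, collapse = ", ")))
  }
  raw <- as.matrix(scores[need])
  if (anyNA(raw)) abort_clpnet("missing values in scores; impute first")
  n <- nrow(raw)
  if (n <= length(need)) abort_clpnet("need more rows than observed variables")
  Z <- zscore_matrix(raw, "score column")
  colnames(Z) <- need
  S <- stats::cov(Z)
  p_all <- ncol(Z)

  # regressor set per wave-2 equation
  all_paths <- as.vector(outer(constructs, constructs,
                               function(a, b) paste0(a, "->", b)))
  keep_paths <- if (is.null(paths)) all_paths else paths
  bad <- setdiff(keep_paths, all_paths)
  if (length(bad)) {
    abort_clpnet(sprintf("unknown path(s): %s", paste(bad, collapse = ", ")))
  }
  regressors <- lapply(constructs, function(to) {
    froms <- constructs[paste0(constructs, "->", to) %in% keep_paths]
    c(paste0(froms, "_t1"), covariates)
  })
  names(regressors) <- constructs

  X_full <- Z[, exo_cols, drop = FALSE]
  fits <- lapply(constructs, function(to) {
    Xj <- Z[, regressors[[to]], drop = FALSE]
    qrj <- qr(cbind(`(Intercept)` = 1, Xj))
    b <- qr.coef(qrj, Z[, paste0(to, "_t2")])
    res <- qr.resid(qrj, Z[, paste0(to, "_t2")])
    list(coef = b[-1], res = res, X = Xj)
  })
  names(fits) <- constructs
  resid_mat <- vapply(fits, `[[`, numeric(n), "res")
  psi <- crossprod(resid_mat) / (n - 1)

  # joint covariance of the stacked coefficient vector:
  # Cov(b_i, b_j) = psi_ij * (Xi'Xi)^-1 Xi'Xj (Xj'Xj)^-1
  coef_names <- unlist(lapply(constructs, function(to) {
    paste0(sub("_t1$", "", regressors[[to]]), "->", to)
  }))
  est <- unlist(lapply(fits, `[[`, "coef"), use.names = FALSE)
  names(est) <- coef_names
  xtx_inv <- lapply(fits, function(f) chol2inv(chol(crossprod(f$X))))
  vc <- matrix(0, length(est), length(est),
               dimnames = list(coef_names, coef_names))
  offsets <- c(0, cumsum(vapply(fits, function(f) ncol(f$X), 0L)))
  for (i in seq_along(constructs)) {
    for (j in seq_along(constructs)) {
      Xi <- fits[[i]]$X
      Xj <- fits[[j]]$X
      blk <- psi[i, j] * xtx_inv[[i]] %*% crossprod(Xi, Xj) %*% xtx_inv[[j]]
      vc[(offsets[i] + 1):offsets[i + 1],
         (offsets[j] + 1):offsets[j + 1]] <- blk
    }
  }

  # model-implied covariance: exogenous block free (= sample), Gamma from
  # the equation fits, residual covariances free
  gamma <- matrix(0, length(exo_cols), length(constructs),
                  dimnames = list(exo_cols, endo_cols))
  for (to in constructs) {
    gamma[regressors[[to]], paste0(to, "_t2")] <- fits[[to]]$coef
  }
  Sxx <- S[exo_cols, exo_cols]
  sigma <- matrix(0, p_all, p_all, dimnames = list(need, need))
  sigma[exo_cols, exo_cols] <- Sxx
  sigma[exo_cols, endo_cols] <- Sxx %*% gamma
  sigma[endo_cols, exo_cols] <- t(Sxx %*% gamma)
  sigma[endo_cols, endo_cols] <- t(gamma) %*% Sxx %*% gamma + psi

  n_free <- length(exo_cols) * (length(exo_cols) + 1) / 2 +
    length(est) + length(constructs) * (length(constructs) + 1) / 2
  df <- p_all * (p_all + 1) / 2 - n_free
  fml <- function(sig) {
    as.numeric(determinant(sig, logarithm = TRUE)$modulus -
                 determinant(S, logarithm = TRUE)$modulus +
                 sum(diag(S %*% solve(sig))) - p_all)
  }
  chisq <- max((n - 1) * fml(sigma), 0)
  sigma_b <- diag(diag(S))
  dimnames(sigma_b) <- dimnames(S)
  chisq_b <- max((n - 1) * fml(sigma_b), 0)
  df_b <- p_all * (p_all + 1) / 2 - p_all
  num <- max(chisq - df, 0)
  den <- max(chisq_b - df_b, chisq - df, 0)
  cfi <- if (den == 0) 1 else 1 - num / den
  tli <- if (df == 0) 1 else {
    ratio_b <- chisq_b / df_b
    min(1, (ratio_b - chisq / df) / (ratio_b - 1))
  }
  rmsea <- if (df == 0) 0 else sqrt(max(chisq - df, 0) / (df * (n - 1)))
  dcor <- function(m) stats::cov2cor(m)
  resid_cor <- dcor(S) - dcor(sigma)
  srmr <- sqrt(mean(resid_cor[lower.tri(resid_cor, diag = TRUE)]^2))

  se <- sqrt(diag(vc))
  z <- est / se
  path_tbl <- tibble::tibble(
    from = sub("->.*$", "", coef_names),
    to = sub("^.*->", "", coef_names),
    estimate = unname(est), se = unname(se), z = unname(z),
    p_value = 2 * stats::pnorm(-abs(z)),
    kind = ifelse(sub("->.*$", "", coef_names) %in% covariates, "covariate",
                  ifelse(sub("->.*$", "", coef_names) ==
                           sub("^.*->", "", coef_names),
                         "autoregressive", "cross_lagged"))
  )
  w1 <- paste0(constructs, "_t1")
  structure(
    list(paths = path_tbl,
         wave1_cor = stats::cov2cor(S[w1, w1]),
         wave2_resid_cor = stats::cov2cor(psi),
         fit = list(chisq = chisq, df = df,
                    p_value = if (df > 0) stats::pchisq(chisq, df,
                                                        lower.tail = FALSE)
                              else NA_real_,
                    cfi = cfi, tli = tli, rmsea = rmsea, srmr = srmr),
         vcov = vc, n = n, constructs = constructs, covariates = covariates),
    class = "clpm"
  )
}

#' @export
print.clpm <- function(x, ...) {
  cat(sprintf("<clpm> %d constructs, n = %d; chisq(%d) = %.3f, CFI = %.3f, TLI = %.3f, RMSEA = %.3f, SRMR = %.3f\n",
              length(x$constructs), x$n, x$fit$df, x$fit$chisq,
              x$fit$cfi, x$fit$tli, x$fit$rmsea, x$fit$srmr))
  print(x$paths)
  invisible(x)
}

#' @export
tidy.clpm <- function(x, ...) x$paths

#' @export
glance.clpm <- function(x, ...) {
  tibble::tibble(chisq = x$fit$chisq, df = x$fit$df,
                 p_value = x$fit$p_value, cfi = x$fit$cfi, tli = x$fit$tli,
                 rmsea = x$fit$rmsea, srmr = x$fit$srmr, n = x$n)
}

#' Wald test for the difference of two cross-lagged paths
#'
#' Tests path asymmetry: `difference = b(path_ba) - b(path_ab)` (reverse
#' minus forward, so a stronger forward path yields a negative difference),
#' with the standard error taken from the joint coefficient covariance and
#' a two-sided normal p-value.
#'
#' @param result A [fit_path_model()] fit.
#' @param path_ab,path_ba Path names `"from->to"` (construct stems), e.g.
#'   `"cptsd->anx"` and `"anx->cptsd"`.
#' @return One-row tibble: `path_forward`, `path_reverse`, `difference`,
#'   `se`, `z`, `p_value`.
#' @export
wald_path_difference <- function(result, path_ab, path_ba) {
  stopifnot(inherits(result, "clpm"))
  nm <- rownames(result$vcov)
  for (pth in c(path_ab, path_ba)) {
    if (!pth %in% nm) abort_clpnet(sprintf("unknown path `%s`", pth))
  }
  est <- result$paths$estimate
  names(est) <- paste0(result$paths$from, "->", result$paths$to)
  if (path_ab == path_ba) {
    return(tibble::tibble(path_forward = path_ab, path_reverse = path_ba,
                          difference = 0, se = 0, z = 0, p_value = 1))
  }
  d <- est[path_ba] - est[path_ab]
  v <- result$vcov[path_ba, path_ba] + result$vcov[path_ab, path_ab] -
    2 * result$vcov[path_ba, path_ab]
  se <- sqrt(max(v, 0))
  z <- if (se > 0) d / se else 0
  tibble::tibble(path_forward = path_ab, path_reverse = path_ba,
                 difference = unname(d), se = se, z = unname(z),
                 p_value = unname(2 * stats::pnorm(-abs(z))))
}

#' Classify fit indices against conventional cutoffs
#'
#' CFI/TLI: above 0.95 "good", above 0.90 "acceptable", else "poor".
#' RMSEA/SRMR: 0.08 or lower "acceptable" (boundary inclusive), else
#' "poor".
#'
#' @param result A [fit_path_model()] fit, or a named list/vector with any
#'   of `cfi`, `tli`, `rmsea`, `srmr`.
#' @param cfi_good,cfi_acceptable,absolute_cutoff Cutoffs (defaults 0.95,
#'   0.90, 0.08).
#' @return Tibble with columns `index`, `value`, `label`.
#' @export
#' @examples
#' evaluate_fit(list(cfi = 0.96, rmsea = 0.08))
evaluate_fit <- function(result, cfi_good = 0.95, cfi_acceptable = 0.90,
                         absolute_cutoff = 0.08) {
  vals <- if (inherits(result, "clpm")) result$fit else as.list(result)
  rows <- list()
  for (idx in c("cfi", "tli")) {
    if (!is.null(vals[[idx]])) {
      v <- vals[[idx]]
      rows[[idx]] <- tibble::tibble(
        index = toupper(idx), value = v,
        label = if (v > cfi_good) "good"
                else if (v > cfi_acceptable) "acceptable" else "poor")
    }
  }
  for (idx in c("rmsea", "srmr")) {
    if (!is.null(vals[[idx]])) {
      v <- vals[[idx]]
      rows[[idx]] <- tibble::tibble(
        index = toupper(idx), value = v,
        label = if (v <= absolute_cutoff) "acceptable" else "poor")
    }
  }
  if (length(rows) == 0L) abort_clpnet("no recognized fit indices")
  dplyr::bind_rows(rows)
}
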