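#' Z-score the item columns of a panel dataset
#'
#' Standardizes every `t1_*`/`t2_*` column to mean 0 and SD 1 (denominator
#' `n - 1`) within its wave, storing the means and SDs so the transform is
#' invertible. Needed so network edge weights are comparable across items
#' with different response ranges.
#'
#' @param data Panel tibble with no missing item responses.
#' @return The tibble with standardized item columns and an attribute
#'   `standardization` (tibble of `column`, `mean`, `sd`).
#' @export
standardize <- function(data) {
  item_cols <- grep("^t[12]_", names(data), value = TRUE)
  if (length(item_cols) == 0L) abort_clpnet("no item columns to standardize")
  m <- as.matrix(data[item_cols])
  if (anyNA(m)) abort_clpnet("missing values; impute first")
  z <- zscore_matrix(m, what = "item column")
  params <- tibble::tibble(column = item_cols,
                           mean = attr(z, "scaled:center"),
                           sd = attr(z, "scaled:scale"))
  for (i in seq_along(item_cols)) data[[item_cols[i]]] <- z[, i]
  attr(data, "standardization") <- params
  data
}

# Node-wise cross-validated lasso fits sharing fold assignment and per-fold
# Gram matrices across outcomes (the predictor block is identical for every
# node regression, so the expensive per-fold crossprods are computed once).
fit_nodewise <- function(Y, X, settings, unpen_idx) {
  n <- nrow(X)
  k <- settings$n_folds
  if (n < k) abort_clpnet("fewer rows than folds")
  q <- ncol(Y)
  p <- ncol(X)
  pf <- rep(1, p)
  pf[unpen_idx] <- 0
  foldid <- withr::with_seed(settings$seed,
                             sample(rep_len(seq_len(k), n)))

  xm_full <- colMeans(X)
  Xc_full <- sweep(X, 2, xm_full)
  G_full <- crossprod(Xc_full) / n
  base_qr <- qr(cbind(`(Intercept)` = 1, X[, unpen_idx, drop = FALSE]))

  folds <- lapply(seq_len(k), function(f) {
    tr <- foldid != f
    Xtr <- X[tr, , drop = FALSE]
    xm <- colMeans(Xtr)
    Xc <- sweep(Xtr, 2, xm)
    list(tr = tr, xm = xm, Xc = Xc, G = crossprod(Xc) / nrow(Xc),
         Xte = X[!tr, , drop = FALSE])
  })

  coefs <- matrix(0, p, q, dimnames = list(colnames(X), colnames(Y)))
  lambda <- numeric(q)
  for (j in seq_len(q)) {
    y <- Y[, j]
    r0 <- qr.resid(base_qr, y)
    lam_max <- max(max(abs(drop(crossprod(Xc_full[, pf > 0, drop = FALSE],
                                          r0))) / n), 1e-6)
    grid <- exp(seq(log(lam_max), log(lam_max * settings$lambda_min_ratio),
                    length.out = settings$n_lambda))
    grid[1] <- lam_max  # exp(log(x)) can sit one ulp below the zeroing bound
    err <- matrix(NA_real_, k, length(grid))
    for (f in seq_len(k)) {
      fd <- folds[[f]]
      ytr <- y[fd$tr]
      ym <- mean(ytr)
      cvec <- drop(crossprod(fd$Xc, ytr - ym)) / nrow(fd$Xc)
      beta <- cd_lasso_path_cpp(fd$G, cvec, grid, pf,
                                settings$tol, settings$maxit)
      intercept <- ym - drop(fd$xm %*% beta)
      pred <- sweep(fd$Xte %*% beta, 2, intercept, `+`)
      err[f, ] <- colMeans((y[!fd$tr] - pred)^2)
    }
    cv_mean <- colMeans(err)
    cv_se <- apply(err, 2, stats::sd) / sqrt(k)
    i_min <- which.min(cv_mean)
    i_sel <- if (settings$lambda_rule == "1se") {
      min(which(cv_mean <= cv_mean[i_min] + cv_se[i_min]))
    } else i_min
    lambda[j] <- grid[i_sel]
    cvec_full <- drop(crossprod(Xc_full, y - mean(y))) / n
    beta_full <- cd_lasso_path_cpp(G_full, cvec_full,
                                   grid[seq_len(i_sel)], pf,
                                   settings$tol, settings$maxit)
    coefs[, j] <- beta_full[, i_sel]
  }
  list(coefs = coefs, lambda = stats::setNames(lambda, colnames(Y)),
       foldid = foldid)
}

#' Estimate the cross-lagged panel network
#'
#' For each wave-2 symptom, fits a LASSO regression on all wave-1 symptoms
#' plus the (unpenalized) covariates, selecting the penalty by k-fold
#' cross-validation with one seeded fold permutation shared across all node
#' regressions. Items and outcomes are z-scored first, so edge weights are
#' fully standardized regression coefficients. Cross-lagged effects are
#' stored in `B` (entry `[i, j]`: wave-1 node `i` predicting wave-2 node
#' `j`), each node's self-prediction in the autoregressive vector `a`
#' (the diagonal of `B` is kept at zero).
#'
#' @param data Screened, imputed panel tibble (see [screen_participants()],
#'   [impute_missing()]); standardization is applied internally.
#' @param settings An [estimator_settings()].
#' @param covariates Covariate column names controlled for (unpenalized) in
#'   every node regression; `NULL` for none.
#' @return An object of class `clpn` with fields `node_labels`, `B`, `a`,
#'   `lambda` (selected penalty per outcome), `covariate_coefs`, `settings`,
#'   `n`.
#' @export
#' @examples
#' tr <- make_truth(paste0("n", 1:5), 0.1, 0.4, 0.3, seed = 1)
#' d <- simulate_panel(tr, generator_config(400, seed = 1,
#'                                          missing_rate = 0,
#'                                          screen_negative_rate = 0,
#'                                          control_fail_rate = 0))
#' net <- estimate_network(d, estimator_settings(seed = 1))
#' net
estimate_network <- function(data, settings = estimator_settings(),
                             covariates = c("gender", "age")) {
  nodes <- panel_nodes(data)
  p <- length(nodes)
  m1 <- as.matrix(data[paste0("t1_", nodes)])
  m2 <- as.matrix(data[paste0("t2_", nodes)])
  if (anyNA(m1) || anyNA(m2)) {
    abort_clpnet("missing item responses; run impute_missing() first")
  }
  X1 <- zscore_matrix(m1, "item column")
  colnames(X1) <- nodes
  Y2 <- zscore_matrix(m2, "item column")
  colnames(Y2) <- nodes
  if (length(covariates)) {
    missing_cov <- setdiff(covariates, names(data))
    if (length(missing_cov)) {
      abort_clpnet(sprintf("covariate column(s) not found: %s",
                           paste(missing_cov, collapse = ", ")))
    }
    CV <- zscore_matrix(as.matrix(data[covariates]), "covariate")
    colnames(CV) <- covariates
    X <- cbind(X1, CV)
    unpen <- p + seq_along(covariates)
  } else {
    X <- X1
    unpen <- integer(0)
  }
  fit <- fit_nodewise(Y2, X, settings, unpen)
  B <- fit$coefs[seq_len(p), , drop = FALSE]
  a <- stats::setNames(diag(B), nodes)
  diag(B) <- 0
  cov_coefs <- if (length(covariates)) {
    t(fit$coefs[p + seq_along(covariates), , drop = FALSE])
  } else {
    matrix(0, p, 0, dimnames = list(nodes, NULL))
  }
  structure(
    list(node_labels = nodes, B = B, a = a, lambda = fit$lambda,
         covariate_coefs = cov_coefs, covariates = covariates,
         settings = settings, n = nrow(data)),
    class = "clpn"
  )
}

#' @export
print.clpn <- function(x, ...) {
  cat(sprintf(
    "<clpn> %d nodes, %d cross-lagged edges (non-zero), n = %d, %d-fold CV (%s rule)\n",
    length(x$node_labels), sum(x$B != 0), x$n,
    x$settings$n_folds, x$settings$lambda_rule))
  invisible(x)
}

#' Display-thresholded edge list
#'
#' Returns the cross-lagged edges with `|weight| >= threshold`, sorted by
#' decreasing magnitude (ties broken by source then target label). The
#' head of this list is the "strongest cross-lagged associations" report;
#' thresholding affects only this view, never the stored coefficients.
#'
#' @param network A `clpn` object.
#' @param threshold Non-negative display cutoff (default 0.05, the
#'   interpretability threshold used when plotting symptom networks).
#' @return Tibble with columns `from`, `to`, `weight`.
#' @export
threshold_for_display <- function(network, threshold = 0.05) {
  stopifnot(inherits(network, "clpn") || is.matrix(network))
  if (!is_scalar_number(threshold) && !identical(threshold, Inf)) {
    abort_clpnet("`threshold` must be a single non-negative number")
  }
  if (threshold < 0) abort_clpnet("`threshold` must be non-negative")
  B <- if (is.matrix(network)) network else network$B
  labels <- rownames(B) %||% as.character(seq_len(nrow(B)))
  idx <- which(B != 0 & abs(B) >= threshold, arr.ind = TRUE)
  edges <- tibble::tibble(
    from = labels[idx[, 1]],
    to = labels[idx[, 2]],
    weight = B[idx]
  )
  dplyr::arrange(edges, dplyr::desc(abs(.data$weight)), .data$from, .data$to)
}

#' Export a network as edge-list CSV or GraphML
#'
#' The CSV carries `from,to,weight,kind` rows with
#' `kind` in `cross_lagged`, `autoregressive`, `covariate`; the GraphML
#' export contains the display-thresholded cross-lagged graph for network
#' viewers.
#'
#' @param network A `clpn` object.
#' @param path Output file path.
#' @param threshold Display threshold applied to cross-lagged edges
#'   (default 0 for the CSV: full network; 0.05 for GraphML).
#' @return `path`, invisibly.
#' @export
write_network_csv <- function(network, path, threshold = 0) {
  stopifnot(inherits(network, "clpn"))
  cl <- dplyr::mutate(threshold_for_display(network, threshold),
                      kind = "cross_lagged")
  auto <- tibble::tibble(from = network$node_labels,
                         to = network$node_labels,
                         weight = unname(network$a),
                         kind = "autoregressive")
  cov <- if (ncol(network$covariate_coefs)) {
    tidyr::pivot_longer(
      tibble::as_tibble(network$covariate_coefs, rownames = "to"),
      -"to", names_to = "from", values_to = "weight"
    )[, c("from", "to", "weight")]
  } else {
    tibble::tibble(from = character(), to = character(), weight = numeric())
  }
  cov$kind <- rep("covariate", nrow(cov))
  readr::write_csv(dplyr::bind_rows(cl, auto, cov), path)
  invisible(path)
}

#' @rdname write_network_csv
#' @export
write_network_graphml <- function(network, path, threshold = 0.05) {
  stopifnot(inherits(network, "clpn"))
  edges <- threshold_for_display(network, threshold)
  g <- igraph::graph_from_data_frame(
    edges, directed = TRUE,
    vertices = data.frame(name = network$node_labels)
  )
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @export
tidy.clpn <- function(x, threshold = 0, ...) {
  threshold_for_display(x, threshold)
}

#' @export
glance.clpn <- function(x, ...) {
  tibble::tibble(
    n_nodes = length(x$node_labels),
    n_edges = sum(x$B != 0),
    sparsity = 1 - sum(x$B != 0) / (length(x$node_labels)^2 - length(x$node_labels)),
    mean_autoregression = mean(x$a),
    mean_lambda = mean(x$lambda),
    n = x$n
  )
}
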