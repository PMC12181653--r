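#' Bootstrap confidence intervals for edge weights
#'
#' Resamples participants with replacement, re-estimates the network per
#' resample, and collects the distribution of every cross-lagged edge
#' weight. Percentile intervals (order-statistic quantiles, so with
#' `n_boot = 2` the bounds are the min and max) summarize estimation
#' accuracy; wide, heavily overlapping intervals across edges indicate that
#' edge-order interpretations are unreliable. Replicate resamples use seeds
#' derived from `(seed, replicate)`, so results are independent of how
#' replicates are scheduled. Estimator failures inside a resample are
#' skipped and counted; more than 5% failures aborts.
#'
#' @param data Screened, imputed panel tibble.
#' @param settings An [estimator_settings()].
#' @param n_boot Number of resamples (the conventional choice is 1000).
#' @param seed Integer seed.
#' @param conf_level Interval coverage (default 0.95).
#' @return Object of class `edge_boot`: `edges` tibble (`from`, `to`,
#'   `estimate`, `boot_mean`, `lower`, `upper`), `replicates` (matrix
#'   n_boot x edges), `n_boot`, `n_failed`.
#' @export
bootstrap_edges <- function(data, settings = estimator_settings(),
                            n_boot = 1000, seed = 1, conf_level = 0.95) {
  if (n_boot < 2) abort_clpnet("`n_boot` must be >= 2")
  full <- estimate_network(data, settings)
  p <- length(full$node_labels)
  off <- which(diag(p) == 0)
  pairs <- arrayInd(off, c(p, p))
  edge_names <- paste0(full$node_labels[pairs[, 1]], "->",
                       full$node_labels[pairs[, 2]])
  n <- nrow(data)
  reps <- matrix(NA_real_, n_boot, length(off),
                 dimnames = list(NULL, edge_names))
  failed <- 0L
  for (b in seq_len(n_boot)) {
    idx <- withr::with_seed(stage_seed(seed, paste0("edgeboot", b)),
                            sample.int(n, n, replace = TRUE))
    net <- tryCatch(estimate_network(data[idx, , drop = FALSE], settings),
                    clpnet_error = function(e) NULL)
    if (is.null(net)) failed <- failed + 1L else reps[b, ] <- net$B[off]
  }
  if (failed > 0.05 * n_boot) {
    abort_clpnet(sprintf("%d of %d bootstrap resamples failed (> 5%%)",
                         failed, n_boot))
  }
  reps_ok <- reps[stats::complete.cases(reps), , drop = FALSE]
  alpha <- 1 - conf_level
  qs <- apply(reps_ok, 2, stats::quantile, probs = c(alpha / 2, 1 - alpha / 2),
              type = 1, names = FALSE)
  edges <- tibble::tibble(
    from = full$node_labels[pairs[, 1]],
    to = full$node_labels[pairs[, 2]],
    estimate = full$B[off],
    boot_mean = colMeans(reps_ok),
    lower = qs[1, ],
    upper = qs[2, ]
  )
  structure(
    list(edges = edges, replicates = reps_ok, n_boot = n_boot,
         n_failed = failed, network = full),
    class = "edge_boot"
  )
}

#' @export
print.edge_boot <- function(x, ...) {
  cover0 <- mean(x$edges$lower <= 0 & x$edges$upper >= 0)
  cat(sprintf(
    "<edge_boot> %d resamples (%d failed), %d edges; %.0f%% of intervals contain 0\n",
    x$n_boot, x$n_failed, nrow(x$edges), 100 * cover0))
  invisible(x)
}

#' @export
tidy.edge_boot <- function(x, ...) x$edges

#' Pairwise interval-overlap summary for bootstrapped edges
#'
#' For each pair of edges, reports whether their bootstrap confidence
#' intervals overlap — the conventional accuracy reading: when most
#' intervals overlap, differences in edge weight should not be
#' over-interpreted.
#'
#' @param x An [bootstrap_edges()] result.
#' @return Logical edge-by-edge matrix (`TRUE` = intervals overlap).
#' @export
edge_ci_overlap <- function(x) {
  stopifnot(inherits(x, "edge_boot"))
  lo <- x$edges$lower
  hi <- x$edges$upper
  m <- outer(lo, hi, `<=`) & t(outer(lo, hi, `<=`))
  dimnames(m) <- list(paste0(x$edges$from, "->", x$edges$to),
                      paste0(x$edges$from, "->", x$edges$to))
  m
}

#' Case-dropping bootstrap for centrality stability
#'
#' For each drop proportion `p`, draws subsamples without replacement of
#' size `(1 - p) * N`, re-estimates the network, and records the
#' correlation between subsample and full-sample centralities across nodes.
#' Proportions whose retained subsample would fall below `10 * p_nodes`
#' rows are skipped with a warning.
#'
#' @param data Screened, imputed panel tibble.
#' @param settings An [estimator_settings()].
#' @param index Centrality to track: `"in_ei"` or `"out_ei"`.
#' @param proportions Grid of case-drop proportions in (0, 0.75].
#' @param n_boot Subsamples per proportion.
#' @param seed Integer seed (replicate-derived sub-seeds).
#' @param method Correlation type; Pearson by default, Spearman available.
#' @return Object of class `case_drop`: `correlations` tibble
#'   (`proportion`, `replicate`, `correlation`), `index`, `n`, `n_boot`.
#' @export
case_drop_bootstrap <- function(data, settings = estimator_settings(),
                                index = c("in_ei", "out_ei"),
                                proportions = seq(0.05, 0.75, by = 0.05),
                                n_boot = 50, seed = 1,
                                method = c("pearson", "spearman")) {
  index <- match.arg(index)
  method <- match.arg(method)
  if (length(proportions) == 0L) abort_clpnet("empty proportion grid")
  if (any(proportions <= 0 | proportions > 0.75)) {
    abort_clpnet("drop proportions must lie in (0, 0.75]")
  }
  n <- nrow(data)
  nodes <- panel_nodes(data)
  full <- expected_influence(estimate_network(data, settings))[[index]]
  rows <- list()
  for (prop in proportions) {
    m <- round((1 - prop) * n)
    if (m < 10 * length(nodes)) {
      warning(sprintf(
        "skipping drop proportion %.2f: retained subsample (%d rows) below 10 x node count",
        prop, m), call. = FALSE)
      next
    }
    cors <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      idx <- withr::with_seed(
        stage_seed(seed, sprintf("casedrop_%g_%d", prop, b)),
        sample.int(n, m, replace = FALSE))
      net <- tryCatch(
        estimate_network(data[idx, , drop = FALSE], settings),
        clpnet_error = function(e) NULL)
      cors[b] <- if (is.null(net)) NA_real_ else {
        sub <- expected_influence(net)[[index]]
        if (stats::sd(sub) == 0 || stats::sd(full) == 0) 0
        else stats::cor(sub, full, method = method)
      }
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      proportion = prop, replicate = seq_len(n_boot), correlation = cors)
  }
  if (length(rows) == 0L) {
    abort_clpnet("all drop proportions were skipped; sample too small")
  }
  structure(
    list(correlations = dplyr::bind_rows(rows), index = index,
         method = method, n = n, n_boot = n_boot),
    class = "case_drop"
  )
}

#' @export
print.case_drop <- function(x, ...) {
  cs <- cs_coefficient(x)
  cat(sprintf("<case_drop> %s, %d proportions x %d subsamples, CS = %.2f (%s)\n",
              x$index, length(unique(x$correlations$proportion)), x$n_boot,
              cs, cs_label(cs)))
  invisible(x)
}

#' @export
tidy.case_drop <- function(x, ...) x$correlations

#' Correlation-stability (CS) coefficient
#'
#' The largest drop proportion `p` such that, at every proportion up to and
#' including `p`, at least `retain_prob` of the subsample-vs-full-sample
#' centrality correlations are `>= cor_threshold`; 0 if no proportion
#' qualifies. With the conventional constants (threshold 0.7, retention
#' 0.95), values above 0.5 indicate a very stable network and values above
#' 0.25 moderate stability.
#'
#' @param result A [case_drop_bootstrap()] result, or any data frame with
#'   `proportion` and `correlation` columns.
#' @param cor_threshold Correlation retention threshold (default 0.7).
#' @param retain_prob Required probability of retaining the threshold
#'   (default 0.95).
#' @return A scalar in `[0, 0.75]`.
#' @export
#' @examples
#' perfect <- data.frame(proportion = rep(c(0.25, 0.75), each = 20),
#'                       correlation = 1)
#' cs_coefficient(perfect)
cs_coefficient <- function(result, cor_threshold = 0.7, retain_prob = 0.95) {
  cors <- if (inherits(result, "case_drop")) result$correlations else result
  if (!is.data.frame(cors) ||
      !all(c("proportion", "correlation") %in% names(cors))) {
    abort_clpnet("malformed case-drop result: need `proportion` and `correlation`")
  }
  if (nrow(cors) == 0L) abort_clpnet("no recorded correlations")
  by_prop <- dplyr::summarise(
    dplyr::group_by(cors, .data$proportion),
    retained = mean(.data$correlation >= cor_threshold, na.rm = TRUE),
    .groups = "drop")
  by_prop <- dplyr::arrange(by_prop, .data$proportion)
  ok <- cumall(by_prop$retained >= retain_prob)
  if (!any(ok)) 0 else max(by_prop$proportion[ok])
}

cumall <- function(x) cumprod(as.numeric(x)) > 0

#' @rdname cs_coefficient
#' @param cs A CS-coefficient value.
#' @return `cs_label()`: the conventional interpretive label —
#'   `"very stable"` above 0.5, `"moderately stable"` above 0.25,
#'   `"unstable"` otherwise.
#' @export
cs_label <- function(cs) {
  ifelse(cs > 0.5, "very stable",
         ifelse(cs > 0.25, "moderately stable", "unstable"))
}
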