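#' Expected-influence centrality of a directed network
#'
#' Out expected influence (Out-EI) of node `i` is the signed sum of its
#' outgoing cross-lagged weights `sum_{j != i} B[i, j]` — how much the
#' symptom predicts others; In-EI of node `j` is the signed sum of incoming
#' weights `sum_{i != j} B[i, j]` — how much it is predicted by others.
#' Autoregressive paths are set to 0 (excluded entirely), as are covariate
#' coefficients. Sums are signed, not absolute: protective (negative) edges
#' reduce a node's expected influence.
#'
#' @param network A `clpn` object, or a square weight matrix with zero
#'   diagonal and row/column names.
#' @param standardize If `TRUE`, adds `in_ei_z`/`out_ei_z` columns z-scored
#'   across nodes (for plotting).
#' @return A tibble with columns `node`, `in_ei`, `out_ei` (class
#'   `centrality_table`).
#' @export
#' @examples
#' B <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
#' B["a", "b"] <- 0.3
#' expected_influence(B)
expected_influence <- function(network, standardize = FALSE) {
  B <- if (inherits(network, "clpn")) network$B else as.matrix(network)
  if (nrow(B) != ncol(B)) abort_clpnet("weight matrix must be square")
  if (any(diag(B) != 0)) {
    abort_clpnet("diagonal must be zero (autoregressive effects are excluded)")
  }
  labels <- rownames(B) %||% as.character(seq_len(nrow(B)))
  out <- tibble::tibble(
    node = labels,
    in_ei = unname(colSums(B)),
    out_ei = unname(rowSums(B))
  )
  if (standardize) {
    zs <- function(v) if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v * 0
    out$in_ei_z <- zs(out$in_ei)
    out$out_ei_z <- zs(out$out_ei)
  }
  class(out) <- c("centrality_table", class(out))
  out
}

#' Top-k centrality ranking
#'
#' Ranks nodes by signed In-EI and Out-EI in descending order,
#' lexicographic tie-break on the node label (a warning is emitted when
#' ties affect the reported head of the ranking).
#'
#' @param centrality A [expected_influence()] table.
#' @param k Number of nodes to report per index (default 3).
#' @return Tibble with columns `index` (`"in_ei"`/`"out_ei"`), `rank`,
#'   `node`, `value`.
#' @export
rank_report <- function(centrality, k = 3) {
  stopifnot(all(c("node", "in_ei", "out_ei") %in% names(centrality)))
  if (k > nrow(centrality)) abort_clpnet("`k` exceeds the node count")
  one <- function(index) {
    v <- centrality[[index]]
    ord <- order(-v, centrality$node)
    if (k > 0) {
      sel <- ord[seq_len(k)]
      boundary <- v[ord[seq_len(min(k + 1L, length(ord)))]]
      if (anyDuplicated(boundary)) {
        warning(sprintf("ties in %s ranking broken lexicographically", index),
                call. = FALSE)
      }
      tibble::tibble(index = index, rank = seq_len(k),
                     node = centrality$node[sel], value = v[sel])
    } else {
      tibble::tibble(index = character(), rank = integer(),
                     node = character(), value = numeric())
    }
  }
  dplyr::bind_rows(one("out_ei"), one("in_ei"))
}

# Bootstrap centralities: resample participants with replacement,
# re-estimate the network, recompute In-EI/Out-EI. Each replicate draws its
# resample under a seed derived from (seed, replicate index), so results do
# not depend on how replicates are partitioned across workers.
boot_centrality <- function(data, settings, n_boot, seed,
                            replicates = seq_len(n_boot)) {
  n <- nrow(data)
  p <- length(panel_nodes(data))
  res_in <- matrix(NA_real_, length(replicates), p)
  res_out <- matrix(NA_real_, length(replicates), p)
  ok <- logical(length(replicates))
  for (i in seq_along(replicates)) {
    b <- replicates[i]
    idx <- withr::with_seed(stage_seed(seed, paste0("boot", b)),
                            sample.int(n, n, replace = TRUE))
    net <- tryCatch(estimate_network(data[idx, , drop = FALSE], settings),
                    clpnet_error = function(e) NULL)
    if (!is.null(net)) {
      ei <- expected_influence(net)
      res_in[i, ] <- ei$in_ei
      res_out[i, ] <- ei$out_ei
      ok[i] <- TRUE
    }
  }
  list(in_ei = res_in, out_ei = res_out, ok = ok,
       nodes = panel_nodes(data))
}

#' Bootstrap difference test for node centralities
#'
#' Nonparametric bootstrap of the centrality difference `c_a - c_b`:
#' participants are resampled with replacement, the network re-estimated and
#' the chosen expected-influence index recomputed per replicate. The
#' difference is flagged significant when the 95% percentile interval
#' excludes 0.
#'
#' @param data Screened, imputed panel tibble.
#' @param settings An [estimator_settings()].
#' @param node_a,node_b Node labels to compare.
#' @param index `"in_ei"` or `"out_ei"`.
#' @param n_boot Number of bootstrap replicates (>= 100 recommended).
#' @param seed Seed for the resampling (replicate-derived sub-seeds make the
#'   result independent of execution order).
#' @param conf_level Interval coverage (default 0.95).
#' @return One-row tibble: `node_a`, `node_b`, `index`, `difference`
#'   (full-sample), `lower`, `upper`, `significant`, `n_boot`.
#' @export
centrality_difference_test <- function(data, settings, node_a, node_b,
                                       index = c("in_ei", "out_ei"),
                                       n_boot = 200, seed = 1,
                                       conf_level = 0.95) {
  index <- match.arg(index)
  nodes <- panel_nodes(data)
  if (!node_a %in% nodes || !node_b %in% nodes) {
    abort_clpnet("unknown node label(s)")
  }
  full <- expected_influence(estimate_network(data, settings))
  d_full <- full[[index]][full$node == node_a] -
    full[[index]][full$node == node_b]
  if (node_a == node_b) {
    return(tibble::tibble(node_a = node_a, node_b = node_b, index = index,
                          difference = 0, lower = 0, upper = 0,
                          significant = FALSE, n_boot = n_boot))
  }
  boots <- boot_centrality(data, settings, n_boot, seed)
  ia <- match(node_a, boots$nodes)
  ib <- match(node_b, boots$nodes)
  diffs <- (boots[[index]][, ia] - boots[[index]][, ib])[boots$ok]
  alpha <- 1 - conf_level
  ci <- stats::quantile(diffs, c(alpha / 2, 1 - alpha / 2),
                        type = 1, names = FALSE)
  tibble::tibble(node_a = node_a, node_b = node_b, index = index,
                 difference = d_full, lower = ci[1], upper = ci[2],
                 significant = ci[1] > 0 || ci[2] < 0, n_boot = n_boot)
}

#' Pairwise centrality difference-test matrix
#'
#' Runs the percentile-bootstrap difference test of
#' [centrality_difference_test()] for every node pair, reusing one set of
#' bootstrap replicates.
#'
#' @inheritParams centrality_difference_test
#' @return A logical node-by-node matrix; `TRUE` where the 95% interval of
#'   the centrality difference excludes 0 (diagonal `FALSE`).
#' @export
centrality_difference_matrix <- function(data, settings,
                                         index = c("in_ei", "out_ei"),
                                         n_boot = 200, seed = 1,
                                         conf_level = 0.95) {
  index <- match.arg(index)
  boots <- boot_centrality(data, settings, n_boot, seed)
  vals <- boots[[index]][boots$ok, , drop = FALSE]
  p <- length(boots$nodes)
  alpha <- 1 - conf_level
  sig <- matrix(FALSE, p, p, dimnames = list(boots$nodes, boots$nodes))
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      ci <- stats::quantile(vals[, i] - vals[, j],
                            c(alpha / 2, 1 - alpha / 2),
                            type = 1, names = FALSE)
      sig[i, j] <- sig[j, i] <- ci[1] > 0 || ci[2] < 0
    }
  }
  sig
}
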