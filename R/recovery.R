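#' Edge-recovery experiment against a known truth network
#'
#' Simulates a panel from `truth`, runs the preprocessing chain
#' (screen, impute) and the CLPN estimator, then scores the estimated
#' support and signs against the generating network:
#' sensitivity = recovered true edges / true edges (with the sign ignored),
#' sign agreement = correctly signed among recovered true edges,
#' specificity = true absent edges left at zero / absent edges, and
#' false-edge rate = 1 - specificity. With an empty truth, sensitivity and
#' sign agreement are undefined and reported as `NA`.
#'
#' @param truth A [make_truth()] network.
#' @param config A [generator_config()].
#' @param settings An [estimator_settings()].
#' @return One-row tibble: `n`, `n_final`, `n_true_edges`, `sensitivity`,
#'   `specificity`, `false_edge_rate`, `sign_agreement`.
#' @export
#' @examples
#' tr <- make_truth(paste0("n", 1:6), 0.15, 0.35, 0.3, seed = 1)
#' cfg <- generator_config(600, seed = 2, missing_rate = 0,
#'                         screen_negative_rate = 0, control_fail_rate = 0)
#' recovery_experiment(tr, cfg)
recovery_experiment <- function(truth, config,
                                settings = estimator_settings()) {
  data <- simulate_panel(truth, config)
  data <- screen_participants(data)
  data <- impute_missing(data)
  net <- estimate_network(data, settings)
  if (!identical(net$node_labels, truth$node_labels)) {
    abort_clpnet("node sets of truth and estimate disagree")
  }
  off <- which(diag(length(truth$node_labels)) == 0)
  b_true <- truth$B_true[off]
  b_est <- net$B[off]
  true_pos <- b_true != 0
  n_true <- sum(true_pos)
  recovered <- b_est != 0 & true_pos
  tibble::tibble(
    n = config$n,
    n_final = nrow(data),
    n_true_edges = n_true,
    sensitivity = if (n_true == 0) NA_real_ else sum(recovered) / n_true,
    specificity = sum(b_est == 0 & !true_pos) / sum(!true_pos),
    false_edge_rate = sum(b_est != 0 & !true_pos) / sum(!true_pos),
    sign_agreement = if (sum(recovered) == 0) NA_real_ else
      sum(sign(b_est[recovered]) == sign(b_true[recovered])) / sum(recovered)
  )
}
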