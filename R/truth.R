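#' Construct a ground-truth cross-lagged network
#'
#' Draws a sparse directed matrix of cross-lagged effects for the synthetic
#' panel generator. Entry `B[i, j]` is the standardized effect of node `i` at
#' wave 1 on node `j` at wave 2; autoregressive effects live on a separate
#' vector `a` and the diagonal of `B` is always zero. The number of non-zero
#' cross-lagged edges is `round(edge_density * p * (p - 1))`, their positions
#' a uniform draw over the off-diagonal cells and their values
#' `±effect_size` (positive with probability `prop_positive`; symptom-symptom
#' couplings are predominantly positive in practice).
#'
#' Stationarity of the implied process requires the spectral radius of
#' `B + diag(a)` to be below 1. Support and signs are redrawn up to 100
#' times to find a stable configuration; a configuration that never
#' stabilizes (e.g. a dense matrix of large effects) is rejected with an
#' error.
#'
#' @param node_labels Character vector of unique node names.
#' @param edge_density Fraction of the `p * (p - 1)` off-diagonal cells that
#'   carry an edge, in `[0, 1]`.
#' @param effect_size Magnitude of each non-zero standardized cross-lagged
#'   effect.
#' @param autoregression Common autoregressive coefficient applied to every
#'   node (wave-1 value predicting the node's own wave-2 value).
#' @param seed Integer seed; the draw is a deterministic function of it.
#' @param within_wave_corr Residual correlation among nodes within a wave,
#'   in `[0, 1)`. Default 0.3, a moderate within-wave dependence typical of
#'   symptom inventories.
#' @param covariate_effects Either a single number used for every
#'   node-covariate loading or a `p x 2` matrix with columns `gender`, `age`.
#'   Default 0.1: covariate control is exercised but not dominant.
#' @param prop_positive Probability that a drawn edge is positive.
#'
#' @return An object of class `truth_network` with fields `node_labels`,
#'   `B_true`, `a_true`, `within_wave_corr`, `covariate_effects`.
#' @seealso [simulate_panel()], [write_truth_csv()]
#' @export
#' @examples
#' tr <- make_truth(paste0("n", 1:6), edge_density = 0.2,
#'                  effect_size = 0.3, autoregression = 0.2, seed = 1)
#' sum(tr$B_true != 0)
make_truth <- function(node_labels, edge_density, effect_size,
                       autoregression, seed,
                       within_wave_corr = 0.3,
                       covariate_effects = 0.1,
                       prop_positive = 0.9) {
  if (anyDuplicated(node_labels)) abort_clpnet("node labels must be unique")
  p <- length(node_labels)
  if (!is_scalar_number(edge_density) || edge_density < 0 || edge_density > 1) {
    abort_clpnet("`edge_density` must lie in [0, 1]")
  }
  n_edges <- round(edge_density * p * (p - 1))
  a <- rep(autoregression, p)
  if (is.matrix(covariate_effects)) {
    stopifnot(nrow(covariate_effects) == p, ncol(covariate_effects) == 2)
    cov_eff <- covariate_effects
  } else {
    cov_eff <- matrix(covariate_effects, p, 2)
  }
  colnames(cov_eff) <- c("gender", "age")
  rownames(cov_eff) <- node_labels

  off_diag <- which(diag(p) == 0)
  B <- withr::with_seed(seed, {
    for (attempt in seq_len(100L)) {
      Bc <- matrix(0, p, p)
      if (n_edges > 0) {
        cells <- sample(off_diag, n_edges)
        signs <- ifelse(stats::runif(n_edges) < prop_positive, 1, -1)
        Bc[cells] <- signs * effect_size
      }
      if (max(Mod(eigen(Bc + diag(a, p), only.values = TRUE)$values)) < 1) {
        break
      }
      Bc <- NULL
    }
    Bc
  })
  if (is.null(B)) {
    abort_clpnet(paste0(
      "no stable configuration found in 100 draws: spectral radius of ",
      "B + diag(a) is >= 1; lower `edge_density`, `effect_size`, or ",
      "`autoregression`"
    ))
  }
  dimnames(B) <- list(node_labels, node_labels)
  new_truth_network(node_labels, B, stats::setNames(a, node_labels),
                    within_wave_corr, cov_eff)
}

new_truth_network <- function(node_labels, B, a, within_wave_corr, cov_eff) {
  stopifnot(all(diag(B) == 0), length(a) == length(node_labels))
  check_rate(within_wave_corr, "within_wave_corr")
  sr <- max(Mod(eigen(B + diag(a, length(a)), only.values = TRUE)$values))
  if (sr >= 1) {
    abort_clpnet(sprintf(
      "unstable truth network: spectral radius of B + diag(a) is %.3f >= 1", sr))
  }
  structure(
    list(node_labels = node_labels, B_true = B, a_true = a,
         within_wave_corr = within_wave_corr, covariate_effects = cov_eff),
    class = "truth_network"
  )
}

#' @export
print.truth_network <- function(x, ...) {
  cat(sprintf(
    "<truth_network> %d nodes, %d cross-lagged edges, a = %.2f..%.2f, rho = %.2f\n",
    length(x$node_labels), sum(x$B_true != 0),
    min(x$a_true), max(x$a_true), x$within_wave_corr))
  invisible(x)
}

#' Serialize / read a truth network as an edge-list CSV
#'
#' Cross-lagged edges are written as `from,to,weight` rows; autoregressive
#' coefficients, the within-wave correlation, and covariate loadings are
#' stored in `#`-prefixed header lines so the file round-trips exactly.
#'
#' @param truth A `truth_network`.
#' @param path Output file path.
#' @return `path`, invisibly (`write_truth_csv`); a `truth_network`
#'   (`read_truth_csv`).
#' @export
write_truth_csv <- function(truth, path) {
  stopifnot(inherits(truth, "truth_network"))
  hdr <- c(
    sprintf("# within_wave_corr %s", format(truth$within_wave_corr, digits = 17)),
    sprintf("# nodes %s", paste(truth$node_labels, collapse = " ")),
    sprintf("# a %s %s", truth$node_labels,
            vapply(truth$a_true, format, "", digits = 17)),
    sprintf("# covariate %s %s %s", truth$node_labels,
            vapply(truth$covariate_effects[, "gender"], format, "", digits = 17),
            vapply(truth$covariate_effects[, "age"], format, "", digits = 17))
  )
  idx <- which(truth$B_true != 0, arr.ind = TRUE)
  edges <- tibble::tibble(
    from = truth$node_labels[idx[, 1]],
    to = truth$node_labels[idx[, 2]],
    weight = truth$B_true[idx]
  )
  edges <- dplyr::arrange(edges, .data$from, .data$to)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("from,to,weight", con)
  if (nrow(edges)) {
    writeLines(sprintf("%s,%s,%s", edges$from, edges$to,
                       vapply(edges$weight, format, "", digits = 17)), con)
  }
  invisible(path)
}

#' @rdname write_truth_csv
#' @export
read_truth_csv <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  fields <- strsplit(sub("^# ", "", hdr), " +")
  get <- function(key) fields[vapply(fields, function(f) f[1] == key, TRUE)]
  rho <- as.numeric(get("within_wave_corr")[[1]][2])
  labels <- get("nodes")[[1]][-1]
  p <- length(labels)
  a <- stats::setNames(numeric(p), labels)
  for (f in get("a")) a[f[2]] <- as.numeric(f[3])
  cov_eff <- matrix(0, p, 2, dimnames = list(labels, c("gender", "age")))
  for (f in get("covariate")) cov_eff[f[2], ] <- as.numeric(f[3:4])
  B <- matrix(0, p, p, dimnames = list(labels, labels))
  if (length(body) > 1) {
    edges <- utils::read.csv(text = paste(body, collapse = "\n"))
    for (i in seq_len(nrow(edges))) {
      B[edges$from[i], edges$to[i]] <- edges$weight[i]
    }
  }
  new_truth_network(labels, B, a, rho, cov_eff)
}
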