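#' Generator configuration for synthetic two-wave panels
#'
#' Bundles the sampling conditions of the simulated survey. Defaults mirror
#' the screening flow of large school-based bullying surveys: roughly a
#' fifth of respondents report no victimization, a few percent fail the
#' embedded control questions, and a small fraction of wave-1 paper
#' questionnaire items are left blank.
#'
#' @param n Number of participants (before screening).
#' @param seed Integer RNG seed; the dataset is a deterministic function of
#'   `(truth, config)`.
#' @param likert_levels Per-node maximum ordinal response (responses run
#'   `0..likert_levels`). A single value is recycled; `NULL` infers 4 for
#'   ITQ-style nodes (`RE*`, `AV*`, `TH*`, `NSC*`, `AD*`, `DR*`) and 3 for
#'   `dep*`/`anx*` nodes, defaulting to 4 otherwise.
#' @param missing_rate Probability that a wave-1 item response is missing
#'   (missing completely at random; wave 2 is complete, as in an enforced
#'   online follow-up).
#' @param screen_negative_rate Fraction of participants reporting no
#'   victimization at all (screened out downstream).
#' @param control_fail_rate Fraction failing the control questions
#'   (excluded downstream as invalid responders).
#' @param discretize If `TRUE` (default) latent scores are discretized to
#'   the ordinal scale by fixed equiprobable normal quantile thresholds; if
#'   `FALSE` the continuous latent scores are emitted (useful for
#'   construct-level recovery experiments without ordinal attenuation).
#'
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n, seed = 1, likert_levels = NULL,
                             missing_rate = 0.02,
                             screen_negative_rate = 0.22,
                             control_fail_rate = 0.07,
                             discretize = TRUE) {
  if (!is_scalar_number(n) || n < 1) abort_clpnet("`n` must be >= 1")
  check_rate(missing_rate, "missing_rate")
  check_rate(screen_negative_rate, "screen_negative_rate")
  check_rate(control_fail_rate, "control_fail_rate")
  structure(
    list(n = as.integer(n), seed = as.integer(seed),
         likert_levels = likert_levels, missing_rate = missing_rate,
         screen_negative_rate = screen_negative_rate,
         control_fail_rate = control_fail_rate,
         discretize = isTRUE(discretize)),
    class = "generator_config"
  )
}

default_likert_levels <- function(node_labels) {
  vapply(node_labels, function(lbl) {
    if (grepl("^(RE|AV|TH|NSC|AD|DR)[0-9]+$", lbl)) 4L
    else if (grepl("^(dep|anx)[0-9]+$", lbl)) 3L
    else 4L
  }, integer(1))
}

#' Simulate a two-wave ordinal panel dataset
#'
#' Draws wave-1 latent scores from a correlated standard Gaussian
#' (equicorrelation `within_wave_corr`), forms wave-2 latent scores as
#' `W1 %*% (B_true + diag(a_true))` plus covariate effects and correlated
#' Gaussian noise (noise variance chosen per node so wave-2 latents have
#' approximately unit variance, keeping standardized effects on the scale of
#' the truth), then discretizes each latent score to the node's ordinal
#' range by fixed equiprobable normal quantile thresholds. Wave-1 item
#' missingness is injected completely at random; screening fields
#' (10 victimization-frequency items and a control-question flag) are
#' populated last.
#'
#' @param truth A [make_truth()] network.
#' @param config A [generator_config()].
#' @return A tibble with columns `id`, `gender` (0/1), `age` (years),
#'   `screen_v1..screen_v10`, `control_ok`, then `t1_<node>` and
#'   `t2_<node>` for every node of `truth`.
#' @export
#' @examples
#' tr <- make_truth(paste0("n", 1:4), 0.1, 0.3, 0.2, seed = 1)
#' head(simulate_panel(tr, generator_config(n = 50, seed = 2)))
simulate_panel <- function(truth, config) {
  stopifnot(inherits(truth, "truth_network"),
            inherits(config, "generator_config"))
  labels <- truth$node_labels
  p <- length(labels)
  n <- config$n
  levels_max <- config$likert_levels %||% default_likert_levels(labels)
  levels_max <- as.integer(rep_len(levels_max, p))
  if (any(levels_max < 1)) abort_clpnet("`likert_levels` must be >= 1")

  M <- truth$B_true + diag(truth$a_true, p)
  sigma1 <- equicorr(p, truth$within_wave_corr)
  signal_var <- diag(t(M) %*% sigma1 %*% M)
  cov_var <- rowSums(truth$covariate_effects^2)
  resid_sd <- sqrt(pmax(1 - signal_var - cov_var, 0.05))

  withr::with_seed(config$seed, {
    w1 <- rmvn_chol(n, sigma1)
    gender <- stats::rbinom(n, 1, 0.5)
    age <- stats::rnorm(n, 13.2, 2.0)
    # population-standardized covariates so loadings are on a z scale
    covz <- cbind(gender = (gender - 0.5) / 0.5, age = (age - 13.2) / 2.0)
    noise <- rmvn_chol(n, equicorr(p, truth$within_wave_corr))
    w2 <- w1 %*% M + covz %*% t(truth$covariate_effects) +
      sweep(noise, 2, resid_sd, `*`)

    if (config$discretize) {
      disc <- function(w, kmax) {
        thr <- stats::qnorm(seq_len(kmax) / (kmax + 1))
        findInterval(w, thr)
      }
      x1 <- vapply(seq_len(p), function(j) disc(w1[, j], levels_max[j]),
                   numeric(n))
      x2 <- vapply(seq_len(p), function(j) disc(w2[, j], levels_max[j]),
                   numeric(n))
    } else {
      x1 <- w1
      x2 <- w2
    }
    x1 <- matrix(as.numeric(x1), n, p)
    x2 <- matrix(as.numeric(x2), n, p)

    if (config$missing_rate > 0) {
      miss <- matrix(stats::runif(n * p) < config$missing_rate, n, p)
      x1[miss] <- NA_real_
    }

    # screening block: victimization frequency and control-question validity
    negative <- stats::runif(n) < config$screen_negative_rate
    screen <- matrix(stats::rbinom(n * 10, 4, 0.12), n, 10)
    none <- rowSums(screen) == 0
    fix_item <- sample.int(10, n, replace = TRUE)
    screen[cbind(which(none & !negative), fix_item[none & !negative])] <- 1L
    screen[negative, ] <- 0L
    control_ok <- stats::runif(n) >= config$control_fail_rate

    out <- tibble::tibble(id = seq_len(n), gender = gender,
                          age = round(age, 1))
    scr <- tibble::as_tibble(as.data.frame(screen))
    names(scr) <- paste0("screen_v", 1:10)
    t1 <- tibble::as_tibble(as.data.frame(x1))
    names(t1) <- paste0("t1_", labels)
    t2 <- tibble::as_tibble(as.data.frame(x2))
    names(t2) <- paste0("t2_", labels)
    dplyr::bind_cols(out, scr, tibble::tibble(control_ok = control_ok), t1, t2)
  })
}

#' Read / write panel datasets as CSV
#'
#' The on-disk dialect is one row per participant with columns
#' `id, gender, age, screen_v1..screen_v10, control_ok, t1_<node>...,
#' t2_<node>...`; missing responses are empty cells.
#'
#' @param data A panel tibble as produced by [simulate_panel()].
#' @param path File path.
#' @return `path` invisibly (`write_panel_csv`); a tibble (`read_panel_csv`).
#' @export
write_panel_csv <- function(data, path) {
  readr::write_csv(data, path, na = "")
  invisible(path)
}

#' @rdname write_panel_csv
#' @export
read_panel_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
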