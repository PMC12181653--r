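# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_clpnet <- function(msg, class = "clpnet_error") {
  rlang::abort(msg, class = class)
}

# Equicorrelation matrix: unit diagonal, rho elsewhere.
equicorr <- function(p, rho) {
  stopifnot(p >= 1, rho >= 0, rho < 1)
  m <- matrix(rho, p, p)
  diag(m) <- 1
  m
}

# Multivariate normal draw via Cholesky; consumes n*p normals in column order.
rmvn_chol <- function(n, sigma) {
  p <- ncol(sigma)
  z <- matrix(stats::rnorm(n * p), n, p)
  z %*% chol(sigma)
}

# Deterministic per-stage seed derived from the pipeline seed and a stage
# name, kept below 2^31 so it is a valid R integer seed.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

# Polynomial rolling hash of a character scalar, reported as hex (used to
# fingerprint pipeline configs in the output manifest).
config_hash <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# Node labels shared by the two waves of a panel tibble. Errors if the
# wave-1 and wave-2 item sets differ.
panel_nodes <- function(data) {
  t1 <- sub("^t1_", "", grep("^t1_", names(data), value = TRUE))
  t2 <- sub("^t2_", "", grep("^t2_", names(data), value = TRUE))
  if (length(t1) == 0L) {
    abort_clpnet("no wave-1 item columns (expected columns named 't1_<node>')")
  }
  if (!setequal(t1, t2)) {
    missing1 <- setdiff(t2, t1)
    missing2 <- setdiff(t1, t2)
    abort_clpnet(paste0(
      "node-set mismatch between waves: ",
      if (length(missing2)) paste0("missing at wave 2: ",
                                   paste(missing2, collapse = ", ")) else "",
      if (length(missing1)) paste0(" missing at wave 1: ",
                                   paste(missing1, collapse = ", ")) else ""
    ))
  }
  t1
}

# Column-standardize a matrix (denominator n - 1), erroring on zero
# variance with the offending label in the message.
zscore_matrix <- function(x, what = "column") {
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  bad <- which(!is.finite(sdv) | sdv == 0)
  if (length(bad)) {
    abort_clpnet(sprintf("zero-variance %s: %s", what,
                         paste(colnames(x)[bad], collapse = ", ")))
  }
  scale(x, center = mu, scale = sdv)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_rate <- function(x, name) {
  if (!is_scalar_number(x) || x < 0 || x >= 1) {
    abort_clpnet(sprintf("`%s` must be a single value in [0, 1), got %s",
                         name, paste(x, collapse = ", ")))
  }
  x
}
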