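#' Screen participants by victimization exposure and response validity
#'
#' Keeps participants who (a) report victimization at least once — any
#' screening item strictly above the scale's "never" anchor — and (b)
#' answered the control questions correctly (`control_ok`). Row order is
#' preserved. The screening tally (input count, victimized count, invalid
#' exclusions, final count, kept ids) is attached to the result and
#' retrievable with [screening_summary()].
#'
#' @param data Panel tibble with `screen_v*` columns and a logical
#'   `control_ok` column.
#' @param never_value The scale's "never" anchor: 0 for the 0-4 adolescent
#'   screen (default), 1 for the 1-6 emerging-adult screen.
#' @return The screened tibble, with a `screening` attribute.
#' @export
#' @examples
#' tr <- make_truth(paste0("n", 1:3), 0, 0.3, 0.2, seed = 1)
#' d <- simulate_panel(tr, generator_config(n = 100, seed = 1))
#' screening_summary(screen_participants(d))
screen_participants <- function(data, never_value = 0) {
  screen_cols <- grep("^screen_v", names(data), value = TRUE)
  if (length(screen_cols) == 0L || !"control_ok" %in% names(data)) {
    abort_clpnet("missing screening columns (`screen_v*`, `control_ok`)")
  }
  sm <- as.matrix(data[screen_cols])
  victimized <- rowSums(sm > never_value, na.rm = TRUE) > 0
  valid <- as.logical(data$control_ok)
  keep <- victimized & valid
  out <- data[keep, , drop = FALSE]
  summary <- structure(
    list(n_input = nrow(data),
         n_victimized = sum(victimized),
         n_excluded_invalid = sum(victimized & !valid),
         n_final = sum(keep),
         kept_ids = data$id[keep]),
    class = "screening_result"
  )
  attr(out, "screening") <- summary
  out
}

#' @rdname screen_participants
#' @param x A tibble returned by [screen_participants()].
#' @export
screening_summary <- function(x) {
  s <- attr(x, "screening")
  if (is.null(s)) abort_clpnet("no screening summary attached; run screen_participants() first")
  s
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf(
    "<screening> %d assessed; %d victimized at least once; %d excluded (control questions); %d retained\n",
    x$n_input, x$n_victimized, x$n_excluded_invalid, x$n_final))
  invisible(x)
}

#' Mean-impute missing item responses
#'
#' Replaces each missing item cell by the arithmetic mean of that item's
#' observed values across participants (series mean). Imputed values are
#' deliberately not rounded back to the ordinal grid: downstream regressions
#' treat responses as numeric and unrounded imputation preserves each item's
#' observed mean exactly. Apply after screening so invalid responders do not
#' contaminate the item means.
#'
#' @param data Panel tibble; imputation applies to `t1_*`/`t2_*` columns.
#' @return The tibble with no missing item responses.
#' @export
impute_missing <- function(data) {
  item_cols <- grep("^t[12]_", names(data), value = TRUE)
  for (col in item_cols) {
    v <- data[[col]]
    if (anyNA(v)) {
      obs <- v[!is.na(v)]
      if (length(obs) == 0L) {
        abort_clpnet(sprintf("item column `%s` is entirely missing", col))
      }
      v[is.na(v)] <- mean(obs)
      data[[col]] <- v
    }
  }
  data
}

#' Composite (sum) scores for an instrument
#'
#' Sums item responses into a total score, plus one total per declared
#' subscale. Waved items (`t1_<item>`, `t2_<item>`) are scored per wave
#' with a `_t1`/`_t2` suffix; unwaved items (e.g. the victimization screens)
#' are scored once.
#'
#' @param data Panel tibble with no missing item responses (see
#'   [impute_missing()]).
#' @param instrument An [instrument_spec()].
#' @return A tibble with `id` plus total and subscale-score columns named
#'   `<instrument>[_<subscale>][_t1|_t2]`.
#' @export
#' @examples
#' tr <- make_truth(symptom_nodes(), 0.02, 0.2, 0.2, seed = 1)
#' d <- simulate_panel(tr, generator_config(200, seed = 1, missing_rate = 0))
#' head(composite_scores(d, default_instruments()$phq9))
composite_scores <- function(data, instrument) {
  if (!inherits(instrument, "instrument_spec")) {
    abort_clpnet("`instrument` must be an instrument_spec (see default_instruments())")
  }
  out <- tibble::tibble(id = data$id %||% seq_len(nrow(data)))
  score_block <- function(cols, suffix) {
    m <- as.matrix(data[cols])
    if (anyNA(m)) {
      abort_clpnet(sprintf("missing responses in %s items; impute first",
                           instrument$name))
    }
    if (any(m < instrument$response_min - 1e-9) ||
        any(m > instrument$response_max + 1e-9)) {
      abort_clpnet(sprintf("out-of-range responses for %s (allowed %d-%d)",
                           instrument$name, instrument$response_min,
                           instrument$response_max))
    }
    out[[paste0(instrument$name, suffix)]] <<- rowSums(m)
    for (sub in names(instrument$subscales)) {
      sub_cols <- cols[match(instrument$subscales[[sub]], instrument$items)]
      out[[paste0(instrument$name, "_", sub, suffix)]] <<-
        rowSums(as.matrix(data[sub_cols]))
    }
  }
  scored <- FALSE
  for (wave in c("t1", "t2")) {
    cols <- paste0(wave, "_", instrument$items)
    if (all(cols %in% names(data))) {
      score_block(cols, paste0("_", wave))
      scored <- TRUE
    }
  }
  if (!scored && all(instrument$items %in% names(data))) {
    score_block(instrument$items, "")
    scored <- TRUE
  }
  if (!scored) {
    abort_clpnet(sprintf("columns for instrument `%s` not found",
                         instrument$name))
  }
  out
}

#' Construct-level composite scores for the path model
#'
#' Convenience wrapper scoring the three built-in symptom instruments into
#' the CPTSD, depression, and anxiety composites used by
#' [fit_path_model()], carrying the covariates along.
#'
#' @param data Screened, imputed panel tibble with the 28 symptom columns.
#' @return Tibble with `id`, `gender`, `age`, `cptsd_t1`, `cptsd_t2`,
#'   `dep_t1`, `dep_t2`, `anx_t1`, `anx_t2`.
#' @export
construct_scores <- function(data) {
  ins <- default_instruments()
  scores <- list(
    cptsd = composite_scores(data, ins$itq),
    dep = composite_scores(data, ins$phq9),
    anx = composite_scores(data, ins$gad7)
  )
  out <- tibble::tibble(
    id = data$id %||% seq_len(nrow(data)),
    gender = data$gender, age = data$age,
    cptsd_t1 = scores$cptsd$itq_t1, cptsd_t2 = scores$cptsd$itq_t2,
    dep_t1 = scores$dep$phq9_t1, dep_t2 = scores$dep$phq9_t2,
    anx_t1 = scores$anx$gad7_t1, anx_t2 = scores$anx$gad7_t2
  )
  out
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability
#' `alpha = k/(k-1) * (1 - sum(item variances) / variance of total)`,
#' with sample variances (denominator `n - 1`).
#'
#' @param items A numeric matrix or data frame, participants in rows, items
#'   in columns; at least 2 items and 2 participants.
#' @return A single numeric value.
#' @export
#' @examples
#' cronbach_alpha(cbind(a = c(1, 2, 3), b = c(1, 2, 3)))
cronbach_alpha <- function(items) {
  m <- as.matrix(items)
  if (ncol(m) < 2L) abort_clpnet("need at least 2 items")
  if (nrow(m) < 2L) abort_clpnet("need at least 2 participants")
  if (anyNA(m)) abort_clpnet("missing values; impute first")
  total_var <- stats::var(rowSums(m))
  if (total_var <= 0) abort_clpnet("zero total-score variance")
  k <- ncol(m)
  k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / total_var)
}
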