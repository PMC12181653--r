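#' Configure an end-to-end analysis run
#'
#' A pipeline config names either an input CSV (the panel dialect of
#' [write_panel_csv()]) or a simulation block (truth network plus generator
#' config), the estimator and bootstrap settings, the output directory,
#' the display threshold, and one global seed from which per-stage seeds
#' are derived deterministically by stage-name hashing.
#'
#' @param input Path to a panel CSV, or `NULL` when simulating.
#' @param simulation A list `list(truth = <truth_network>,
#'   config = <generator_config>)`, or `NULL` when reading `input`.
#'   Exactly one of `input`/`simulation` must be given.
#' @param out_dir Output directory (created if needed).
#' @param seed Global integer seed.
#' @param settings An [estimator_settings()]; its `seed` is overridden by
#'   the derived stage seed.
#' @param n_boot Edge-bootstrap resamples (0 skips the edge bootstrap).
#' @param case_drop_n_boot Subsamples per case-drop proportion (0 skips
#'   the stability stage).
#' @param proportions Case-drop proportion grid.
#' @param threshold Display threshold for the exported edge list.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, simulation = NULL, out_dir,
                            seed = 1, settings = estimator_settings(),
                            n_boot = 200, case_drop_n_boot = 25,
                            proportions = c(0.1, 0.3, 0.5, 0.75),
                            threshold = 0.05) {
  if (is.null(input) == is.null(simulation)) {
    abort_clpnet("exactly one of `input` or `simulation` must be given")
  }
  if (!is.null(simulation)) {
    stopifnot(inherits(simulation$truth, "truth_network"),
              inherits(simulation$config, "generator_config"))
  }
  structure(
    list(input = input, simulation = simulation, out_dir = out_dir,
         seed = as.integer(seed), settings = settings, n_boot = n_boot,
         case_drop_n_boot = case_drop_n_boot, proportions = proportions,
         threshold = threshold),
    class = "pipeline_config"
  )
}

#' Read a pipeline config from YAML
#'
#' The file mirrors [pipeline_config()]: top-level keys `input` or
#' `simulation` (with `truth:` — `node_labels`, `edge_density`,
#' `effect_size`, `autoregression`, `truth_seed`, and optional
#' `within_wave_corr`, `covariate_effects` — and `config:` — `n` plus any
#' [generator_config()] rates), `out_dir`, `seed`, `estimator`,
#' `bootstrap` (`n_boot`, `case_drop_n_boot`, `proportions`), `threshold`.
#'
#' @param path YAML file path.
#' @param out_dir Optional override of the configured output directory.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  est <- do.call(estimator_settings, y$estimator %||% list())
  sim <- NULL
  if (!is.null(y$simulation)) {
    tr <- y$simulation$truth
    labels <- tr$node_labels %||% symptom_nodes()
    if (identical(labels, "symptom_nodes")) labels <- symptom_nodes()
    truth <- make_truth(
      labels, edge_density = tr$edge_density, effect_size = tr$effect_size,
      autoregression = tr$autoregression, seed = tr$truth_seed %||% 1,
      within_wave_corr = tr$within_wave_corr %||% 0.3,
      covariate_effects = tr$covariate_effects %||% 0.1
    )
    gc_args <- y$simulation$config
    # YAML 1.1 reads a bare `n:` key as boolean FALSE; map it back
    names(gc_args)[names(gc_args) == "FALSE"] <- "n"
    sim <- list(truth = truth, config = do.call(generator_config, gc_args))
  }
  boot <- y$bootstrap %||% list()
  pipeline_config(
    input = y$input, simulation = sim,
    out_dir = out_dir %||% y$out_dir %||% ".",
    seed = y$seed %||% 1, settings = est,
    n_boot = boot$n_boot %||% 200,
    case_drop_n_boot = boot$case_drop_n_boot %||% 25,
    proportions = unlist(boot$proportions) %||% c(0.1, 0.3, 0.5, 0.75),
    threshold = y$threshold %||% 0.05
  )
}

#' Run the full two-level analysis pipeline
#'
#' Executes, in order: simulate (or read) the panel, screen, impute,
#' composite scoring and the construct-level path model (when the full
#' 28-symptom node set is present), then standardize, CLPN estimation,
#' expected-influence centralities, and the bootstrap stability stages.
#' All tabular artifacts are written as CSV under `config$out_dir`,
#' together with a `manifest.yaml` recording the config hash and seed and a
#' line-oriented `log.txt` (timestamps live only in the log, so data
#' outputs are byte-identical across reruns with the same config and
#' seed).
#'
#' @param config A [pipeline_config()] or the path to a YAML config.
#' @return Invisibly, a list with the fitted objects and artifact paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  log_lines <- character()
  t0 <- Sys.time()
  note <- function(stage, msg) {
    line <- sprintf("[%s] %-10s %s",
                    format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage, msg)
    log_lines <<- c(log_lines, line)
  }
  artifacts <- list()

  # --- data ---------------------------------------------------------------
  if (!is.null(config$simulation)) {
    sim_cfg <- config$simulation$config
    sim_cfg$seed <- stage_seed(config$seed, "simulate")
    data <- simulate_panel(config$simulation$truth, sim_cfg)
    write_panel_csv(data, out("dataset.csv"))
    write_truth_csv(config$simulation$truth, out("truth_edges.csv"))
    artifacts$dataset <- out("dataset.csv")
    note("simulate", sprintf("n = %d, %d nodes", nrow(data),
                             length(panel_nodes(data))))
  } else {
    data <- read_panel_csv(config$input)
    note("load", sprintf("%s: n = %d", config$input, nrow(data)))
  }

  # --- screen + impute ----------------------------------------------------
  screened <- screen_participants(data)
  scr <- screening_summary(screened)
  readr::write_csv(tibble::tibble(
    n_input = scr$n_input, n_victimized = scr$n_victimized,
    n_excluded_invalid = scr$n_excluded_invalid, n_final = scr$n_final
  ), out("screening.csv"))
  artifacts$screening <- out("screening.csv")
  note("screen", sprintf("%d -> %d participants", scr$n_input, scr$n_final))
  clean <- impute_missing(screened)
  note("impute", "item-mean imputation of missing responses")

  # --- construct-level path model (28-symptom panels only) ----------------
  panel_fit <- NULL
  if (all(paste0("t1_", symptom_nodes()) %in% names(clean))) {
    scores <- construct_scores(clean)
    readr::write_csv(scores, out("construct_scores.csv"))
    panel_fit <- fit_path_model(scores)
    readr::write_csv(tidy(panel_fit), out("path_model.csv"))
    readr::write_csv(glance(panel_fit), out("path_model_fit.csv"))
    readr::write_csv(evaluate_fit(panel_fit), out("path_model_fit_labels.csv"))
    artifacts$path_model <- out("path_model.csv")
    note("panel", sprintf("chisq(%d) = %.3f", panel_fit$fit$df,
                          panel_fit$fit$chisq))
  } else {
    note("panel", "skipped: panel does not carry the 28-symptom node set")
  }

  # --- CLPN ---------------------------------------------------------------
  est <- config$settings
  est$seed <- stage_seed(config$seed, "clpn")
  network <- estimate_network(clean, est)
  write_network_csv(network, out("network_full.csv"), threshold = 0)
  edges <- threshold_for_display(network, config$threshold)
  readr::write_csv(edges, out("edges.csv"))
  write_network_graphml(network, out("network.graphml"), config$threshold)
  artifacts$edges <- out("edges.csv")
  note("clpn", sprintf("%d non-zero edges, %d displayed at |w| >= %.2f",
                       sum(network$B != 0), nrow(edges), config$threshold))

  centrality <- expected_influence(network)
  readr::write_csv(centrality, out("centrality.csv"))
  artifacts$centrality <- out("centrality.csv")
  note("centrality", sprintf("max Out-EI at %s",
                             centrality$node[which.max(centrality$out_ei)]))

  # --- stability ----------------------------------------------------------
  eboot <- NULL
  if (config$n_boot >= 2) {
    eboot <- bootstrap_edges(clean, est, n_boot = config$n_boot,
                             seed = stage_seed(config$seed, "edgeboot"))
    readr::write_csv(eboot$edges, out("edge_ci.csv"))
    artifacts$edge_ci <- out("edge_ci.csv")
    note("edgeboot", sprintf("%d resamples, %d failed", config$n_boot,
                             eboot$n_failed))
  }
  stability <- list()
  if (config$case_drop_n_boot >= 1) {
    cs_rows <- list()
    for (idx in c("in_ei", "out_ei")) {
      cd <- case_drop_bootstrap(clean, est, index = idx,
                                proportions = config$proportions,
                                n_boot = config$case_drop_n_boot,
                                seed = stage_seed(config$seed,
                                                  paste0("casedrop_", idx)))
      readr::write_csv(cd$correlations,
                       out(sprintf("stability_curve_%s.csv", idx)))
      cs <- cs_coefficient(cd)
      cs_rows[[idx]] <- tibble::tibble(index = idx, cs = cs,
                                       label = cs_label(cs))
      stability[[idx]] <- cd
    }
    readr::write_csv(dplyr::bind_rows(cs_rows), out("cs_coefficients.csv"))
    artifacts$cs <- out("cs_coefficients.csv")
    note("stability", paste(vapply(cs_rows, function(r)
      sprintf("CS(%s) = %.2f", r$index, r$cs), ""), collapse = ", "))
  }

  # --- manifest + log -----------------------------------------------------
  cfg_core <- config
  cfg_core$out_dir <- NULL  # fingerprint the analysis, not its destination
  cfg_repr <- paste(utils::capture.output(utils::str(cfg_core)), collapse = "\n")
  yaml::write_yaml(list(
    seed = config$seed,
    config_hash = config_hash(cfg_repr),
    threshold = config$threshold,
    n_boot = config$n_boot,
    package_version = as.character(utils::packageVersion("clpnet"))
  ), out("manifest.yaml"))
  note("done", sprintf("elapsed %.1fs",
                       as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  writeLines(log_lines, out("log.txt"))
  invisible(list(data = clean, screening = scr, network = network,
                 centrality = centrality, panel_model = panel_fit,
                 edge_boot = eboot, stability = stability,
                 artifacts = artifacts, out_dir = config$out_dir))
}
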