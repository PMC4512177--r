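#' Run configuration
#'
#' One structure holding everything a run needs: the protocol, the
#' generative model, the cohort composition, the analysis parameters
#' (windows, thresholds, bin width, smoothing) and the master seed. Every
#' parameter defaults to the values of the source experiment. Round-trips
#' losslessly through [write_run_config()] / [read_run_config()].
#'
#' @param protocol [protocol_config()] arguments as a list.
#' @param simulation [simulation_config()] arguments as a list.
#' @param groups Cohort groups (see [cohort_spec()]).
#' @param analysis List of analysis parameters: `window_paired_ms`,
#'   `window_cs_only_ms`, `bin_width`, `cr_threshold`, `smooth_width_ms`,
#'   `exclude_early_movement`, `zero_bin`, `normalization`.
#' @param phases Phases to simulate/analyze.
#' @param seed Master seed (mandatory for simulation).
#' @return A list of class `run_config`.
#' @export
run_config <- function(protocol = list(), simulation = list(),
                       groups = list(list(label = "WT", n_subjects = 2),
                                     list(label = "MUT", n_subjects = 2,
                                          config = list(p_max = 0.35))),
                       analysis = list(),
                       phases = c("acquisition", "extinction",
                                  "reacquisition"),
                       seed = 1L) {
  analysis_defaults <- list(
    window_paired_ms = c(100, 250), window_cs_only_ms = c(100, 280),
    bin_width = 0.025, cr_threshold = 0.15, smooth_width_ms = 10,
    exclude_early_movement = FALSE, zero_bin = "nonresponse",
    normalization = "per_trial")
  cfg <- list(protocol = protocol, simulation = simulation, groups = groups,
              analysis = utils::modifyList(analysis_defaults, analysis),
              phases = phases, seed = as.integer(seed))
  # validate by construction
  do.call(protocol_config, cfg$protocol)
  do.call(simulation_config, cfg$simulation)
  structure(cfg, class = "run_config")
}

#' Write / read a run configuration
#'
#' Human-readable YAML serialization of a [run_config()].
#'
#' @param config A `run_config`.
#' @param path File path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` returns the `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  keep <- intersect(c("protocol", "simulation", "groups", "analysis",
                      "phases", "seed"), names(raw))
  do.call(run_config, raw[keep])
}

#' Run the full analysis pipeline
#'
#' Simulate (or accept) a cohort, normalize, decompose every session,
#' extract per-trial response metrics, and run the group statistics.
#' Deterministic given `config$seed`. Per-stage trial accounting (how many
#' trials went in, how many were excluded and why) is reported via
#' `message()`.
#'
#' @param config A [run_config()].
#' @param cohort Optional pre-built `eyeblink_cohort`; when NULL one is
#'   simulated from the config.
#' @param out_dir Optional directory; when given, the metrics and timing
#'   tables are written there as tab-separated text with a `# schema: 1`
#'   header.
#' @return A list of class `eyeblink_run`: `metrics` (per-session),
#'   `timing` (per-trial), `stats` (list of group comparisons), `cohort`,
#'   `config`.
#' @export
run_pipeline <- function(config = run_config(), cohort = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  protocol <- do.call(protocol_config, config$protocol)
  sim_cfg <- do.call(simulation_config, config$simulation)
  if (is.null(cohort)) {
    spec <- cohort_spec(config$groups, protocol, sim_cfg,
                        master_seed = config$seed)
    cohort <- simulate_cohort(spec, phases = config$phases)
  }
  check_trial_table(cohort$trials)
  message(sprintf("simulate: %d trials from %d subjects",
                  nrow(cohort$trials), length(unique(cohort$trials$subject))))

  an <- config$analysis
  cohort <- normalize_cohort(cohort, normalization = an$normalization)
  n_invalid <- sum(!cohort$trials$valid)
  message(sprintf("preprocess: %d trials excluded (%s)", n_invalid,
                  paste(names(table(droplevels(
                    cohort$trials$exclusion_reason[!cohort$trials$valid]))),
                    collapse = ", ")))

  metrics <- decompose_cohort(
    cohort, window_paired_ms = an$window_paired_ms,
    window_cs_only_ms = an$window_cs_only_ms, bin_width = an$bin_width,
    cr_threshold = an$cr_threshold, smooth_width_ms = an$smooth_width_ms,
    exclude_early_movement = an$exclude_early_movement,
    zero_bin = an$zero_bin)
  message(sprintf("decomposition: %d session rows", nrow(metrics)))

  timing <- trial_response_metrics(cohort, an$smooth_width_ms)
  message(sprintf("response metrics: %d CR-scored trials",
                  sum(timing$status == "cr", na.rm = TRUE)))

  curves <- build_learning_curves(metrics)
  stats_out <- list()
  if (length(unique(metrics$group)) >= 2 &&
      "acquisition" %in% as.character(metrics$phase)) {
    acq <- dplyr::filter(curves, .data$phase == "acquisition")
    if (length(unique(acq$session)) >= 2)
      stats_out$rm_anova_probability <- rm_anova_2way(acq, "probability")
    lf <- last_four_mean(curves, "acquisition",
                         n_last = min(4L, max(acq$session)))
    gs <- split(lf$probability, lf$group)
    if (length(gs) == 2 && all(lengths(gs) >= 2)) {
      tt <- stats::t.test(gs[[1]], gs[[2]], var.equal = TRUE)
      stats_out$last_four_t <- tibble::tibble(
        effect = paste(names(gs), collapse = " vs "),
        df1 = NA_real_, df2 = unname(tt$parameter),
        statistic = unname(tt$statistic), p_value = tt$p.value,
        cohens_d = cohens_dprime(gs[[1]], gs[[2]]))
    }
    stats_out$last_four <- lf
  }
  if (all(c("extinction", "reacquisition") %in%
          as.character(metrics$phase))) {
    stats_out$savings <- savings_summary(curves)
  }

  result <- structure(list(metrics = metrics, timing = timing,
                           stats = stats_out, cohort = cohort,
                           config = config),
                      class = "eyeblink_run")
  if (!is.null(out_dir)) export_run(result, out_dir)
  result
}

required_trial_columns <- c("subject", "group", "phase", "session", "block",
                            "trial", "kind", "cs_onset_ms", "us_onset_ms")

check_trial_table <- function(trials) {
  missing <- setdiff(required_trial_columns, names(trials))
  if (length(missing))
    stopf("trial table is missing required column(s): %s",
          paste(missing, collapse = ", "))
  invisible(trials)
}

config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(unclass(config))),
             collapse = "\n")
  sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 977)) %% 1e9
}

export_run <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- sprintf("# schema: 1\n# config_hash: %d\n# seed: %d",
                 config_hash(result$config), result$config$seed)
  write_table <- function(df, file) {
    path <- file.path(out_dir, file)
    writeLines(hdr, path)
    suppressWarnings(utils::write.table(
      df, path, append = TRUE, sep = "\t", row.names = FALSE,
      quote = FALSE, na = ""))
    path
  }
  write_table(result$metrics, "session_metrics.tsv")
  write_table(result$timing, "trial_timing.tsv")
  invisible(out_dir)
}

#' Read a metrics/timing table written by [run_pipeline()]
#'
#' @param path File path of a `# schema: 1` tab-separated table.
#' @return A tibble.
#' @export
read_metrics_table <- function(path) {
  tibble::as_tibble(utils::read.delim(path, comment.char = "#",
                                      stringsAsFactors = FALSE))
}
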