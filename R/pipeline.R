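# End-to-end pipeline: fixtures -> simulation -> analysis -> report.
# These functions (plus the thin command-line script in inst/cli) are the
# package's batch interface.

#' Generate a stimulus fixtures directory
#'
#' Writes the direction sequence described by a configuration (frames as CSV
#' plus a JSON manifest) deterministically from the config seed.
#'
#' @param config An [experiment_config()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
make_fixtures <- function(config, dir) {
  seq <- config_sequence(config)
  write_direction_sequence(seq, dir)
}

#' Run the configured experiment
#'
#' Builds the network and parameters from the config, loads the stimulus from
#' `stimulus_dir` (or generates it in memory if `NULL`) and runs the full
#' direction sweep. If `out_dir` is given, writes `rasters.csv` (columns
#' `step`, `unit_id`, `time_ms`), a per-step `decisions.log` emulating the
#' LED readout (one line per step: step, true direction, subpopulation rates,
#' decision), and `results_meta.json` (labels, directions, step duration).
#'
#' @param config An [experiment_config()].
#' @param stimulus_dir Optional fixtures directory from [make_fixtures()].
#' @param out_dir Optional results directory.
#' @return The `stp_experiment`, invisibly if `out_dir` is given.
#' @export
simulate_experiment <- function(config, stimulus_dir = NULL, out_dir = NULL) {
  seq <- if (is.null(stimulus_dir)) {
    config_sequence(config)
  } else {
    read_direction_sequence(stimulus_dir)
  }
  ex <- run_experiment(
    config_net(config), config_lif(config), config_stp(config), seq,
    use_post_jump_u = config$flags$use_post_jump_u,
    recurrent_spikes = config$flags$recurrent_spikes,
    carry_over_state = config$flags$carry_over_state)
  if (is.null(out_dir)) return(ex)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_rasters_csv(ex, file.path(out_dir, "rasters.csv"))
  dec <- step_decisions(ex)
  writeLines(sprintf(
    "step %3d | direction %-5s | subpop1 %6.2f spk/s | subpop2 %6.2f spk/s | decision %s",
    dec$step, dec$direction, dec$rate_subpop1, dec$rate_subpop2, dec$decision),
    file.path(out_dir, "decisions.log"))
  jsonlite::write_json(
    list(labels = ex$net$labels, directions = ex$directions,
         step_duration = ex$step_duration, n_units = nrow(ex$net$w)),
    file.path(out_dir, "results_meta.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(ex)
}

#' Write / read experiment rasters as CSV
#'
#' One row per spike: `step`, `unit_id`, `time_ms` (time within the step).
#'
#' @param experiment An `stp_experiment`.
#' @param path CSV path.
#' @return `path` (writer); the reader returns a list of per-step rasters.
#' @export
write_rasters_csv <- function(experiment, path) {
  rows <- lapply(experiment$steps, function(s) {
    n <- vapply(s$raster, length, integer(1))
    data.frame(step = rep(s$step_index, sum(n)),
               unit_id = rep(seq_along(s$raster), n),
               time_ms = unlist(s$raster))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a results directory back into an `stp_experiment`-like object
#'
#' Reconstructs rasters and metadata written by [simulate_experiment()] so the
#' analysis functions can run on stored results. Traces are not stored, so
#' only raster-based analyses are available.
#'
#' @param results_dir Directory with `rasters.csv` and `results_meta.json`.
#' @return An object usable by [experiment_scc()], [step_decisions()] and
#'   [direction_rates()].
#' @export
read_results <- function(results_dir) {
  meta_path <- file.path(results_dir, "results_meta.json")
  raster_path <- file.path(results_dir, "rasters.csv")
  if (!file.exists(meta_path) || !file.exists(raster_path)) {
    stopf("`%s` does not contain rasters.csv and results_meta.json", results_dir)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  df <- utils::read.csv(raster_path)
  n_steps <- length(meta$directions)
  steps <- lapply(seq_len(n_steps), function(s) {
    sub <- df[df$step == s, ]
    raster <- lapply(seq_len(meta$n_units), function(u) {
      sort(sub$time_ms[sub$unit_id == u])
    })
    list(raster = raster, counts = vapply(raster, length, integer(1)),
         direction = meta$directions[s], step_index = s)
  })
  structure(list(steps = steps,
                 net = list(labels = meta$labels,
                            w = matrix(NA, meta$n_units, meta$n_units)),
                 directions = meta$directions,
                 step_duration = meta$step_duration),
            class = "stp_experiment")
}

#' Analyze an experiment and assemble the report
#'
#' Computes the direction-selectivity summary (mean subpopulation rates per
#' direction), the per-step decision accuracy, the spike-count-correlation
#' matrix with within/between means, and the resource summary when synaptic
#' traces are available. If `out_dir` is given, writes `report.json`,
#' `scc.csv` and `rates.csv`.
#'
#' @param x An `stp_experiment` or a results directory path.
#' @param out_dir Optional output directory.
#' @param bin_width SCC bin width, ms.
#' @param window Rate window, ms (default: full step).
#' @return The report, a list.
#' @export
analyze_results <- function(x, out_dir = NULL, bin_width = 1, window = NULL) {
  ex <- if (is.character(x)) read_results(x) else x
  stopifnot(inherits(ex, "stp_experiment"))
  dec <- step_decisions(ex, window)
  scc <- experiment_scc(ex, bin_width = bin_width)
  report <- list(
    n_steps = length(ex$steps),
    direction_rates = direction_rates(ex, window),
    decision_accuracy = mean(dec$correct, na.rm = TRUE),
    decisions = dec,
    scc_mean_within = scc$mean_within,
    scc_mean_between = scc$mean_between,
    scc = scc
  )
  if (!is.null(ex$steps[[1]]$mean_x)) {
    report$resources <- resource_summary(ex)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(as.data.frame(scc$r), file.path(out_dir, "scc.csv"),
                     row.names = FALSE)
    utils::write.csv(report$direction_rates, file.path(out_dir, "rates.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(n_steps = report$n_steps,
           decision_accuracy = report$decision_accuracy,
           scc_mean_within = report$scc_mean_within,
           scc_mean_between = report$scc_mean_between,
           direction_rates = report$direction_rates),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  report
}

#' Run the complete pipeline
#'
#' Fixture generation, simulation and analysis in one call, with all
#' artifacts written under `dir` (`stimulus/`, `results/`, `report/`).
#'
#' @param config An [experiment_config()].
#' @param dir Working directory for the artifacts.
#' @return The report from [analyze_results()], invisibly.
#' @export
run_pipeline <- function(config, dir) {
  stim_dir <- file.path(dir, "stimulus")
  res_dir <- file.path(dir, "results")
  rep_dir <- file.path(dir, "report")
  make_fixtures(config, stim_dir)
  ex <- simulate_experiment(config, stim_dir, res_dir)
  invisible(analyze_results(ex, rep_dir))
}
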