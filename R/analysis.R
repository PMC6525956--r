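#' Firing rates over a response window
#'
#' Computes each unit's firing rate as the spike count inside the half-open
#' window `[start, end)` divided by the window length, in spikes/s, plus the
#' arithmetic mean rate of each subpopulation. The window supports the
#' onset-skip convention used for evoked cortical responses (discard the
#' initial transient, e.g. window `(280, 1280)` of a 1280-ms trial, so that
#' rates are estimated after stimulus onset has quenched response
#' variability).
#'
#' @param raster List of per-unit spike-time vectors (ms).
#' @param window Numeric pair `(start, end)` in ms, `end > start`.
#' @param labels Integer subpopulation labels (1 or 2) per unit; optional.
#' @return A `rate_summary`: list with `per_unit_rate` (spikes/s),
#'   `per_subpop_rate` (named numeric, if labels given), `window` and
#'   `labels`.
#' @examples
#' firing_rate(list(c(10, 500, 900), numeric(0)), window = c(0, 1000),
#'             labels = c(1, 2))
#' @export
firing_rate <- function(raster, window, labels = NULL) {
  if (length(window) != 2 || !is.numeric(window)) {
    stopf("`window` must be a numeric pair (start, end) in ms")
  }
  if (window[2] <= window[1]) stopf("`window` must satisfy end > start")
  len_s <- (window[2] - window[1]) / 1000
  rates <- vapply(raster, function(t) {
    sum(t >= window[1] & t < window[2]) / len_s
  }, numeric(1))
  per_subpop <- NULL
  if (!is.null(labels)) {
    if (length(labels) != length(raster)) {
      stopf("`labels` must have one entry per unit")
    }
    per_subpop <- vapply(sort(unique(labels)), function(l) {
      mean(rates[labels == l])
    }, numeric(1))
    names(per_subpop) <- paste0("subpop", sort(unique(labels)))
  }
  structure(list(per_unit_rate = rates, per_subpop_rate = per_subpop,
                 window = window, labels = labels),
            class = "rate_summary")
}

#' @export
print.rate_summary <- function(x, ...) {
  cat(sprintf("Firing rates over [%g, %g) ms:\n", x$window[1], x$window[2]))
  cat("  per unit (spikes/s):", paste(signif(x$per_unit_rate, 4), collapse = ", "), "\n")
  if (!is.null(x$per_subpop_rate)) {
    cat("  per subpopulation:",
        paste(names(x$per_subpop_rate), signif(x$per_subpop_rate, 4),
              sep = " = ", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Direction decision from subpopulation rates
#'
#' The LED-style readout: `"right"` if the subpopulation-1 mean rate exceeds
#' the subpopulation-2 mean rate (red LED), `"left"` if the reverse holds
#' (blue LED), `"undecided"` on an exact tie.
#'
#' @param rates A `rate_summary` with both subpopulation means, or a numeric
#'   pair `(subpop1, subpop2)`.
#' @return `"right"`, `"left"` or `"undecided"`.
#' @examples
#' decide_direction(c(10, 5))
#' decide_direction(c(7, 7))
#' @export
decide_direction <- function(rates) {
  if (inherits(rates, "rate_summary")) {
    if (is.null(rates$per_subpop_rate) || length(rates$per_subpop_rate) != 2) {
      stopf("`rates` must contain both subpopulation means")
    }
    rates <- rates$per_subpop_rate
  }
  if (length(rates) != 2 || anyNA(rates)) {
    stopf("`rates` must be the pair of subpopulation mean rates")
  }
  if (rates[1] > rates[2]) "right" else if (rates[2] > rates[1]) "left" else "undecided"
}

#' Bin spike trains into nonoverlapping count windows
#'
#' Counts spikes in consecutive half-open bins `[0, bw), [bw, 2 bw), ...`
#' covering `[0, T)`. With the default 1-ms bins this is the count series
#' entering the spike-count-correlation analysis.
#'
#' @param raster List of per-unit spike-time vectors (ms), or a single
#'   numeric vector.
#' @param T Total duration, ms; `bin_width` must divide it.
#' @param bin_width Bin width, ms (default 1).
#' @return An integer matrix of counts, `T / bin_width` rows by one column
#'   per unit.
#' @examples
#' bin_counts(list(c(3.2, 7)), T = 10)[, 1]
#' @export
bin_counts <- function(raster, T, bin_width = 1) {
  if (is.numeric(raster)) raster <- list(raster)
  check_number(T, "T", lower = 0, strict_lower = TRUE)
  n_bins <- T / bin_width
  if (abs(n_bins - round(n_bins)) > 1e-9) {
    stopf("`bin_width` (%g) must divide T (%g)", bin_width, T)
  }
  n_bins <- as.integer(round(n_bins))
  out <- vapply(raster, function(t) {
    validate_spike_train(t, T = T)
    tabulate(floor(t / bin_width) + 1L, nbins = n_bins)
  }, integer(n_bins))
  matrix(out, nrow = n_bins)
}

#' Pairwise spike-count correlation matrix
#'
#' Pearson correlation between all pairs of binned spike-count series, plus
#' the mean correlation over within-subpopulation pairs and over
#' between-subpopulation pairs (off-diagonal pairs only, each unordered pair
#' counted once). Units whose count series has zero variance have undefined
#' correlations; their pairs are excluded from the means and reported in
#' `zero_variance_units`.
#'
#' @param counts Matrix of binned counts, bins in rows, one column per unit
#'   (see [bin_counts()] / [experiment_counts()]).
#' @param labels Integer subpopulation labels per unit.
#' @param bin_width Bin width of the series, ms (metadata).
#' @return An `scc_matrix`: list with the correlation matrix `r` (diagonal 1
#'   where defined), `mean_within`, `mean_between`, `bin_width`,
#'   `zero_variance_units` and `labels`.
#' @export
scc_matrix <- function(counts, labels, bin_width = 1) {
  counts <- as.matrix(counts)
  n <- ncol(counts)
  if (n < 2) stopf("at least 2 count series are required")
  if (length(labels) != n) stopf("`labels` must have one entry per unit")
  vars <- apply(counts, 2, stats::var)
  zero_var <- unname(which(vars == 0))
  r <- suppressWarnings(stats::cor(counts))
  if (length(zero_var)) {
    r[zero_var, ] <- NA_real_
    r[, zero_var] <- NA_real_
  }
  diag(r)[setdiff(seq_len(n), zero_var)] <- 1
  same <- outer(labels, labels, "==")
  upper <- upper.tri(r)
  mean_within <- mean(r[upper & same], na.rm = TRUE)
  mean_between <- if (any(upper & !same)) mean(r[upper & !same], na.rm = TRUE) else NA_real_
  structure(list(r = r, bin_width = bin_width, mean_within = mean_within,
                 mean_between = mean_between,
                 zero_variance_units = zero_var, labels = labels),
            class = "scc_matrix")
}

#' @export
print.scc_matrix <- function(x, ...) {
  cat(sprintf("Spike-count correlations (%g-ms bins): mean within = %.4f, mean between = %.4f\n",
              x$bin_width, x$mean_within, x$mean_between))
  if (length(x$zero_variance_units)) {
    cat("  zero-variance units excluded:",
        paste(x$zero_variance_units, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Concatenated binned counts of a whole experiment
#'
#' Bins every step's raster in nonoverlapping windows and concatenates the
#' per-step series across direction steps (optionally only one direction's
#' steps) into one long series per unit — the input to [scc_matrix()].
#'
#' @param experiment An `stp_experiment` from [run_experiment()].
#' @param bin_width Bin width, ms.
#' @param scope `"all"`, `"right"` or `"left"`: which steps to concatenate.
#' @return Integer matrix, bins in rows, one column per unit.
#' @export
experiment_counts <- function(experiment, bin_width = 1,
                              scope = c("all", "right", "left")) {
  scope <- match.arg(scope)
  keep <- if (scope == "all") seq_along(experiment$steps) else {
    which(experiment$directions == scope)
  }
  if (!length(keep)) stopf("no steps with direction '%s'", scope)
  T <- experiment$step_duration
  do.call(rbind, lapply(experiment$steps[keep], function(s) {
    bin_counts(s$raster, T = T, bin_width = bin_width)
  }))
}

#' Spike-count correlations of a whole experiment
#'
#' @inheritParams experiment_counts
#' @return An [scc_matrix()] over the concatenated count series.
#' @export
experiment_scc <- function(experiment, bin_width = 1,
                           scope = c("all", "right", "left")) {
  scope <- match.arg(scope)
  scc_matrix(experiment_counts(experiment, bin_width, scope),
             labels = experiment$net$labels, bin_width = bin_width)
}

#' Per-step rates, decisions and decision accuracy
#'
#' Computes, for every direction step, the mean firing rate of each
#' subpopulation over the response window, the LED-style decision from
#' [decide_direction()], and whether it matches the step's true direction.
#'
#' @inheritParams experiment_counts
#' @param window Response window in ms (default: the full step).
#' @return A data frame with columns `step`, `direction`, `rate_subpop1`,
#'   `rate_subpop2`, `decision` and `correct`.
#' @export
step_decisions <- function(experiment, window = NULL) {
  if (is.null(window)) window <- c(0, experiment$step_duration)
  labels <- experiment$net$labels
  rows <- lapply(experiment$steps, function(s) {
    rs <- firing_rate(s$raster, window, labels)$per_subpop_rate
    if (length(rs) < 2) rs <- c(rs, NA_real_)  # single-subpop networks
    data.frame(step = s$step_index, direction = s$direction,
               rate_subpop1 = rs[[1]], rate_subpop2 = rs[[2]],
               decision = if (anyNA(rs)) NA_character_ else decide_direction(rs),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$correct <- out$decision == out$direction
  out
}

#' Mean subpopulation rates per motion direction
#'
#' The quantity behind the direction-selectivity bar charts: the mean (over
#' steps and units) firing rate of each subpopulation, split by stimulus
#' direction.
#'
#' @inheritParams step_decisions
#' @return A data frame with columns `direction`, `subpop` and `rate`.
#' @export
direction_rates <- function(experiment, window = NULL) {
  dec <- step_decisions(experiment, window)
  agg <- do.call(rbind, lapply(c("right", "left"), function(d) {
    sel <- dec$direction == d
    data.frame(direction = d, subpop = c(1L, 2L),
               rate = c(mean(dec$rate_subpop1[sel]),
                        mean(dec$rate_subpop2[sel])))
  }))
  agg
}

#' Time-averaged synaptic resources and release probability per subpopulation
#'
#' Averages the per-step time averages of `x` (resources available) and `u`
#' (release probability) over the units of each subpopulation, per direction.
#'
#' @inheritParams step_decisions
#' @return A data frame with columns `direction`, `subpop`, `mean_x`,
#'   `mean_u`.
#' @export
resource_summary <- function(experiment) {
  labels <- experiment$net$labels
  rows <- lapply(experiment$steps, function(s) {
    data.frame(direction = s$direction, subpop = labels,
               x = s$mean_x, u = s$mean_u)
  })
  df <- do.call(rbind, rows)
  agg_x <- stats::aggregate(x ~ direction + subpop, df, mean)
  agg_u <- stats::aggregate(u ~ direction + subpop, df, mean)
  out <- merge(agg_x, agg_u, by = c("direction", "subpop"))
  names(out)[3:4] <- c("mean_x", "mean_u")
  out[order(out$direction, out$subpop), ]
}
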