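#' Experiment configuration
#'
#' Assembles the full parameter set of a motion-discrimination experiment:
#' network topology, STP and LIF parameters, stimulus-generator settings and
#' behaviour flags. All defaults reproduce the reference parameter tables
#' (`tau_f = 750` ms, `tau_d = 50` ms, `x0 = 1`, `A = 0.039`; `theta = -55`
#' mV, `V_rest = -70` mV, `R_m = 200`, `tau_m = 30` ms, `tau_arp = 2` ms,
#' `dt = 1` ms, `T = 1000` ms). For the two-unit network the current gain is
#' doubled (`gain_scale = 2`) so that its mean activity falls in the same
#' range as the six-unit circuit's.
#'
#' @param network `"six_unit"` or `"two_unit"`.
#' @param cross_links Between-subpopulation links for the six-unit build (see
#'   [build_six_unit()]).
#' @param stp Named list overriding STP fields `tau_f`, `tau_d`, `x0`, `A`.
#' @param lif Named list overriding LIF fields `theta`, `V_rest`, `R_m`,
#'   `tau_m`, `tau_arp`, `dt`, `T`.
#' @param stimulus Named list overriding stimulus fields `n_steps`,
#'   `bar_width`, `shift_per_step`, `noise_prob`, `U_min`, `U_max`,
#'   `start_position`.
#' @param gain_scale Multiplier on `A` (default 1 for six-unit, 2 for
#'   two-unit).
#' @param seed Integer seed for stimulus noise.
#' @param use_post_jump_u,recurrent_spikes,carry_over_state Behaviour flags,
#'   see [run_direction_step()] and [run_experiment()].
#' @return An `experiment_config` list.
#' @examples
#' cfg <- experiment_config()
#' cfg$stp$A
#' @export
experiment_config <- function(network = c("six_unit", "two_unit"),
                              cross_links = matrix(c(3, 4), ncol = 2),
                              stp = list(), lif = list(), stimulus = list(),
                              gain_scale = NULL, seed = 1L,
                              use_post_jump_u = TRUE,
                              recurrent_spikes = FALSE,
                              carry_over_state = FALSE) {
  network <- match.arg(network)
  if (is.null(gain_scale)) gain_scale <- if (network == "two_unit") 2 else 1
  stp_def <- list(tau_f = 750, tau_d = 50, x0 = 1, A = 0.039)
  lif_def <- list(theta = -55, V_rest = -70, R_m = 200, tau_m = 30,
                  tau_arp = 2, dt = 1, T = 1000)
  stim_def <- list(n_steps = 200, bar_width = 10, shift_per_step = 5,
                   noise_prob = 0, U_min = 0.05, U_max = 0.6,
                   start_position = 0)
  merge_over <- function(def, user) {
    bad <- setdiff(names(user), names(def))
    if (length(bad)) stopf("unknown field(s): %s", paste(bad, collapse = ", "))
    def[names(user)] <- user
    def
  }
  structure(list(
    network = network,
    cross_links = cross_links,
    stp = merge_over(stp_def, stp),
    lif = merge_over(lif_def, lif),
    stimulus = merge_over(stim_def, stimulus),
    gain_scale = gain_scale,
    seed = as.integer(seed),
    flags = list(use_post_jump_u = use_post_jump_u,
                 recurrent_spikes = recurrent_spikes,
                 carry_over_state = carry_over_state)
  ), class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("Experiment config: %s network, %d steps, bar width %d, seed %d\n",
              x$network, x$stimulus$n_steps, x$stimulus$bar_width, x$seed))
  invisible(x)
}

#' Write / read an experiment configuration as YAML
#'
#' The YAML keys mirror the parameter-table symbol names (`tau_f`, `tau_d`,
#' `x0`, `A`, `theta`, `V_rest`, `R_m`, `tau_m`, `tau_arp`, `dt`, `T`) for
#' traceability.
#'
#' @param config An [experiment_config()].
#' @param path YAML file path.
#' @return `path` (writer) or the `experiment_config` (reader).
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  lst <- unclass(config)
  lst$cross_links <- if (length(lst$cross_links)) {
    apply(lst$cross_links, 1, as.integer, simplify = FALSE)
  } else {
    list()
  }
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lst <- yaml::read_yaml(path)
  cl <- if (length(lst$cross_links)) {
    do.call(rbind, lst$cross_links)
  } else {
    matrix(numeric(0), ncol = 2)
  }
  experiment_config(
    network = lst$network, cross_links = cl,
    stp = lst$stp[setdiff(names(lst$stp), character(0))],
    lif = lst$lif, stimulus = lst$stimulus,
    gain_scale = lst$gain_scale, seed = lst$seed,
    use_post_jump_u = lst$flags$use_post_jump_u,
    recurrent_spikes = lst$flags$recurrent_spikes,
    carry_over_state = lst$flags$carry_over_state)
}

# materialize the pieces of a config
config_net <- function(config) {
  switch(config$network,
         six_unit = build_six_unit(config$cross_links),
         two_unit = build_two_unit())
}

config_stp <- function(config) {
  stp_params(tau_f = config$stp$tau_f, tau_d = config$stp$tau_d,
             U = config$stimulus$U_max,
             A = config$stp$A * config$gain_scale)
}

config_lif <- function(config) {
  do.call(lif_params, config$lif)
}

config_sequence <- function(config) {
  st <- config$stimulus
  n_rows <- if (config$network == "two_unit") 2 else 6
  make_direction_sequence(
    n_steps = st$n_steps, bar_width = st$bar_width,
    shift_per_step = st$shift_per_step, noise_prob = st$noise_prob,
    rng_seed = config$seed, U_min = st$U_min, U_max = st$U_max,
    start_position = st$start_position, step_duration = config$lif$T,
    n_rows = n_rows)
}
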