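#' Relax a synapse between spikes
#'
#' Closed-form inter-spike dynamics of the two synaptic variables: `u` decays
#' exponentially towards its resting value `U` with time constant `tau_f`, and
#' `x` recovers towards 1 with time constant `tau_d`:
#' \deqn{u' = U + (u - U) e^{-\Delta t/\tau_f}, \quad
#'       x' = 1 - (1 - x) e^{-\Delta t/\tau_d}.}
#'
#' @param state An [stp_state()].
#' @param params An [stp_params()].
#' @param dt_elapsed Elapsed time since the state was valid, ms (>= 0).
#' @return The relaxed `stp_state`.
#' @examples
#' p <- stp_params(U = 0.15)
#' stp_relax(stp_state(0.5, 1), p, 750)  # u = 0.15 + 0.35 * exp(-1)
#' @export
stp_relax <- function(state, params, dt_elapsed) {
  check_number(dt_elapsed, "dt_elapsed", lower = 0)
  u <- params$U + (state$u - params$U) * exp(-dt_elapsed / params$tau_f)
  x <- 1 - (1 - state$x) * exp(-dt_elapsed / params$tau_d)
  stp_state(clamp01(u), clamp01(x))
}

#' Apply a presynaptic spike to a synapse
#'
#' The spike-triggered jumps of the model: residual calcium rises as
#' `u+ = u- + U * (1 - u-)`, a fraction `release = u * x-` of the available
#' resources is released, and `x+ = x- - release`. By the standard convention
#' for facilitating synapses the release uses the post-jump `u+`
#' (`use_post_jump_u = TRUE`); setting it to `FALSE` uses the pre-jump `u-`,
#' the alternative reading of the resource-drop term.
#'
#' @inheritParams stp_relax
#' @param use_post_jump_u Logical; use the post-jump `u` in the released
#'   fraction (default `TRUE`).
#' @return A list with elements `state` (the post-spike `stp_state`) and
#'   `release` (the released resource fraction, in \[0, 1\]).
#' @examples
#' p <- stp_params(U = 0.15)
#' stp_apply_spike(stp_rest_state(p), p)
#' @export
stp_apply_spike <- function(state, params, use_post_jump_u = TRUE) {
  u_post <- state$u + params$U * (1 - state$u)
  release <- (if (use_post_jump_u) u_post else state$u) * state$x
  x_post <- state$x - release
  list(state = stp_state(clamp01(u_post), clamp01(x_post)), release = release)
}

#' One forward-Euler update of the synaptic variables
#'
#' Discretizes the inter-spike dynamics with a single forward-Euler step and,
#' if `spiked` is `TRUE`, applies the spike-triggered jumps after the
#' continuous update within the same step (so that the event-driven solution
#' is recovered as `dt -> 0`).
#'
#' @inheritParams stp_apply_spike
#' @param spiked Logical; did a presynaptic spike occur in this step?
#' @param dt Step size, ms (> 0).
#' @return The updated `stp_state`.
#' @export
stp_euler_step <- function(state, params, spiked, dt, use_post_jump_u = TRUE) {
  check_number(dt, "dt", lower = 0, strict_lower = TRUE)
  u <- state$u + (params$U - state$u) * dt / params$tau_f
  x <- state$x + (1 - state$x) * dt / params$tau_d
  st <- stp_state(clamp01(u), clamp01(x))
  if (isTRUE(spiked)) st <- stp_apply_spike(st, params, use_post_jump_u)$state
  st
}

#' Simulate a synapse over a presynaptic spike train
#'
#' Evolves the synaptic variables `(u, x)` over a full presynaptic spike train
#' and samples the trajectory every `dt` ms at times `0, dt, ..., ceiling(T /
#' dt) - 1` steps. Two integration modes are available:
#'
#' * `"event_driven"`: exact closed-form relaxation between events; spikes are
#'   applied at their exact times. A jump occurring exactly at a sample time is
#'   applied before sampling (a spike at `t = 0` is visible in the first
#'   sample).
#' * `"euler"`: fixed-step forward Euler as in [stp_euler_step()]; a spike at
#'   time `s` is applied within the step ending at the first sample time
#'   `>= s`.
#'
#' Inter-spike relaxation is evaluated in closed form in both modes (the Euler
#' mode uses the exact geometric recursion `u_{n+1} = u_n + (U - u_n) dt /
#' tau_f`, i.e. `u_n = U + (u_0 - U) (1 - dt/tau_f)^n`), so long trajectories
#' are cheap while remaining bit-identical to step-by-step iteration.
#'
#' @inheritParams stp_apply_spike
#' @param train Numeric vector of presynaptic spike times, ms, sorted
#'   nondecreasing, all `< T`.
#' @param T Total simulated duration, ms.
#' @param dt Sampling (and, for `mode = "euler"`, integration) step, ms.
#' @param mode `"event_driven"` or `"euler"`.
#' @return A data frame with columns `time_ms`, `u`, `x` and `efficacy`
#'   (`u * x`), with `ceiling(T / dt)` rows. The number of clamping events
#'   (values nudged back into \[0, 1\] to absorb floating-point drift) is
#'   attached as attribute `"n_clamped"`.
#' @examples
#' p <- stp_params(U = 0.15)
#' traj <- stp_simulate_train(p, train = c(0, 20, 40), T = 100, dt = 1)
#' head(traj)
#' @export
stp_simulate_train <- function(params, train, T, dt = 1,
                               mode = c("event_driven", "euler"),
                               use_post_jump_u = TRUE) {
  mode <- match.arg(mode)
  check_number(T, "T", lower = 0, strict_lower = TRUE)
  check_number(dt, "dt", lower = 0, strict_lower = TRUE)
  validate_spike_train(train, T = T)
  n <- ceiling(T / dt)
  times <- (seq_len(n) - 1) * dt
  U <- params$U
  clamped <- 0L

  # post-event anchor states, computed sequentially over the spikes
  ns <- length(train)
  anch_u <- numeric(ns)
  anch_x <- numeric(ns)

  if (mode == "event_driven") {
    cu <- U; cx <- 1; t_prev <- 0
    for (k in seq_len(ns)) {
      ef <- exp(-(train[k] - t_prev) / params$tau_f)
      ed <- exp(-(train[k] - t_prev) / params$tau_d)
      cu <- U + (cu - U) * ef
      cx <- 1 - (1 - cx) * ed
      u_post <- cu + U * (1 - cu)
      rel <- (if (use_post_jump_u) u_post else cu) * cx
      cu <- u_post
      cx <- cx - rel
      clamped <- clamped + n_clamped(c(cu, cx))
      cu <- clamp01(cu); cx <- clamp01(cx)
      anch_u[k] <- cu; anch_x[k] <- cx
      t_prev <- train[k]
    }
    seg <- findInterval(times, train)            # index of last spike <= t
    t0 <- c(0, train)[seg + 1L]
    u0 <- c(U, anch_u)[seg + 1L]
    x0 <- c(1, anch_x)[seg + 1L]
    u <- U + (u0 - U) * exp(-(times - t0) / params$tau_f)
    x <- 1 - (1 - x0) * exp(-(times - t0) / params$tau_d)
  } else {
    af <- 1 - dt / params$tau_f
    ad <- 1 - dt / params$tau_d
    # spike at time s lands in the step ending at the first sample time >= s;
    # sample i is at time (i - 1) * dt
    idx <- pmin(ceiling(train / dt) + 1L, n + 1L)
    cu <- U; cx <- 1; i_prev <- 1L
    for (k in seq_len(ns)) {
      m <- idx[k] - i_prev
      cu <- U + (cu - U) * af^m
      cx <- 1 - (1 - cx) * ad^m
      u_post <- cu + U * (1 - cu)
      rel <- (if (use_post_jump_u) u_post else cu) * cx
      cu <- u_post
      cx <- cx - rel
      clamped <- clamped + n_clamped(c(cu, cx))
      cu <- clamp01(cu); cx <- clamp01(cx)
      anch_u[k] <- cu; anch_x[k] <- cx
      i_prev <- idx[k]
    }
    seg <- findInterval(seq_len(n), idx)
    i0 <- c(1L, idx)[seg + 1L]
    u0 <- c(U, anch_u)[seg + 1L]
    x0 <- c(1, anch_x)[seg + 1L]
    u <- U + (u0 - U) * af^(seq_len(n) - i0)
    x <- 1 - (1 - x0) * ad^(seq_len(n) - i0)
  }

  out <- data.frame(time_ms = times, u = u, x = x, efficacy = u * x)
  attr(out, "n_clamped") <- clamped
  out
}

#' Write a sampled synaptic trajectory to CSV
#'
#' @param traj A trajectory from [stp_simulate_train()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(traj, path, row.names = FALSE)
  invisible(path)
}

#' Write a spike train as a one-column CSV of times in ms
#'
#' @param times Numeric vector of spike times, ms.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spike_train_csv <- function(times, path) {
  validate_spike_train(times)
  utils::write.csv(data.frame(time_ms = times), path, row.names = FALSE)
  invisible(path)
}

#' Read a spike train from a one-column CSV
#'
#' @param path CSV file with a `time_ms` column (or a single unnamed column).
#' @return Numeric vector of spike times, ms.
#' @export
read_spike_train_csv <- function(path) {
  df <- utils::read.csv(path)
  times <- if ("time_ms" %in% names(df)) df$time_ms else df[[1]]
  validate_spike_train(times)
  as.numeric(times)
}
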