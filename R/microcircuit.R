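#' Build the six-unit microcircuit
#'
#' Two subpopulations of three units each, with dense within-subpopulation
#' connectivity and sparse between-subpopulation connectivity, mirroring the
#' connectivity statistics of direction-selective neurons in layers 2/3 of V1
#' (units sharing a direction preference are more highly connected). Units
#' 1-3 form subpopulation 1 (right-preferring), units 4-6 subpopulation 2
#' (left-preferring). Within each subpopulation the binary connectivity matrix
#' is all ones (bidirectional, self-connections included); between
#' subpopulations only the listed links are present.
#'
#' @param cross_links A two-column matrix (or list of length-2 vectors) of
#'   unit pairs connecting the two subpopulations; each link is made
#'   reciprocal. The default is the single reciprocal pair 3--4, the minimal
#'   choice keeping the graph connected while satisfying within > between
#'   connectivity.
#' @return A `microcircuit`: a list with the binary matrix `w` (`w[i, j] = 1`
#'   iff presynaptic unit `j` connects to postsynaptic unit `i`) and integer
#'   `labels` giving each unit's subpopulation (1 or 2).
#' @examples
#' net <- build_six_unit()
#' net$w
#' @export
build_six_unit <- function(cross_links = matrix(c(3, 4), ncol = 2)) {
  if (is.list(cross_links)) cross_links <- do.call(rbind, cross_links)
  if (length(cross_links) && ncol(cross_links) != 2) {
    stopf("`cross_links` must be pairs of unit indices")
  }
  labels <- rep(1:2, each = 3)
  w <- matrix(0L, 6, 6)
  w[1:3, 1:3] <- 1L
  w[4:6, 4:6] <- 1L
  for (k in seq_len(nrow(cross_links))) {
    a <- cross_links[k, 1]; b <- cross_links[k, 2]
    if (any(c(a, b) < 1 | c(a, b) > 6)) stopf("cross link out of range")
    if (labels[a] == labels[b]) {
      stopf("cross link %d-%d joins units of the same subpopulation", a, b)
    }
    w[a, b] <- 1L
    w[b, a] <- 1L
  }
  structure(list(w = w, labels = labels), class = "microcircuit")
}

#' Build the two-unit microcircuit
#'
#' The fully bidirectionally connected pair with self-connections: a 2 x 2
#' all-ones connectivity matrix. The two units carry distinct subpopulation
#' labels (for the release-probability assignment) but form a single
#' connected component, so both receive identical summed input and behave as
#' one subpopulation.
#'
#' @return A `microcircuit` with `w = matrix(1, 2, 2)` and labels `c(1, 2)`.
#' @export
build_two_unit <- function() {
  structure(list(w = matrix(1L, 2, 2), labels = c(1L, 2L)),
            class = "microcircuit")
}

#' @export
print.microcircuit <- function(x, ...) {
  n <- nrow(x$w)
  within <- sum(x$w[outer(x$labels, x$labels, "==")])
  between <- sum(x$w) - within
  cat(sprintf("Microcircuit: %d units, %d within- and %d between-subpopulation links\n",
              n, within, between))
  invisible(x)
}

#' STP-gated postsynaptic current
#'
#' The instantaneous current into a unit: the gain times the sum of the
#' synaptic efficacies `u_j * x_j` over its presynaptic inputs,
#' `I = A * sum_j w_ij * u_j * x_j`.
#'
#' @param w_row Binary connectivity row of the postsynaptic unit.
#' @param efficacies Vector of presynaptic efficacies `u_j * x_j`.
#' @param A Multiplicative gain.
#' @return The current (dimensionless; scaled to mV by the membrane
#'   resistance factor).
#' @examples
#' compute_current(c(1, 0), c(0.5, 0.9), A = 0.039)  # 0.0195
#' @export
compute_current <- function(w_row, efficacies, A) {
  if (length(w_row) != length(efficacies)) {
    stopf("`w_row` and `efficacies` must have equal length")
  }
  A * sum(w_row * efficacies)
}

#' One Euler step of a leaky integrate-and-fire unit
#'
#' While refractory, the membrane is held at `V_rest` and the remaining
#' refractory time is decremented. Otherwise the potential advances by one
#' forward-Euler step of `tau_m dV/dt = -(V - V_rest) + R_m * I`; if the
#' updated potential reaches the threshold `theta` the unit spikes, the
#' potential is reset to `V_rest` and the refractory clock is set to
#' `tau_arp`.
#'
#' @param state List with elements `V` (mV) and `refractory_remaining` (ms).
#' @param params A [lif_params()].
#' @param I Input current.
#' @return A list with the updated `state` and logical `spiked`.
#' @export
lif_step <- function(state, params, I) {
  if (state$refractory_remaining > 0) {
    return(list(
      state = list(V = params$V_rest,
                   refractory_remaining = state$refractory_remaining - params$dt),
      spiked = FALSE))
  }
  V <- state$V +
    (params$dt / params$tau_m) * (-(state$V - params$V_rest) + params$R_m * I)
  if (V >= params$theta) {
    list(state = list(V = params$V_rest, refractory_remaining = params$tau_arp),
         spiked = TRUE)
  } else {
    list(state = list(V = V, refractory_remaining = 0), spiked = FALSE)
  }
}

#' Simulate one direction step of the microcircuit
#'
#' Runs the network for one stimulus presentation. At the start of the step
#' every synapse `j` is re-initialized at rest with the step's release
#' probability for its unit's subpopulation (`u = U = u_pair[label(j)]`,
#' `x = 1`) and every membrane at `V_rest`, unless an explicit `init` state is
#' supplied (carry-over mode). The presynaptic train of synapse `j` is row `j`
#' of the frame; unit spikes do not re-enter the synapses unless
#' `recurrent_spikes = TRUE`. Each `dt` the update order is: (1) advance the
#' synaptic variables (forward Euler) and apply the spike jumps for synapses
#' whose frame pixel is 1, (2) compute the currents `I = A * w \%*\% (u * x)`
#' (evaluated continuously from the synaptic state, so a constant
#' subthreshold current `A * sum(w) * U` flows even in the absence of
#' presynaptic spikes), (3) advance the LIF units.
#'
#' @param net A `microcircuit` from [build_six_unit()] or [build_two_unit()].
#' @param lif A [lif_params()]; `T` must equal `ncol(frame) * dt`.
#' @param stp An [stp_params()] template; its `U` is overridden per step by
#'   `u_pair`.
#' @param frame A `binary_frame` whose row count equals the unit count, or a
#'   6-row frame for the two-unit build (the first two rows are used).
#' @param u_pair Numeric pair `(U1, U2)`: the initial release probabilities
#'   recruited by subpopulations 1 and 2 on this step.
#' @param keep_traces Keep the full `V`, `I`, `u`, `x` time series (default
#'   `TRUE`; [run_experiment()] turns this off and keeps summaries).
#' @param use_post_jump_u See [stp_apply_spike()].
#' @param recurrent_spikes If `TRUE`, a unit's own emitted spikes also drive
#'   its outgoing synapse at the next time step, in addition to the external
#'   train (alternative reading of the input wiring; default `FALSE`).
#' @param init Optional list `(u, x, V, refractory)` of initial vectors for
#'   carry-over across steps.
#' @param direction,step_index Metadata stored in the result.
#' @return A `simulation_result`: list with `raster` (list of spike-time
#'   vectors, ms), `counts`, `mean_u`, `mean_x` (per-unit time averages),
#'   `direction`, `step_index`, `u_pair`, `final` (end-of-step state) and,
#'   if `keep_traces`, matrices `V_trace`, `I_trace`, `u_trace`, `x_trace`
#'   (units x time samples, sampled every `dt` at times `0, dt, ...`).
#' @export
run_direction_step <- function(net, lif, stp, frame, u_pair,
                               keep_traces = TRUE, use_post_jump_u = TRUE,
                               recurrent_spikes = FALSE, init = NULL,
                               direction = NA_character_, step_index = NA_integer_) {
  N <- nrow(net$w)
  validate_frame(frame)
  if (nrow(frame) != N) {
    if (N == 2 && nrow(frame) >= 2) {
      frame <- frame[1:2, , drop = FALSE]
    } else {
      stopf("frame has %d rows but the network has %d units", nrow(frame), N)
    }
  }
  n_t <- ncol(frame)
  dt <- lif$dt
  if (abs(n_t * dt - lif$T) > 1e-9) {
    stopf("frame columns (%d) x dt (%g) must equal the step duration T = %g ms",
          n_t, dt, lif$T)
  }
  if (length(u_pair) != 2 || any(u_pair <= 0) || any(u_pair > 1)) {
    stopf("`u_pair` must be two release probabilities in (0, 1]")
  }

  U <- as.numeric(u_pair[net$labels])
  if (is.null(init)) {
    u <- U
    x <- rep(1, N)
    V <- rep(lif$V_rest, N)
    refr <- rep(0, N)
  } else {
    u <- init$u; x <- init$x; V <- init$V; refr <- init$refractory
  }

  af <- dt / stp$tau_f
  ad <- dt / stp$tau_d
  km <- dt / lif$tau_m
  spike_in <- frame > 0L
  fired_prev <- rep(FALSE, N)

  spk <- matrix(FALSE, N, n_t)
  if (keep_traces) {
    V_trace <- matrix(NA_real_, N, n_t)
    I_trace <- matrix(NA_real_, N, n_t)
    u_trace <- matrix(NA_real_, N, n_t)
    x_trace <- matrix(NA_real_, N, n_t)
  }
  u_sum <- numeric(N)
  x_sum <- numeric(N)

  for (k in seq_len(n_t)) {
    # (1) synaptic variables: relax, then spike jumps within the same step
    u <- u + (U - u) * af
    x <- x + (1 - x) * ad
    sp <- spike_in[, k]
    if (recurrent_spikes) sp <- sp | fired_prev
    if (any(sp)) {
      u_post <- u[sp] + U[sp] * (1 - u[sp])
      rel <- (if (use_post_jump_u) u_post else u[sp]) * x[sp]
      u[sp] <- u_post
      x[sp] <- x[sp] - rel
    }
    u <- clamp01(u)
    x <- clamp01(x)

    # (2) currents from the current synaptic state
    I <- stp$A * drop(net$w %*% (u * x))

    # (3) LIF update with absolute refractoriness
    inref <- refr > 0
    Vn <- V + km * (-(V - lif$V_rest) + lif$R_m * I)
    Vn[inref] <- lif$V_rest
    refr[inref] <- refr[inref] - dt
    fired <- !inref & Vn >= lif$theta
    Vn[fired] <- lif$V_rest
    refr[fired] <- lif$tau_arp
    V <- Vn
    fired_prev <- fired

    spk[, k] <- fired
    u_sum <- u_sum + u
    x_sum <- x_sum + x
    if (keep_traces) {
      V_trace[, k] <- V
      I_trace[, k] <- I
      u_trace[, k] <- u
      x_trace[, k] <- x
    }
  }

  raster <- lapply(seq_len(N), function(i) (which(spk[i, ]) - 1) * dt)
  out <- list(
    raster = raster,
    counts = vapply(raster, length, integer(1)),
    mean_u = u_sum / n_t,
    mean_x = x_sum / n_t,
    direction = direction,
    step_index = step_index,
    u_pair = u_pair,
    final = list(u = u, x = x, V = V, refractory = refr)
  )
  if (keep_traces) {
    out$V_trace <- V_trace
    out$I_trace <- I_trace
    out$u_trace <- u_trace
    out$x_trace <- x_trace
  }
  class(out) <- "simulation_result"
  out
}

#' Run a full direction-sweep experiment
#'
#' Applies [run_direction_step()] to every step of a [make_direction_sequence()]
#' sweep, in order. By default the synaptic and membrane state is
#' re-initialized at each step (each step recruits a new pair of initial
#' release probabilities); `carry_over_state = TRUE` instead carries `(u, x,
#' V)` across step boundaries (the resting target of `u` still follows the
#' step's schedule).
#'
#' @inheritParams run_direction_step
#' @param seq A `direction_sequence`.
#' @param carry_over_state Carry synaptic/membrane state across steps
#'   (default `FALSE`).
#' @return An `stp_experiment`: list with `steps` (one `simulation_result`
#'   per direction step), the `net`, `lif`, `stp` objects used, `directions`
#'   and `step_duration`.
#' @examples
#' net <- build_six_unit()
#' seq2 <- make_direction_sequence(n_steps = 2)
#' ex <- run_experiment(net, lif_params(), stp_params(), seq2)
#' length(ex$steps)
#' @export
run_experiment <- function(net, lif, stp, seq, keep_traces = FALSE,
                           use_post_jump_u = TRUE, recurrent_spikes = FALSE,
                           carry_over_state = FALSE) {
  stopifnot(inherits(seq, "direction_sequence"))
  n <- length(seq$frames)
  steps <- vector("list", n)
  init <- NULL
  for (s in seq_len(n)) {
    res <- run_direction_step(
      net, lif, stp, seq$frames[[s]], seq$u_pairs[s, ],
      keep_traces = keep_traces, use_post_jump_u = use_post_jump_u,
      recurrent_spikes = recurrent_spikes, init = init,
      direction = seq$directions[s], step_index = s)
    if (carry_over_state) init <- res$final
    steps[[s]] <- res
  }
  structure(
    list(steps = steps, net = net, lif = lif, stp = stp,
         directions = seq$directions, step_duration = seq$step_duration),
    class = "stp_experiment")
}

#' @export
print.stp_experiment <- function(x, ...) {
  n <- length(x$steps)
  total <- sum(vapply(x$steps, function(s) sum(s$counts), numeric(1)))
  cat(sprintf("STP experiment: %d units, %d direction steps, %d spikes total\n",
              nrow(x$net$w), n, total))
  invisible(x)
}
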