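#' Short-term plasticity (Tsodyks-Markram) kinetic parameters
#'
#' Bundles the kinetic constants of the two-variable phenomenological model of
#' short-term synaptic plasticity. Between presynaptic spikes the utilization
#' variable `u` relaxes towards its resting value `U` with time constant
#' `tau_f` (facilitation recovery) and the resource variable `x` relaxes
#' towards 1 with time constant `tau_d` (depression recovery). At each
#' presynaptic spike `u` jumps by `U * (1 - u)` and a fraction `u * x` of the
#' resources is released. The released fraction, scaled by the gain `A`, gates
#' the postsynaptic current.
#'
#' The default values are the facilitation-dominated (STF) regime used
#' throughout the package: `tau_f = 750` ms, `tau_d = 50` ms, `A = 0.039`.
#' With `tau_f >> tau_d` a spike burst leaves `u` elevated for hundreds of
#' milliseconds while `x` recovers within tens of milliseconds, so the synaptic
#' efficacy `u * x` transiently exceeds its resting value `U` after the burst.
#'
#' @param tau_f Facilitation recovery time constant, ms (> 0).
#' @param tau_d Depression recovery time constant, ms (> 0).
#' @param U Resting (initial) release probability, in (0, 1].
#' @param A Multiplicative gain of the generated current, dimensionless (> 0;
#'   current units are absorbed into the membrane-resistance scale factor).
#'
#' @return An object of class `stp_params`.
#' @seealso [stp_state()], [stp_simulate_train()]
#' @examples
#' stp_params()
#' stp_params(U = 0.2)
#' @export
stp_params <- function(tau_f = 750, tau_d = 50, U = 0.6, A = 0.039) {
  check_number(tau_f, "tau_f", lower = 0, strict_lower = TRUE)
  check_number(tau_d, "tau_d", lower = 0, strict_lower = TRUE)
  check_number(U, "U", lower = 0, upper = 1, strict_lower = TRUE)
  check_number(A, "A", lower = 0, strict_lower = TRUE)
  structure(list(tau_f = tau_f, tau_d = tau_d, U = U, A = A),
            class = "stp_params")
}

#' Instantaneous state of a Tsodyks-Markram synapse
#'
#' @param u Running release probability (residual-calcium variable), in
#'   \[0, 1\].
#' @param x Fraction of neurotransmitter resources available, in \[0, 1\].
#'
#' @return An object of class `stp_state`. At rest `u = U` and `x = 1`.
#' @seealso [stp_rest_state()]
#' @export
stp_state <- function(u, x) {
  check_number(u, "u", lower = 0, upper = 1)
  check_number(x, "x", lower = 0, upper = 1)
  structure(list(u = u, x = x), class = "stp_state")
}

#' Resting state of a synapse
#'
#' @param params An [stp_params()] object.
#' @return The resting `stp_state`: `u = U`, `x = 1`.
#' @export
stp_rest_state <- function(params) {
  stp_state(u = params$U, x = 1)
}

#' @export
print.stp_params <- function(x, ...) {
  cat(sprintf(
    "STP parameters: tau_f = %g ms, tau_d = %g ms, U = %g, A = %g\n",
    x$tau_f, x$tau_d, x$U, x$A))
  invisible(x)
}

#' @export
print.stp_state <- function(x, ...) {
  cat(sprintf("STP state: u = %.6g, x = %.6g (efficacy u*x = %.6g)\n",
              x$u, x$x, x$u * x$x))
  invisible(x)
}

#' Leaky integrate-and-fire membrane parameters
#'
#' Membrane parameters of the LIF units driven by the STP-gated current. The
#' membrane potential integrates `tau_m dV/dt = -(V - V_rest) + R_m * I`; a
#' spike is emitted when `V >= theta`, after which `V` is reset to `V_rest`
#' and held there for the absolute refractory period `tau_arp`.
#'
#' Defaults: threshold -55 mV, rest -70 mV, `R_m = 200` (a plain scale factor
#' converting the dimensionless STP current to mV; only the product
#' `R_m * A` matters), `tau_m = 30` ms, `tau_arp = 2` ms, integration step
#' `dt = 1` ms, stimulus duration `T = 1000` ms.
#'
#' @param theta Spike emission threshold, mV.
#' @param V_rest Resting membrane potential, mV (must be below `theta`).
#' @param R_m Membrane resistance scale factor (mV per unit current).
#' @param tau_m Membrane time constant, ms.
#' @param tau_arp Absolute refractory period, ms.
#' @param dt Integration time step, ms.
#' @param T Stimulus (direction-step) duration, ms.
#'
#' @return An object of class `lif_params`.
#' @export
lif_params <- function(theta = -55, V_rest = -70, R_m = 200, tau_m = 30,
                       tau_arp = 2, dt = 1, T = 1000) {
  check_number(theta, "theta")
  check_number(V_rest, "V_rest", upper = theta, strict_upper = TRUE)
  check_number(R_m, "R_m", lower = 0, strict_lower = TRUE)
  check_number(tau_m, "tau_m", lower = 0, strict_lower = TRUE)
  check_number(tau_arp, "tau_arp", lower = 0)
  check_number(dt, "dt", lower = 0, strict_lower = TRUE)
  check_number(T, "T", lower = 0, strict_lower = TRUE)
  structure(list(theta = theta, V_rest = V_rest, R_m = R_m, tau_m = tau_m,
                 tau_arp = tau_arp, dt = dt, T = T),
            class = "lif_params")
}

#' @export
print.lif_params <- function(x, ...) {
  cat(sprintf(
    paste0("LIF parameters: theta = %g mV, V_rest = %g mV, R_m = %g, ",
           "tau_m = %g ms, tau_arp = %g ms, dt = %g ms, T = %g ms\n"),
    x$theta, x$V_rest, x$R_m, x$tau_m, x$tau_arp, x$dt, x$T))
  invisible(x)
}

validate_spike_train <- function(times, T = NULL, name = "train") {
  if (length(times) == 0L) return(invisible(numeric(0)))
  if (!is.numeric(times) || anyNA(times)) {
    stopf("`%s` must be a numeric vector of spike times (ms)", name)
  }
  if (any(times < 0)) stopf("`%s` contains negative spike times", name)
  if (is.unsorted(times)) stopf("`%s` must be sorted nondecreasing", name)
  if (!is.null(T) && any(times >= T)) {
    stopf("`%s` contains spike times at or beyond T = %g ms", name, T)
  }
  invisible(as.numeric(times))
}
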