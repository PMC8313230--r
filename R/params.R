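#' Membrane parameters of a LIF neuron
#'
#' Container for the passive cell parameters of the discrete-time leaky
#' integrate-and-fire model. The decay factor `alpha = exp(-dt/tau_m)` is
#' derived on construction. The membrane resistance is fixed at 1 GOhm and is
#' absorbed into the weight units (see the package help page), so it never
#' appears as a number.
#'
#' @param tau_m membrane time constant in ms.
#' @param v_th baseline firing threshold in mV.
#' @param t_refr absolute refractory period in ms (spiking is suppressed for
#'   `round(t_refr/dt)` steps after each spike; the membrane keeps
#'   integrating).
#' @param dt simulation step in ms.
#' @return An object of class `cell_params`.
#' @examples
#' cp <- cell_params(tau_m = 20, v_th = 10)
#' cp$alpha # exp(-1/20)
#' @export
cell_params <- function(tau_m = 20, v_th = 10, t_refr = 3, dt = 1) {
  stopifnot(is.numeric(tau_m), all(tau_m > 0), is.numeric(v_th), v_th > 0,
            is.numeric(t_refr), t_refr >= 0, is.numeric(dt), dt > 0)
  alpha <- exp(-dt / tau_m)
  structure(list(tau_m = tau_m, v_th = v_th, R_m = 1, t_refr = t_refr,
                 dt = dt, alpha = alpha, n_ref = as.integer(round(t_refr / dt))),
            class = "cell_params")
}

#' Spike-frequency adaptation parameters
#'
#' The adaptive threshold is `A(t) = v_th + beta * a(t)` with
#' `a(t+dt) = rho * a(t) + (1 - rho) * z(t) * dt` and
#' `rho = exp(-dt/tau_a)`. `beta = 0` reduces the neuron exactly to a plain
#' LIF neuron; a negative `beta` gives the dual, enhanced-excitability (ELIF)
#' model in which each spike lowers the threshold.
#'
#' Note on magnitude: because `a` increments by `(1 - rho)` per spike, the
#' per-spike threshold jump is `beta * (1 - exp(-dt/tau_a))` mV. Task presets
#' in this package use `beta` values of order 1000 mV so that jumps are of
#' order 1 mV (see the methods vignette for the unit convention).
#'
#' @param beta threshold increment scale in mV (may be a per-neuron vector).
#' @param tau_a adaptation time constant in ms (scalar or per-neuron).
#' @param dt simulation step in ms.
#' @return An object of class `sfa_params` with derived decay `rho`.
#' @export
sfa_params <- function(beta = 0, tau_a = 200, dt = 1) {
  stopifnot(is.numeric(beta), is.numeric(tau_a), all(tau_a > 0), dt > 0)
  rho <- exp(-dt / tau_a)
  stopifnot(all(rho > 0), all(rho < 1))
  structure(list(beta = beta, tau_a = tau_a, rho = rho, dt = dt),
            class = "sfa_params")
}

#' Short-term synaptic plasticity parameters (Tsodyks-Markram model)
#'
#' @param U baseline utilisation, in (0, 1).
#' @param F facilitation time constant, ms.
#' @param D depression time constant, ms.
#' @return An object of class `stp_params`.
#' @examples
#' stp_params(U = 0.25, F = 17, D = 671) # depression-dominant cortical values
#' @export
stp_params <- function(U, F, D) {
  stopifnot(is.numeric(U), all(U > 0), all(U < 1),
            is.numeric(F), all(F > 0), is.numeric(D), all(D > 0))
  structure(list(U = U, F = F, D = D), class = "stp_params")
}

#' Initial hidden state of a population of neurons
#'
#' All state variables start at their resting values: membrane potential 0 mV,
#' adaptation trace 0, no refractoriness, no spike.
#'
#' @param n number of neurons.
#' @return A list with numeric vectors `v`, `a`, `refr`, `z` of length `n`.
#' @export
neuron_state <- function(n = 1) {
  list(v = numeric(n), a = numeric(n), refr = integer(n), z = numeric(n))
}

#' Initial state of a set of STP synapses at their fixed point
#'
#' With no presynaptic spikes the facilitation and depression traces are zero,
#' so utilisation sits at its baseline (u = U) and resources at their
#' maximum (r = 1).
#'
#' @param params an [stp_params()] object.
#' @param n number of synapses (recycled against the parameter vectors).
#' @return A list with fields `u_prime`, `u`, `r_prime`, `r`.
#' @export
stp_state <- function(params, n = length(params$U)) {
  U <- rep_len(params$U, n)
  list(u_prime = numeric(n), u = U, r_prime = numeric(n), r = rep(1, n))
}
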