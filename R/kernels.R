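# Single-time-step reference kernels. These are the definitional, vectorised
# (over neurons / synapses) state updates; the batched simulator in src/ is
# required by the test suite to match them step for step.

#' Spike generation from membrane potential and threshold
#'
#' A neuron spikes when its normalised potential `(v - A)/A` is >= 0
#' (the Heaviside step with H(0) = 1). The normalised potential is also
#' returned because it is the argument of the surrogate derivative used in
#' training.
#'
#' @param v membrane potential, mV (vector).
#' @param A current firing threshold, mV (vector, must be positive).
#' @return A list with binary vector `z` and numeric vector `v_norm`.
#' @examples
#' spike_function(10, 10)$z        # exactly at threshold: spikes
#' spike_function(9.9, 10)$z       # just below: silent
#' @export
spike_function <- function(v, A) {
  if (any(!is.finite(v)) || any(!is.finite(A)))
    stop("spike_function: non-finite membrane potential or threshold")
  if (any(A <= 0)) stop("spike_function: threshold must be positive")
  v_norm <- (v - A) / A
  list(z = as.numeric(v_norm >= 0), v_norm = v_norm)
}

#' One discrete-time step of a (possibly adaptive-threshold) LIF neuron
#'
#' Advances the membrane potential by
#' `v' = alpha v + (1 - alpha) I`, tests the spike condition against the
#' threshold `A` (suppressed during the refractory period), and applies the
#' reset by subtracting `v_th * z * dt` for the spike emitted this step.
#' The input current `I` is already expressed as `R_m * I` in mV.
#'
#' @param state a [neuron_state()] list.
#' @param params a [cell_params()] object.
#' @param I input current for this step (vector, mV).
#' @param A firing threshold for this step; defaults to the fixed baseline
#'   `params$v_th` (pass the adaptive threshold from
#'   [sfa_threshold_step()] for neurons with SFA).
#' @return The updated state list; `$z` holds the spike emitted this step.
#' @export
lif_step <- function(state, params, I, A = params$v_th) {
  if (any(!is.finite(state$v)) || any(!is.finite(I)))
    stop("lif_step: non-finite state or input current")
  vp <- params$alpha * state$v + (1 - params$alpha) * I
  gate <- state$refr == 0
  sp <- spike_function(vp, rep_len(A, length(vp)))
  z <- sp$z * gate
  refr <- ifelse(state$refr > 0L, state$refr - 1L, 0L)
  refr[z > 0] <- params$n_ref
  list(v = vp - params$v_th * z * params$dt, a = state$a,
       refr = as.integer(refr), z = z, v_norm = sp$v_norm)
}

#' One step of the adaptive-threshold dynamics
#'
#' Updates the adaptation trace with the most recent spike,
#' `a' = rho a + (1 - rho) z dt`, and returns the threshold
#' `A = v_th + beta a'` that applies to the next membrane update. A negative
#' `beta` yields the enhanced-excitability (ELIF) model.
#'
#' @param state a [neuron_state()] list (fields `a` and `z` are used).
#' @param sfa an [sfa_params()] object.
#' @param cell a [cell_params()] object.
#' @return A list with threshold vector `A` (mV) and updated trace `a`.
#' @export
sfa_threshold_step <- function(state, sfa, cell) {
  a <- sfa$rho * state$a + (1 - sfa$rho) * state$z * sfa$dt
  list(A = cell$v_th + sfa$beta * a, a = a)
}

#' One step of the Tsodyks-Markram short-term plasticity dynamics
#'
#' Advances the facilitation trace u', utilisation u = U + u', depression
#' trace r' and available resources r = 1 - r' given the presynaptic spike
#' of the current step. The pre-update utilisation enters both increment
#' terms, matching the stated variable coupling of the model.
#'
#' @param state an [stp_state()] list.
#' @param params an [stp_params()] object.
#' @param z_pre presynaptic spike indicator (0/1 vector).
#' @param dt simulation step, ms.
#' @return The updated state list.
#' @export
stp_step <- function(state, params, z_pre, dt = 1) {
  eF <- exp(-dt / params$F)
  eD <- exp(-dt / params$D)
  u_now <- state$u
  u_prime <- eF * state$u_prime + params$U * (1 - u_now) * z_pre * dt
  r_prime <- eD * state$r_prime + u_now * (1 - state$r_prime) * z_pre * dt
  list(u_prime = u_prime, u = params$U + u_prime,
       r_prime = r_prime, r = 1 - r_prime)
}

#' Dynamic synaptic weight under short-term plasticity
#'
#' The momentary efficacy of a synapse is the static weight scaled by the
#' product of utilisation and available resources, `W * u * r`.
#'
#' @param W_rec static recurrent weight (vector or matrix).
#' @param state an [stp_state()] list.
#' @return The effective weight(s).
#' @export
effective_weight <- function(W_rec, state) {
  W_rec * state$u * state$r
}

#' Dampened pseudo-derivative of the spike function
#'
#' The surrogate used in the backward pass:
#' `gamma * max(0, 1 - |v_norm|)`, a triangular bump of height `gamma`
#' centred on the firing threshold. It is never used in the forward pass.
#'
#' @param v_norm normalised membrane potential `(v - A)/A`.
#' @param gamma damping factor, >= 0 (default 0.3).
#' @return Numeric vector of derivative values.
#' @examples
#' pseudo_derivative(0)            # peak: 0.3
#' pseudo_derivative(c(-2, 2))     # outside the support: 0
#' @export
pseudo_derivative <- function(v_norm, gamma = 0.3) {
  stopifnot(is.numeric(gamma), gamma >= 0)
  gamma * pmax(0, 1 - abs(v_norm))
}
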