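# Network assembly: weight initialisation and the snn_network container.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Gaussian weight initialisation
#'
#' Entries are drawn i.i.d. from `N(0, (w0 / sqrt(n_afferent))^2)`, where
#' `n_afferent` is the number of units feeding each layer and `w0` is the
#' normalisation constant (1 Volt). Input and recurrent weights are stored in
#' volts and converted to mV inside the dynamics, so that the published
#' learning-rate schedules act on weights of order `1/sqrt(n)`; the readout
#' weights are dimensionless scores. Signs are unconstrained. Readout biases
#' are zero-initialised.
#'
#' @param n_in,n_rec,n_out layer sizes (positive integers).
#' @param seed optional integer seed; the same seed reproduces the same
#'   matrices exactly.
#' @param w0 normalisation constant in volts.
#' @param self_connections keep recurrent self-connections? If `FALSE`
#'   (default) the diagonal of the recurrent matrix is zeroed and stays zero
#'   during training.
#' @return A list with matrices `Win` (n_rec x n_in), `Wrec` (n_rec x n_rec),
#'   `Wout` (n_out x n_rec) and bias vector `bout`.
#' @export
init_weights <- function(n_in, n_rec, n_out, seed = NULL, w0 = 1,
                         self_connections = FALSE) {
  stopifnot(n_in >= 1, n_rec >= 1, n_out >= 1)
  with_seed(seed, {
    Win <- matrix(rnorm(n_rec * n_in, sd = w0 / sqrt(n_in)), n_rec, n_in)
    Wrec <- matrix(rnorm(n_rec * n_rec, sd = w0 / sqrt(n_rec)), n_rec, n_rec)
    Wout <- matrix(rnorm(n_out * n_rec, sd = w0 / sqrt(n_rec)), n_out, n_rec)
    if (!self_connections) diag(Wrec) <- 0
    list(Win = Win, Wrec = Wrec, Wout = Wout, bout = numeric(n_out))
  })
}

#' Assemble a recurrent spiking network
#'
#' Builds a fully connected recurrent network of LIF neurons of which a
#' fraction `frac_sfa` carries an adaptive firing threshold (SFA; use a
#' negative `beta` for the enhanced-excitability ELIF variant). Optionally all
#' recurrent synapses are subject to short-term plasticity.
#'
#' @param n_in,n_rec,n_out numbers of input channels, recurrent neurons and
#'   readout neurons.
#' @param frac_sfa fraction of recurrent neurons with SFA, in `[0, 1]`. Which
#'   neurons adapt is a seeded random subset unless `sfa_mask` is given.
#' @param beta adaptation strength in mV (scalar; applied to the SFA subset).
#' @param tau_a adaptation time constant(s) in ms; scalar, or a vector of
#'   length `n_rec` (e.g. from [sample_tau_a()]).
#' @param tau_m,v_th,t_refr,dt passed to [cell_params()].
#' @param tau_out readout trace time constant in ms (low-pass filter applied
#'   to the network spikes before the linear readout).
#' @param w0 weight initialisation constant in volts, see [init_weights()].
#' @param self_connections keep recurrent self-connections?
#' @param stp optional [stp_params()] applied to all recurrent synapses
#'   (values may be per-presynaptic-neuron vectors).
#' @param sfa_mask optional logical vector of length `n_rec` selecting the
#'   adapting neurons explicitly.
#' @param seed integer seed controlling weight draws and the SFA subset.
#' @return An object of class `snn_network`.
#' @examples
#' net <- snn_network(40, 60, 1, frac_sfa = 1, beta = 1000, tau_a = 200, seed = 1)
#' net
#' @export
snn_network <- function(n_in, n_rec, n_out, frac_sfa = 1, beta = 1000,
                        tau_a = 200, tau_m = 20, v_th = 10, t_refr = 3,
                        dt = 1, tau_out = 20, w0 = 1,
                        self_connections = FALSE, stp = NULL,
                        sfa_mask = NULL, seed = NULL) {
  stopifnot(frac_sfa >= 0, frac_sfa <= 1, tau_out > 0)
  cell <- cell_params(tau_m = tau_m, v_th = v_th, t_refr = t_refr, dt = dt)
  w <- with_seed(seed, {
    w <- init_weights(n_in, n_rec, n_out, w0 = w0,
                      self_connections = self_connections)
    if (is.null(sfa_mask)) {
      n_sfa <- round(frac_sfa * n_rec)
      sfa_mask <- logical(n_rec)
      if (n_sfa > 0) sfa_mask[sample.int(n_rec, n_sfa)] <- TRUE
    }
    c(w, list(sfa_mask = sfa_mask))
  })
  sfa_mask <- w$sfa_mask
  stopifnot(length(sfa_mask) == n_rec)
  beta_vec <- ifelse(sfa_mask, beta, 0)
  tau_a_vec <- rep_len(tau_a, n_rec)
  sfa <- sfa_params(beta = beta_vec, tau_a = tau_a_vec, dt = dt)
  if (!is.null(stp)) {
    stopifnot(inherits(stp, "stp_params"))
    stp <- stp_params(U = rep_len(stp$U, n_rec), F = rep_len(stp$F, n_rec),
                      D = rep_len(stp$D, n_rec))
  }
  structure(list(
    n_in = n_in, n_rec = n_rec, n_out = n_out,
    Win = w$Win, Wrec = w$Wrec, Wout = w$Wout, bout = w$bout,
    cell = cell, sfa = sfa, sfa_mask = sfa_mask,
    alpha = rep_len(cell$alpha, n_rec),
    tau_out = tau_out, kappa = exp(-dt / tau_out),
    d_in = 1, d_rec = 1, w_scale = 1000,
    stp = stp, self_connections = self_connections, w0 = w0, seed = seed
  ), class = "snn_network")
}

#' @export
print.snn_network <- function(x, ...) {
  cat("Recurrent spiking network (", x$n_in, " -> ", x$n_rec, " -> ",
      x$n_out, ")\n", sep = "")
  n_sfa <- sum(x$sfa_mask)
  cat("  neurons with SFA: ", n_sfa, "/", x$n_rec, sep = "")
  if (n_sfa > 0) {
    b <- unique(x$sfa$beta[x$sfa_mask])
    ta <- range(x$sfa$tau_a[x$sfa_mask])
    cat("  (beta ", paste(signif(b, 3), collapse = "/"), " mV, tau_a ",
        if (diff(ta) == 0) paste0(ta[1], " ms") else
          paste0("[", ta[1], ", ", ta[2], "] ms"), ")", sep = "")
  }
  cat("\n  tau_m ", x$cell$tau_m, " ms, v_th ", x$cell$v_th, " mV, refractory ",
      x$cell$t_refr, " ms, dt ", x$cell$dt, " ms\n", sep = "")
  if (!is.null(x$stp)) cat("  short-term plasticity on recurrent synapses\n")
  invisible(x)
}

#' Synaptic input current for one time step
#'
#' Computes the weighted sum of delayed input and recurrent spikes,
#' `I_j(t) = sum_i Win_ji x_i(t - d_in) + sum_i Wrec_ji z_i(t - d_rec)`,
#' with histories zero-padded at the episode start. If the network has
#' short-term plasticity, time-dependent effective recurrent weights can be
#' supplied via `W_rec_eff`.
#'
#' @param spikes_in input spike history, a `T x n_in` matrix (rows = steps).
#' @param spikes_rec recurrent spike history, `T x n_rec`.
#' @param network an [snn_network()].
#' @param t time step (1-based row index) for which to compute the current.
#' @param W_rec_eff optional effective recurrent weight matrix for this step.
#' @return Numeric vector of length `n_rec` (current as R_m * I, mV).
#' @export
input_current <- function(spikes_in, spikes_rec, network, t,
                          W_rec_eff = network$Wrec) {
  if (ncol(spikes_in) != network$n_in || ncol(spikes_rec) != network$n_rec)
    stop("input_current: spike history shape does not match the network")
  ti <- t - network$d_in
  tr <- t - network$d_rec
  x <- if (ti >= 1) spikes_in[ti, ] else numeric(network$n_in)
  z <- if (tr >= 1) spikes_rec[tr, ] else numeric(network$n_rec)
  drop(network$Win %*% x + W_rec_eff %*% z) * (network$w_scale %||% 1000)
}
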