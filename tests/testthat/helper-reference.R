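# Reference simulator: a plain R loop over the exported single-step kernels.
# The compiled batched simulator must reproduce it bit for bit.

# x: T x n_in matrix (one episode). Returns T x n matrices of all state
# variables plus readout traces/outputs.
ref_simulate <- function(network, x, gamma = 0.3) {
  T_ <- nrow(x)
  n <- network$n_rec
  cell <- network$cell
  sfa <- network$sfa
  A_floor <- 0.01 * cell$v_th
  state <- neuron_state(n)
  stp_st <- if (!is.null(network$stp)) stp_state(network$stp, n) else NULL
  s <- numeric(n)
  Z <- V <- VP <- A_rec <- PD <- S <- matrix(0, T_, n)
  Y <- matrix(0, T_, network$n_out)
  z1 <- z2 <- numeric(n)
  zhist <- matrix(0, T_, n)
  for (t in seq_len(T_)) {
    if (t >= 3) {
      if (is.null(stp_st)) {
        I <- input_current(x, zhist, network, t - 1)
      } else {
        Weff <- sweep(network$Wrec, 2, stp_st$u * stp_st$r, "*")
        I <- input_current(x, zhist, network, t - 1, W_rec_eff = Weff)
        stp_st <- stp_step(stp_st, network$stp, z2, dt = cell$dt)
      }
    } else I <- numeric(n)
    thr <- sfa_threshold_step(list(a = state$a, z = z1), sfa, cell)
    A_t <- pmax(thr$A, A_floor)
    gate <- as.numeric(state$refr == 0)
    st <- lif_step(list(v = state$v, refr = state$refr), cell, I, A = A_t)
    state <- list(v = st$v, a = thr$a, refr = st$refr)
    s <- network$kappa * s + st$z
    Z[t, ] <- st$z
    V[t, ] <- st$v
    VP[t, ] <- st$v + cell$v_th * st$z * cell$dt
    A_rec[t, ] <- A_t
    PD[t, ] <- pseudo_derivative(st$v_norm, gamma) * gate
    S[t, ] <- s
    Y[t, ] <- drop(network$Wout %*% s + network$bout)
    zhist[t, ] <- st$z
    z2 <- z1
    z1 <- st$z
  }
  list(z = Z, v = V, vp = VP, A = A_rec, pd = PD, s = S, y = Y)
}

# Small random network used across tests.
tiny_network <- function(n_in = 5, n_rec = 8, n_out = 2, seed = 1, ...) {
  snn_network(n_in, n_rec, n_out, frac_sfa = 0.5, beta = 1500, tau_a = 150,
              tau_m = 20, v_th = 10, t_refr = 3, seed = seed, ...)
}

# Poisson input raster for one episode, T x n_in.
random_raster <- function(T_, n_in, rate_hz = 100, seed = NULL) {
  sfanet:::with_seed(seed, matrix(rbinom(T_ * n_in, 1, rate_hz / 1000),
                                  T_, n_in))
}

as_batch_array <- function(x) array(t(x), dim = c(1, ncol(x), nrow(x)))
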