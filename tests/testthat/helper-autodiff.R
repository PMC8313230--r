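# Independent gradient oracle for the surrogate-gradient backward pass.
#
# Forward-mode tangent propagation: for each scalar parameter, the exact
# directional derivative of the network outputs is pushed through the same
# forward graph, with the spike node carrying the dampened pseudo-derivative
# as its local derivative (and no gradient through the refractory gate).
# The smooth loss head is then differentiated by a central difference on the
# perturbed outputs. This never touches the reverse-mode code in src/.

# Primal pass storing everything the tangent recursion needs.
oracle_primal <- function(network, x, gamma = 0.3) {
  ref <- ref_simulate(network, x, gamma = gamma)
  ref
}

# Tangent of (y, z) w.r.t. one scalar parameter. `which` is one of
# "Win", "Wrec", "Wout", "bout"; (i, j) the entry.
oracle_tangent <- function(network, x, primal, which, i, j = 1,
                           gamma = 0.3) {
  T_ <- nrow(x); n <- network$n_rec; n_out <- network$n_out
  alpha <- network$alpha; rho <- network$sfa$rho; beta <- network$sfa$beta
  v_th <- network$cell$v_th; kappa <- network$kappa
  A_floor <- 0.01 * v_th
  dWin <- matrix(0, n, network$n_in); dWrec <- matrix(0, n, n)
  dWout <- matrix(0, n_out, n); dbout <- numeric(n_out)
  switch(which, Win = {dWin[i, j] <- 1}, Wrec = {dWrec[i, j] <- 1},
         Wout = {dWout[i, j] <- 1}, bout = {dbout[i] <- 1})
  dv <- da <- ds <- numeric(n)
  dz1 <- dz2 <- numeric(n)
  dY <- matrix(0, T_, n_out); dZ <- matrix(0, T_, n)
  ws <- network$w_scale
  for (t in seq_len(T_)) {
    if (t >= 3) {
      z2 <- primal$z[t - 2, ]
      dcur <- ws * drop(dWin %*% x[t - 2, ] + dWrec %*% z2 +
                          network$Wrec %*% dz2)
    } else dcur <- numeric(n)
    dvp <- alpha * dv + (1 - alpha) * dcur
    da <- rho * da + (1 - rho) * dz1
    A_t <- primal$A[t, ]
    dA <- ifelse(A_t > A_floor, beta * da, 0)
    vp <- primal$vp[t, ]
    dvn <- dvp / A_t - vp * dA / A_t^2
    dz <- primal$pd[t, ] * dvn
    dv <- dvp - v_th * dz
    ds <- kappa * ds + dz
    dY[t, ] <- drop(network$Wout %*% ds + dWout %*% primal$s[t, ] + dbout)
    dZ[t, ] <- dz
    dz2 <- dz1; dz1 <- dz
  }
  list(dy = dY, dz = dZ)
}

# Independent smooth loss head: summed-bit BCE over window means of y for
# sigmoid batches (plus optional rate regularisation on z), written as plain
# loops over episodes and windows. y, z are T x n matrices (single episode).
oracle_loss_head <- function(y, z, batch, reg_coeff = 0, target_rate = 10) {
  stopifnot(dim(batch$x)[1] == 1)
  wid <- batch$win_id[1, ]
  K <- batch$n_dec[1]
  total <- 0; G <- K
  for (k in seq_len(K)) {
    steps <- which(wid == k)
    for (jb in seq_len(dim(batch$targets)[3])) {
      ybar <- mean(y[steps, jb])
      p <- 1 / (1 + exp(-ybar))
      p <- min(max(p, 1e-7), 1 - 1e-7)
      tg <- batch$targets[1, k, jb]
      total <- total - (tg * log(p) + (1 - tg) * log(1 - p))
    }
  }
  loss <- total / G
  if (reg_coeff > 0) {
    rates <- colSums(z) / (nrow(z) / 1000)
    loss <- loss + reg_coeff * sum((rates - target_rate)^2)
  }
  loss
}

# Full oracle gradient for one parameter tensor entry via forward-mode
# tangents + central difference through the loss head.
oracle_grad_entry <- function(network, x, batch, primal, which, i, j,
                              gamma = 0.3, reg_coeff = 0, target_rate = 10,
                              h = 1e-3) {
  tg <- oracle_tangent(network, x, primal, which, i, j, gamma = gamma)
  h <- h / max(1, max(abs(tg$dy)), max(abs(tg$dz)))
  lp <- oracle_loss_head(primal$y + h * tg$dy, primal$z + h * tg$dz, batch,
                         reg_coeff, target_rate)
  lm <- oracle_loss_head(primal$y - h * tg$dy, primal$z - h * tg$dz, batch,
                         reg_coeff, target_rate)
  (lp - lm) / (2 * h)
}

# Oracle gradients for all trainable tensors of a small network.
oracle_gradients <- function(network, x, batch, gamma = 0.3, reg_coeff = 0,
                             target_rate = 10) {
  primal <- oracle_primal(network, x, gamma = gamma)
  g <- list(Win = matrix(0, network$n_rec, network$n_in),
            Wrec = matrix(0, network$n_rec, network$n_rec),
            Wout = matrix(0, network$n_out, network$n_rec),
            bout = numeric(network$n_out))
  for (i in seq_len(network$n_rec)) {
    for (j in seq_len(network$n_in))
      g$Win[i, j] <- oracle_grad_entry(network, x, batch, primal, "Win",
                                       i, j, gamma, reg_coeff, target_rate)
    for (j in seq_len(network$n_rec))
      g$Wrec[i, j] <- oracle_grad_entry(network, x, batch, primal, "Wrec",
                                        i, j, gamma, reg_coeff, target_rate)
  }
  for (i in seq_len(network$n_out)) {
    for (j in seq_len(network$n_rec))
      g$Wout[i, j] <- oracle_grad_entry(network, x, batch, primal, "Wout",
                                        i, j, gamma, reg_coeff, target_rate)
    g$bout[i] <- oracle_grad_entry(network, x, batch, primal, "bout", i, 1,
                                   gamma, reg_coeff, target_rate)
  }
  if (!network$self_connections) diag(g$Wrec) <- 0
  g
}
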