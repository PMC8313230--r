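# Losses, the Adam optimiser, and the surrogate-gradient BPTT update.

#' Training configuration
#'
#' Collects everything that determines a training run: the Adam schedule,
#' loss coefficients, the surrogate-gradient damping, and the seed. Defaults
#' correspond to the 1-D STORE-RECALL schedule (400 iterations, batch 64,
#' initial learning rate 0.01 decayed by 0.3 every 100 iterations, rate
#' regularisation 0.001 towards 10 Hz).
#'
#' @param iterations number of weight updates.
#' @param batch_size episodes per update.
#' @param lr initial learning rate.
#' @param lr_decay multiplicative decay factor.
#' @param decay_every iterations between decays (`Inf` = constant rate).
#' @param lr_ramp ramp the learning rate up over the first `lr_ramp_iters`
#'   iterations (used by the 20-D STORE-RECALL schedule)?
#' @param lr_ramp_from starting rate of the ramp.
#' @param lr_ramp_iters length of the ramp.
#' @param gamma damping of the pseudo-derivative.
#' @param reg_coeff firing-rate regularisation coefficient.
#' @param target_rate target firing rate, Hz.
#' @param entropy_coeff coefficient of the (subtracted) readout entropy bonus;
#'   0 disables it.
#' @param task_weight weight of the task loss in the total objective (1 by
#'   default; 0 trains on the regularisers alone).
#' @param stop_error stop early once the episode-level error on the training
#'   batch drops below this value (`NULL` = never).
#' @param clip_norm optional global gradient-norm clip (`NULL` = none).
#' @param seed integer seed; together with the config it fully determines the
#'   run.
#' @return An object of class `train_config`.
#' @export
train_config <- function(iterations = 400, batch_size = 64, lr = 0.01,
                         lr_decay = 0.3, decay_every = 100, lr_ramp = FALSE,
                         lr_ramp_from = 1e-5, lr_ramp_iters = 200,
                         gamma = 0.3, reg_coeff = 0.001, target_rate = 10,
                         entropy_coeff = 0, task_weight = 1,
                         stop_error = NULL, clip_norm = NULL, seed = 1) {
  stopifnot(iterations >= 0, batch_size >= 1, lr > 0, gamma >= 0,
            reg_coeff >= 0, target_rate >= 0, entropy_coeff >= 0,
            task_weight >= 0)
  structure(as.list(environment()), class = "train_config")
}

#' Firing-rate regularisation loss
#'
#' Penalises the squared deviation of each neuron's mean firing rate from a
#' target rate: `coeff * sum_j (rate_j - target)^2`, with the rate averaged
#' over time and batch.
#'
#' @param z spike raster: array `B x n_rec x T` or a single-episode
#'   `T x n_rec` matrix.
#' @param target_rate target rate in Hz.
#' @param coeff scale of the term.
#' @param dt simulation step, ms.
#' @return The scalar loss.
#' @export
rate_regularizer <- function(z, target_rate = 10, coeff = 0.001, dt = 1) {
  rate_reg_grad(z, target_rate, coeff, dt)$loss
}

rate_reg_grad <- function(z, target_rate, coeff, dt) {
  if (length(dim(z)) == 2) z <- array(t(z), dim = c(1, ncol(z), nrow(z)))
  B <- dim(z)[1]; n <- dim(z)[2]; T_ <- dim(z)[3]
  dt_s <- dt / 1000
  rates <- rowSums(matrix(z, B * n, T_))
  rates <- colSums(matrix(rates, B, n)) / (B * T_ * dt_s)
  list(loss = coeff * sum((rates - target_rate)^2),
       grad = 2 * coeff * (rates - target_rate) / (B * T_ * dt_s),
       rates = rates)
}

clamp_p <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

# Task loss, its gradients w.r.t. the readout traces (gy), directly w.r.t.
# spikes (gz, window-mean mode), and any direct readout-weight gradients.
loss_task <- function(fw, batch, network, entropy_coeff = 0) {
  K <- max(batch$n_dec)
  dims_y <- dim(fw$y)
  if (batch$mode == "sigmoid") {
    pool <- pool_windows(fw$y, batch$win_id, K)
    nb <- dim(batch$targets)[3]
    tg <- matrix(NA_real_, nrow(pool$mean), nb)
    for (j in seq_len(nb)) tg[, j] <- batch$targets[cbind(pool$b, pool$k, j)]
    G <- nrow(tg)
    p <- clamp_p(sigmoid(pool$mean))
    loss <- -sum(tg * log(p) + (1 - tg) * log(1 - p)) / G
    gdec <- (p - tg) / G
    bonus <- 0
    if (entropy_coeff > 0) {
      H <- -(p * log(p) + (1 - p) * log(1 - p))
      bonus <- entropy_coeff * mean(H)
      gdec <- gdec + entropy_coeff * pool$mean * p * (1 - p) / (G * nb)
    }
    gy <- scatter_windows(pool, gdec)
    pred <- (p >= (batch$threshold %||% 0.5)) * 1
    ok <- pred == tg
    dec_ok <- rowMeans(ok) == 1
    acc <- c(bit = mean(ok), decision = mean(dec_ok),
             episode = episode_acc(dec_ok, pool$b, dim(fw$y)[1]))
    list(loss = loss, gy = gy, gz = NULL, gWout = NULL, gbout = NULL,
         bonus = bonus, acc = acc)
  } else if (batch$mode == "softmax_end") {
    ends <- window_ends(batch)
    C <- dims_y[2]
    ymat <- t(vapply(seq_along(ends$t),
                     function(i) fw$y[ends$b[i], , ends$t[i]], numeric(C)))
    P <- softmax_rows(ymat)
    tg <- batch$targets[cbind(ends$b, ends$k)]
    G <- length(tg)
    loss <- -sum(log(clamp_p(P[cbind(seq_len(G), tg)]))) / G
    gdec <- P
    gdec[cbind(seq_len(G), tg)] <- gdec[cbind(seq_len(G), tg)] - 1
    gdec <- gdec / G
    gy <- array(0, dim = dims_y)
    for (i in seq_len(G)) gy[ends$b[i], , ends$t[i]] <- gdec[i, ]
    pred <- max.col(P, ties.method = "first")
    dec_ok <- pred == tg
    acc <- c(bit = mean(dec_ok), decision = mean(dec_ok),
             episode = episode_acc(dec_ok, ends$b, dims_y[1]))
    list(loss = loss, gy = gy, gz = NULL, gWout = NULL, gbout = NULL,
         bonus = 0, acc = acc)
  } else if (batch$mode == "softmax_winmean") {
    pool <- pool_windows(fw$z, batch$win_id, K)
    ywin <- sweep(pool$mean %*% t(network$Wout), 2, network$bout, "+")
    P <- softmax_rows(ywin)
    tg <- batch$targets[cbind(pool$b, pool$k)]
    G <- length(tg)
    loss <- -sum(log(clamp_p(P[cbind(seq_len(G), tg)]))) / G
    gdec <- P
    gdec[cbind(seq_len(G), tg)] <- gdec[cbind(seq_len(G), tg)] - 1
    gdec <- gdec / G
    gz <- scatter_windows(pool, gdec %*% network$Wout, C = network$n_rec)
    gy <- array(0, dim = dims_y)
    pred <- max.col(P, ties.method = "first")
    dec_ok <- pred == tg
    acc <- c(bit = mean(dec_ok), decision = mean(dec_ok),
             episode = episode_acc(dec_ok, pool$b, dims_y[1]))
    list(loss = loss, gy = gy, gz = gz, gWout = t(gdec) %*% pool$mean,
         gbout = colSums(gdec), bonus = 0, acc = acc)
  } else stop("unknown batch mode: ", batch$mode)
}

episode_acc <- function(dec_ok, b, B) {
  eok <- tapply(dec_ok, factor(b, levels = seq_len(B)), function(v) all(v))
  mean(unlist(eok), na.rm = TRUE)
}

#' Task loss of simulated readouts
#'
#' Computes the masked task loss for a simulated batch: mean per-decision
#' cross-entropy for softmax readouts, or summed per-bit binary cross-entropy
#' (averaged over decisions) for sigmoid readouts. Loss is evaluated only in
#' decision windows; a batch without any decision window is rejected.
#'
#' @param records an `snn_records` object from [simulate.snn_network()] whose
#'   batch carries targets, or a readout array together with `batch`.
#' @param batch the `snn_batch` (defaults to the one inside `records`).
#' @return The scalar loss.
#' @export
task_loss <- function(records, batch = records$batch) {
  if (is.null(batch)) stop("task_loss: no batch with targets available")
  fw <- list(y = records$y, z = records$z)
  loss_task(fw, batch, records$network)$loss
}

## ---------------------------------------------------------------------------
## Adam

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_update <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

## ---------------------------------------------------------------------------
## One BPTT update

#' One surrogate-gradient BPTT update
#'
#' Runs the forward pass on a task batch, forms the total loss (task loss +
#' firing-rate regularisation - entropy bonus), backpropagates through the
#' unrolled network dynamics with the dampened pseudo-derivative in place of
#' the spike derivative, and applies one Adam update to all trainable
#' tensors (input, recurrent and readout weights and the readout bias).
#'
#' @param network an [snn_network()] (no STP; gradients through short-term
#'   plasticity state are not supported).
#' @param batch an `snn_batch` with targets.
#' @param config a [train_config()].
#' @param opt_state Adam state from a previous call, or `NULL` to start.
#' @param lr learning rate for this step (defaults to `config$lr`).
#' @return A list with the updated `network`, `opt_state`, a `loss`
#'   breakdown (`task_loss`, `rate_reg`, `entropy_bonus`, `total`), training
#'   `accuracy`, per-neuron `rates`, and the raw `grads`.
#' @export
bptt_step <- function(network, batch, config, opt_state = NULL,
                      lr = config$lr) {
  if (!is.null(network$stp))
    stop("bptt_step: training networks with STP synapses is not supported")
  fw <- forward_pass(network, batch$x, gamma = config$gamma,
                     record_grad = TRUE)
  lt <- loss_task(fw, batch, network, config$entropy_coeff)
  tw <- config$task_weight %||% 1
  rr <- rate_reg_grad(fw$z, config$target_rate, config$reg_coeff,
                      network$cell$dt)
  gz_extra <- if (is.null(lt$gz)) array(0, dim = c(0, 0, 0)) else tw * lt$gz
  ws <- network$w_scale
  bw <- snn_backward_cpp(batch$x, fw$z, fw$vp, fw$A, fw$pd, fw$s, tw * lt$gy,
                         rr$grad, gz_extra, network$Win * ws,
                         network$Wrec * ws, network$Wout, network$alpha,
                         network$sfa$rho, network$sfa$beta,
                         network$cell$v_th, network$kappa)
  grads <- list(Win = bw$Win * ws, Wrec = bw$Wrec * ws,
                Wout = bw$Wout * 1 + tw * (lt$gWout %||% 0),
                bout = bw$bout + tw * (lt$gbout %||% 0))
  if (!network$self_connections) diag(grads$Wrec) <- 0
  if (any(vapply(grads, function(g) any(!is.finite(g)), logical(1))))
    stop("bptt_step: non-finite gradient")
  if (!is.null(config$clip_norm)) {
    gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
    if (gn > config$clip_norm)
      grads <- lapply(grads, function(g) g * config$clip_norm / gn)
  }
  params <- network[c("Win", "Wrec", "Wout", "bout")]
  if (is.null(opt_state)) opt_state <- adam_init(params)
  upd <- adam_update(params, grads, opt_state, lr)
  network[c("Win", "Wrec", "Wout", "bout")] <- upd$params
  loss <- list(task_loss = lt$loss, rate_reg = rr$loss,
               entropy_bonus = lt$bonus,
               total = tw * lt$loss + rr$loss - tw * lt$bonus)
  list(network = network, opt_state = upd$state, loss = loss,
       accuracy = lt$acc, rates = rr$rates, grads = grads)
}

# Gradients only (no optimiser step); used by tests and diagnostics.
bptt_gradients <- function(network, batch, config = train_config()) {
  fw <- forward_pass(network, batch$x, gamma = config$gamma,
                     record_grad = TRUE)
  lt <- loss_task(fw, batch, network, config$entropy_coeff)
  rr <- rate_reg_grad(fw$z, config$target_rate, config$reg_coeff,
                      network$cell$dt)
  gz_extra <- if (is.null(lt$gz)) array(0, dim = c(0, 0, 0)) else lt$gz
  ws <- network$w_scale
  bw <- snn_backward_cpp(batch$x, fw$z, fw$vp, fw$A, fw$pd, fw$s, lt$gy,
                         rr$grad, gz_extra, network$Win * ws,
                         network$Wrec * ws, network$Wout, network$alpha,
                         network$sfa$rho, network$sfa$beta,
                         network$cell$v_th, network$kappa)
  grads <- list(Win = bw$Win * ws, Wrec = bw$Wrec * ws,
                Wout = bw$Wout + (lt$gWout %||% 0),
                bout = bw$bout + (lt$gbout %||% 0))
  if (!network$self_connections) diag(grads$Wrec) <- 0
  list(grads = grads, loss = lt$loss + rr$loss - lt$bonus, task_loss = lt$loss)
}
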