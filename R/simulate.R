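# Batched episode simulation, readout decoding, and accuracy measures.

#' Readout specification
#'
#' Describes how continuous readout activations are turned into decisions.
#' Three modes are supported:
#' \describe{
#'   \item{`trace-sigmoid`}{network spikes are low-pass filtered with time
#'     constant `trace_tau`; per decision window the readout traces are
#'     averaged, passed through a sigmoid and thresholded (STORE-RECALL).}
#'   \item{`trace-softmax`}{as above, but the softmax of the readout values at
#'     the end of each decision window picks the output symbol
#'     (duplication/reversal, sequential MNIST).}
#'   \item{`window-mean-softmax`}{the readout sees the mean firing rate of
#'     each network neuron over the decision window; softmax over the linear
#'     readout picks the symbol (12AX).}
#' }
#'
#' @param mode one of the three modes above.
#' @param trace_tau low-pass time constant in ms.
#' @param window decision window length in ms (fixed-window tasks).
#' @param threshold sigmoid decision threshold.
#' @return An object of class `readout_spec`.
#' @export
readout_spec <- function(mode = c("trace-sigmoid", "trace-softmax",
                                  "window-mean-softmax"),
                         trace_tau = 20, window = NULL, threshold = 0.5) {
  mode <- match.arg(mode)
  stopifnot(trace_tau > 0, is.null(window) || window > 0)
  structure(list(mode = mode, trace_tau = trace_tau, window = window,
                 threshold = threshold), class = "readout_spec")
}

# Forward roll-out through the compiled kernel. `x` is B x n_in x T.
forward_pass <- function(network, x, gamma = 0.3, record_grad = FALSE) {
  stopifnot(length(dim(x)) == 3, dim(x)[2] == network$n_in)
  if (network$cell$dt != 1)
    stop("the batched simulator requires dt = 1 ms")
  use_stp <- !is.null(network$stp)
  if (use_stp) {
    U <- network$stp$U
    eF <- exp(-network$cell$dt / network$stp$F)
    eD <- exp(-network$cell$dt / network$stp$D)
  } else {
    U <- eF <- eD <- numeric(0)
  }
  snn_forward_cpp(x, network$Win * network$w_scale,
                  network$Wrec * network$w_scale, network$Wout, network$bout,
                  network$alpha, network$sfa$rho, network$sfa$beta,
                  network$cell$v_th, network$cell$n_ref, network$kappa,
                  gamma, record_grad, use_stp, U, eF, eD)
}

#' Simulate episodes of a spiking network
#'
#' Rolls the network forward over a batch of input spike rasters and returns
#' the full trial record: spikes, adaptive thresholds, membrane potentials,
#' readout traces and (when a task batch is supplied) per-window decisions.
#'
#' @param object an [snn_network()].
#' @param nsim number of episodes to draw from `task` when no explicit inputs
#'   are given.
#' @param seed optional integer seed (controls task sampling).
#' @param batch an `snn_batch` as produced by the task generators; its inputs
#'   and decision windows are used.
#' @param x alternatively, a raw input array `B x n_in x T` or a single
#'   episode matrix `T x n_in`.
#' @param task an `snn_task`; used with `nsim` to sample a fresh batch.
#' @param ... unused.
#' @return An object of class `snn_records`: a list with arrays `z`, `A`, `v`
#'   (all `B x n_rec x T`), readout `y` (`B x n_out x T`), per-neuron mean
#'   rates in Hz (`B x n_rec`), the input `x`, and decisions (activations,
#'   predictions, targets) when a batch was given.
#' @export
simulate.snn_network <- function(object, nsim = 1, seed = NULL, batch = NULL,
                                 x = NULL, task = NULL, ...) {
  if (is.null(batch) && is.null(x)) {
    if (is.null(task)) stop("simulate: provide a batch, an input array, or a task")
    batch <- with_seed(seed, task$sample(nsim))
  }
  if (!is.null(batch)) x <- batch$x
  if (length(dim(x)) == 2) {
    x <- array(t(x), dim = c(1, ncol(x), nrow(x))) # T x n_in -> 1 x n_in x T
  }
  fw <- forward_pass(object, x)
  B <- dim(x)[1]; T_ <- dim(x)[3]
  dt_s <- object$cell$dt / 1000
  rates <- matrix(rowSums(matrix(fw$z, B * object$n_rec, T_)),
                  B, object$n_rec) / (T_ * dt_s)
  rec <- list(x = x, z = fw$z, A = fw$A, v = fw$v, y = fw$y, rates = rates,
              network = object, batch = batch)
  if (!is.null(batch)) {
    rec$decisions <- decode_decisions(fw$y, fw$z, object, batch)
  }
  structure(rec, class = "snn_records")
}

#' @export
print.snn_records <- function(x, ...) {
  d <- dim(x$z)
  cat("snn_records: ", d[1], " episode(s), ", d[2], " neurons, ", d[3],
      " ms\n", sep = "")
  cat("  mean firing rate: ", round(mean(x$rates), 2), " Hz\n", sep = "")
  if (!is.null(x$decisions)) {
    ok <- x$decisions$correct
    cat("  decision accuracy: ", round(100 * mean(ok, na.rm = TRUE), 2),
        "% over ", sum(!is.na(ok)), " decisions\n", sep = "")
  }
  invisible(x)
}

# Pool an array B x C x T over decision windows given win_id (B x T, 0 = no
# window). Returns per-decision means plus the bookkeeping needed to scatter
# gradients back onto member time steps.
pool_windows <- function(arr, win_id, K) {
  B <- dim(arr)[1]; C <- dim(arr)[2]; T_ <- dim(arr)[3]
  m <- matrix(aperm(arr, c(1, 3, 2)), B * T_, C)
  sel <- which(win_id > 0)
  if (length(sel) == 0) stop("no decision windows in batch")
  b <- ((sel - 1) %% B) + 1
  g <- (b - 1) * K + win_id[sel]
  sums <- rowsum(m[sel, , drop = FALSE], g)
  len <- as.vector(rowsum(rep(1, length(sel)), g))
  gid <- as.integer(rownames(sums))
  list(mean = sums / len, len = len, gid = gid,
       b = (gid - 1) %/% K + 1, k = (gid - 1) %% K + 1,
       sel = sel, sel_g = g, B = B, C = C, T = T_, K = K)
}

# Scatter per-decision gradients (G x C) back to a B x C x T array, dividing
# by window length (gradient of a window mean).
scatter_windows <- function(pool, gdec, C = ncol(gdec)) {
  m <- matrix(0, pool$B * pool$T, C)
  row <- match(pool$sel_g, pool$gid)
  m[pool$sel, ] <- gdec[row, , drop = FALSE] / pool$len[row]
  aperm(array(m, dim = c(pool$B, pool$T, C)), c(1, 3, 2))
}

softmax_rows <- function(m) {
  e <- exp(m - apply(m, 1, max))
  e / rowSums(e)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Turn readout traces / spikes into per-window activations and predictions.
decode_decisions <- function(y, z, network, batch) {
  K <- max(batch$n_dec)
  mode <- batch$mode
  if (mode == "sigmoid") {
    pool <- pool_windows(y, batch$win_id, K)
    act <- sigmoid(pool$mean)                      # G x n_bits
    pred <- (act >= batch$threshold %||% 0.5) * 1
    tg <- matrix(NA_real_, nrow(act), ncol(act))
    for (j in seq_len(ncol(act)))
      tg[, j] <- batch$targets[cbind(pool$b, pool$k, j)]
    correct <- rowMeans(pred == tg) == 1
    bit_correct <- pred == tg
    list(mode = mode, activations = act, predicted = pred, targets = tg,
         b = pool$b, k = pool$k, correct = correct,
         bit_accuracy = mean(bit_correct), pool = pool)
  } else if (mode == "softmax_end") {
    ends <- window_ends(batch)                     # list(b, k, t)
    ymat <- t(vapply(seq_along(ends$t), function(i) y[ends$b[i], , ends$t[i]],
                     numeric(dim(y)[2])))
    act <- softmax_rows(ymat)
    pred <- max.col(act, ties.method = "first")
    tg <- batch$targets[cbind(ends$b, ends$k)]
    list(mode = mode, activations = act, predicted = pred, targets = tg,
         b = ends$b, k = ends$k, correct = pred == tg)
  } else if (mode == "softmax_winmean") {
    pool <- pool_windows(z, batch$win_id, K)
    ywin <- pool$mean %*% t(network$Wout)
    ywin <- sweep(ywin, 2, network$bout, "+")
    act <- softmax_rows(ywin)
    pred <- max.col(act, ties.method = "first")
    tg <- batch$targets[cbind(pool$b, pool$k)]
    list(mode = mode, activations = act, predicted = pred, targets = tg,
         b = pool$b, k = pool$k, correct = pred == tg, pool = pool)
  } else stop("unknown readout mode: ", mode)
}

# Last time step of each decision window.
window_ends <- function(batch) {
  B <- nrow(batch$win_id); T_ <- ncol(batch$win_id)
  b <- integer(0); k <- integer(0); tt <- integer(0)
  for (bi in seq_len(B)) {
    w <- batch$win_id[bi, ]
    for (ki in seq_len(batch$n_dec[bi])) {
      b <- c(b, bi); k <- c(k, ki); tt <- c(tt, max(which(w == ki)))
    }
  }
  list(b = b, k = k, t = tt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fraction of correct predictions
#'
#' Measures task performance at one of three granularities: per decision
#' (each output symbol scored independently), per episode (an episode counts
#' only if every one of its decisions is correct -- the "success rate"), or
#' per bit (multi-bit sigmoid decisions, each bit scored independently).
#'
#' @param predictions,targets aligned decision sequences: either matrices
#'   `B x K` of symbol indices (NA-padded where episodes have fewer
#'   decisions) or `B x K x n_bits` binary arrays.
#' @param granularity `"decision"`, `"episode"`, or `"bit"`.
#' @return A fraction in `[0, 1]`.
#' @export
success_rate <- function(predictions, targets,
                         granularity = c("decision", "episode", "bit")) {
  granularity <- match.arg(granularity)
  if (!identical(dim(predictions), dim(targets)))
    stop("success_rate: predictions and targets have different shapes")
  ok <- predictions == targets
  if (length(dim(ok)) == 3) {
    dec_ok <- apply(ok, c(1, 2), function(v) all(v))
  } else dec_ok <- ok
  switch(granularity,
    bit = mean(ok, na.rm = TRUE),
    decision = mean(dec_ok, na.rm = TRUE),
    episode = {
      eok <- apply(dec_ok, 1, function(v) all(v, na.rm = TRUE) &&
                     any(!is.na(v)))
      mean(eok)
    })
}
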