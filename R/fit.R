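# The model-fitting front end: snn() trains a network on a task and returns
# a classed fit object with the usual methods.

#' Train a spiking network on a temporal-computing task
#'
#' The main entry point of the package. Builds (or takes) a recurrent
#' spiking network, then optimises its input, recurrent and readout weights
#' with surrogate-gradient backpropagation through time on batches drawn
#' from the task generator, following the schedule in `train`.
#'
#' The total loss is the task loss (cross-entropy or per-bit binary
#' cross-entropy, evaluated only in decision windows), plus a firing-rate
#' regulariser pulling every neuron's mean rate towards a target, minus an
#' optional entropy bonus. The run is fully reproducible from
#' `train$seed`.
#'
#' @param task an `snn_task` from one of the task generators
#'   ([store_recall_task()], [store_recall_task_20d()], [task_12ax()],
#'   [duplication_task()], [smnist_task()]).
#' @param train a [train_config()].
#' @param network an [snn_network()]; if `NULL`, one is built from the task
#'   geometry and the arguments in `...` (e.g. `n_rec`, `frac_sfa`, `beta`,
#'   `tau_a`). The readout trace constant is taken from the task's readout
#'   specification.
#' @param verbose print progress every `verbose` iterations (0 = silent).
#' @param ... passed to [snn_network()] when `network` is `NULL`.
#' @return An object of class `snn_fit` with components `network` (trained),
#'   `curve` (per-iteration losses, accuracy, mean rate, learning rate),
#'   `task`, `config`, and flags `converged`/`diverged`.
#' @examples
#' \donttest{
#' task <- store_recall_task()
#' fit <- snn(task, train = train_config(iterations = 5, batch_size = 8),
#'            n_rec = 20, frac_sfa = 1, beta = 1000, tau_a = 200)
#' fit
#' }
#' @export
snn <- function(task, train = train_config(), network = NULL, verbose = 0,
                ...) {
  stopifnot(inherits(task, "snn_task"), inherits(train, "train_config"))
  if (is.null(network)) {
    args <- list(...)
    if (is.null(args$n_rec)) args$n_rec <- 100
    if (is.null(args$seed)) args$seed <- train$seed
    network <- do.call(snn_network,
                       c(list(n_in = task$n_in, n_out = task$n_out,
                              tau_out = task$readout$trace_tau), args))
  }
  stopifnot(inherits(network, "snn_network"),
            network$n_in == task$n_in, network$n_out == task$n_out)

  curve <- vector("list", train$iterations)
  opt_state <- NULL
  converged <- FALSE; diverged <- FALSE
  initial_total <- NA_real_; n_bad <- 0
  iterations_run <- 0L

  set.seed(train$seed)
  for (i in seq_len(train$iterations)) {
    lr_i <- schedule_lr(train, i)
    batch <- task$sample(train$batch_size)
    step <- bptt_step(network, batch, train, opt_state, lr = lr_i)
    network <- step$network; opt_state <- step$opt_state
    iterations_run <- i
    curve[[i]] <- data.frame(
      iteration = i, total = step$loss$total, task_loss = step$loss$task_loss,
      rate_reg = step$loss$rate_reg, entropy_bonus = step$loss$entropy_bonus,
      acc_decision = step$accuracy["decision"],
      acc_episode = step$accuracy["episode"],
      acc_bit = step$accuracy["bit"],
      mean_rate = mean(step$rates), lr = lr_i)
    if (verbose > 0 && i %% verbose == 0)
      message(sprintf("iter %4d  loss %.4f  acc %.3f  rate %.1f Hz", i,
                      step$loss$total, step$accuracy["decision"],
                      mean(step$rates)))
    if (is.na(initial_total)) initial_total <- step$loss$total
    if (step$loss$total > 10 * initial_total) {
      n_bad <- n_bad + 1
      if (n_bad >= 50) {
        diverged <- TRUE
        warning("training diverged at iteration ", i, "; stopping")
        break
      }
    } else n_bad <- 0
    if (!is.null(train$stop_error) &&
        (1 - step$accuracy["episode"]) < train$stop_error) {
      converged <- TRUE
      break
    }
  }
  curve <- if (iterations_run > 0) do.call(rbind, curve[seq_len(iterations_run)])
           else data.frame()
  rownames(curve) <- NULL
  structure(list(network = network, curve = curve, task = task,
                 config = train, converged = converged, diverged = diverged,
                 iterations_run = iterations_run), class = "snn_fit")
}

schedule_lr <- function(train, i) {
  if (isTRUE(train$lr_ramp) && i <= train$lr_ramp_iters) {
    exp(seq(log(train$lr_ramp_from), log(train$lr),
            length.out = train$lr_ramp_iters))[i]
  } else {
    train$lr * train$lr_decay^(floor((i - 1) / train$decay_every))
  }
}

sample_task_batch <- function(task, n, test = FALSE) {
  if ("test" %in% names(formals(task$sample))) task$sample(n, test = test)
  else task$sample(n)
}

#' Evaluate a network on freshly generated task episodes
#'
#' Simulates the network on `n` new episodes (in chunks) and accumulates
#' accuracy at all three granularities.
#'
#' @param network an [snn_network()].
#' @param task an `snn_task`.
#' @param n number of test episodes.
#' @param batch_size episodes per simulation chunk.
#' @param seed optional seed for the test episodes.
#' @param test draw from the task's held-out test dictionary where the task
#'   distinguishes one (20-D STORE-RECALL).
#' @return A list with `accuracy` (named: decision, episode, bit),
#'   `n_episodes`, `n_decisions` and `mean_rate` (Hz).
#' @export
evaluate_network <- function(network, task, n = 2048, batch_size = 128,
                             seed = NULL, test = TRUE) {
  with_seed(seed, {
    done <- 0
    dec_ok <- numeric(0); bit_ok <- numeric(0); ep_ok <- numeric(0)
    rate_sum <- 0
    while (done < n) {
      nb <- min(batch_size, n - done)
      batch <- sample_task_batch(task, nb, test = test)
      rec <- simulate(network, batch = batch)
      d <- rec$decisions
      ok <- d$predicted == d$targets
      if (is.matrix(ok) && ncol(ok) > 1 && d$mode == "sigmoid") {
        bit_ok <- c(bit_ok, as.vector(ok))
        dok <- rowMeans(ok) == 1
      } else dok <- as.vector(ok)
      dec_ok <- c(dec_ok, dok)
      eok <- tapply(dok, factor(d$b, levels = seq_len(nb)),
                    function(v) all(v))
      ep_ok <- c(ep_ok, unlist(eok))
      rate_sum <- rate_sum + sum(rec$rates)
      done <- done + nb
    }
    if (length(bit_ok) == 0) bit_ok <- dec_ok
    list(accuracy = c(decision = mean(dec_ok, na.rm = TRUE),
                      episode = mean(ep_ok, na.rm = TRUE),
                      bit = mean(bit_ok, na.rm = TRUE)),
         n_episodes = n, n_decisions = length(dec_ok),
         mean_rate = rate_sum / (n * network$n_rec))
  })
}

#' @export
print.snn_fit <- function(x, ...) {
  cat("snn_fit: network trained on task '", x$task$name, "'\n", sep = "")
  print(x$network)
  if (nrow(x$curve) > 0) {
    last <- x$curve[nrow(x$curve), ]
    cat(sprintf("  %d iterations, final loss %.4f, training accuracy %.3f\n",
                x$iterations_run, last$total, last$acc_decision))
  }
  if (x$converged) cat("  stopped early: training error below threshold\n")
  if (x$diverged) cat("  WARNING: training diverged\n")
  invisible(x)
}

#' @export
summary.snn_fit <- function(object, n_eval = 0, seed = NULL, ...) {
  out <- list(fit = object)
  if (n_eval > 0)
    out$evaluation <- evaluate_network(object$network, object$task,
                                       n = n_eval, seed = seed)
  class(out) <- "summary.snn_fit"
  out
}

#' @export
print.summary.snn_fit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$evaluation)) {
    acc <- x$evaluation$accuracy
    cat(sprintf("  test accuracy over %d episodes: decision %.2f%%, episode %.2f%%, bit %.2f%%\n",
                x$evaluation$n_episodes, 100 * acc["decision"],
                100 * acc["episode"], 100 * acc["bit"]))
    cat(sprintf("  mean firing rate %.2f Hz\n", x$evaluation$mean_rate))
  }
  invisible(x)
}

#' @export
coef.snn_fit <- function(object, ...) {
  object$network[c("Win", "Wrec", "Wout", "bout")]
}

#' Predict on freshly generated task episodes
#'
#' @param object an `snn_fit`.
#' @param n number of test episodes.
#' @param seed optional seed.
#' @param test use the task's held-out test distribution where available.
#' @param batch_size simulation chunk size.
#' @param ... unused.
#' @return The list from [evaluate_network()].
#' @export
predict.snn_fit <- function(object, n = 2048, seed = NULL, test = TRUE,
                            batch_size = 128, ...) {
  evaluate_network(object$network, object$task, n = n, seed = seed,
                   test = test, batch_size = batch_size)
}

#' @export
plot.snn_fit <- function(x, ...) {
  stopifnot(nrow(x$curve) > 0)
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  plot(x$curve$iteration, x$curve$total, type = "l", xlab = "iteration",
       ylab = "loss", main = "training loss", ...)
  plot(x$curve$iteration, x$curve$acc_decision, type = "l", ylim = c(0, 1),
       xlab = "iteration", ylab = "accuracy", main = "training accuracy", ...)
  invisible(x)
}

#' @export
simulate.snn_fit <- function(object, nsim = 1, seed = NULL, ...) {
  simulate(object$network, nsim = nsim, seed = seed, task = object$task, ...)
}
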