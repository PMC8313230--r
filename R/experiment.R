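# Reproducible experiment driver: specs, tau_a sampling, multi-seed runs.

#' Sample per-neuron adaptation time constants
#'
#' @param distribution `"fixed"`, `"uniform"`, or `"power-law"` (density
#'   proportional to `tau^(-exponent)` truncated to `[lower, upper]`).
#' @param n number of neurons.
#' @param value time constant for the fixed distribution, ms.
#' @param lower,upper support bounds, ms (the lower cutoff also regularises
#'   the power law near zero).
#' @param exponent power-law exponent (1 gives a log-uniform draw).
#' @param seed optional integer seed.
#' @return Numeric vector of length `n`, within the support.
#' @export
sample_tau_a <- function(distribution = c("fixed", "uniform", "power-law"),
                         n, value = 200, lower = 1, upper = 8000,
                         exponent = 1, seed = NULL) {
  distribution <- match.arg(distribution)
  stopifnot(n >= 1, lower > 0, upper > lower || distribution == "fixed")
  with_seed(seed, switch(distribution,
    fixed = rep(value, n),
    uniform = runif(n, lower, upper),
    `power-law` = {
      u <- runif(n)
      if (abs(exponent - 1) < 1e-12) {
        lower * (upper / lower)^u
      } else {
        k <- 1 - exponent
        (lower^k + u * (upper^k - lower^k))^(1 / k)
      }
    }))
}

task_registry <- function() {
  list(store_recall_1d = store_recall_task,
       store_recall_20d = store_recall_task_20d,
       `12ax` = task_12ax,
       duplication_reversal = duplication_task)
}

#' Specification of a full experiment
#'
#' A serialisable description of one experiment: the task and its
#' parameters, the network architecture, the training schedule, and the
#' seeds. Re-running a spec reproduces the logged metrics exactly.
#'
#' @param task task name: `"store_recall_1d"`, `"store_recall_20d"`,
#'   `"12ax"`, or `"duplication_reversal"`.
#' @param task_args list of arguments for the task constructor.
#' @param network list of [snn_network()] arguments (sizes, `frac_sfa`,
#'   `beta`, `tau_a` or a `tau_a_dist` list for [sample_tau_a()]).
#' @param train list of [train_config()] arguments (the per-seed `seed` is
#'   filled in by [run_experiment()]).
#' @param seeds integer vector of network initialisation seeds.
#' @param eval_episodes test episodes per seed.
#' @param label free-text label.
#' @param desk_scale logical: `TRUE` for configurations that run on a single
#'   CPU in minutes; the full published schedules are `FALSE`.
#' @return An object of class `experiment_spec`.
#' @export
experiment_spec <- function(task, task_args = list(), network = list(),
                            train = list(), seeds = 1, eval_episodes = 2048,
                            label = task, desk_scale = TRUE) {
  bad <- character(0)
  if (!is.character(task) || !task %in% names(task_registry()))
    bad <- c(bad, "task")
  for (nm in c("task_args", "network", "train"))
    if (!is.list(get(nm))) bad <- c(bad, nm)
  if (!is.numeric(seeds) || length(seeds) < 1) bad <- c(bad, "seeds")
  if (!is.numeric(eval_episodes) || eval_episodes < 1)
    bad <- c(bad, "eval_episodes")
  ok_net <- union(names(formals(snn_network)), "tau_a_dist")
  bad_net <- setdiff(names(network), ok_net)
  if (length(bad_net)) bad <- c(bad, paste0("network$", bad_net))
  bad_tr <- setdiff(names(train), names(formals(train_config)))
  if (length(bad_tr)) bad <- c(bad, paste0("train$", bad_tr))
  if (length(bad))
    stop("experiment_spec: invalid field(s): ", paste(bad, collapse = ", "))
  structure(list(task = task, task_args = task_args, network = network,
                 train = train, seeds = seeds,
                 eval_episodes = eval_episodes, label = label,
                 desk_scale = desk_scale), class = "experiment_spec")
}

#' @export
print.experiment_spec <- function(x, ...) {
  cat("experiment_spec '", x$label, "': task ", x$task, ", ",
      length(x$seeds), " seed(s), ", x$eval_episodes, " test episodes",
      if (!x$desk_scale) " [full scale: not intended for a single CPU]",
      "\n", sep = "")
  invisible(x)
}

build_experiment_network <- function(spec, task, seed) {
  net_args <- spec$network
  if (!is.null(net_args$tau_a_dist)) {
    d <- net_args$tau_a_dist
    net_args$tau_a <- do.call(sample_tau_a,
                              c(d, list(n = net_args$n_rec %||% 100,
                                        seed = seed + 7)))
    net_args$tau_a_dist <- NULL
  }
  do.call(snn_network, c(list(n_in = task$n_in, n_out = task$n_out,
                              tau_out = task$readout$trace_tau, seed = seed),
                         net_args))
}

#' Run an experiment over its seeds
#'
#' For each seed: builds the task and network, trains with [snn()],
#' evaluates on freshly generated test episodes, and (optionally) writes
#' checkpoints, learning curves and a summary table under `out_dir`. The
#' summary reports mean and standard deviation over seeds.
#'
#' @param spec an [experiment_spec()].
#' @param out_dir optional output directory.
#' @param evaluate_only a saved checkpoint path (or an [snn_network()]); if
#'   given, no training happens and the network weights are not modified.
#' @param verbose progress printing interval for [snn()].
#' @return A list with per-seed `fits`, per-seed `evaluations`, and the
#'   `summary` data frame.
#' @export
run_experiment <- function(spec, out_dir = NULL, evaluate_only = NULL,
                           verbose = 0) {
  stopifnot(inherits(spec, "experiment_spec"))
  task <- do.call(task_registry()[[spec$task]], spec$task_args)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  fits <- list(); evals <- list()
  for (s in spec$seeds) {
    key <- paste0("seed", s)
    if (!is.null(evaluate_only)) {
      net <- if (inherits(evaluate_only, "snn_network")) evaluate_only
             else read_snn(evaluate_only)
      fit <- NULL
    } else {
      net <- build_experiment_network(spec, task, s)
      tr <- do.call(train_config, c(spec$train, list(seed = s)))
      fit <- snn(task, train = tr, network = net, verbose = verbose)
      net <- fit$network
      if (!is.null(out_dir)) {
        write_snn(net, file.path(out_dir, paste0(key, "_checkpoint.json")))
        write.csv(fit$curve, file.path(out_dir, paste0(key, "_curve.csv")),
                  row.names = FALSE)
      }
    }
    ev <- evaluate_network(net, task, n = spec$eval_episodes,
                           seed = s + 1000, test = TRUE)
    fits[[key]] <- fit
    evals[[key]] <- ev
  }
  acc <- t(vapply(evals, function(e) e$accuracy, numeric(3)))
  rates <- vapply(evals, function(e) e$mean_rate, numeric(1))
  summary <- data.frame(
    label = spec$label, n_seeds = length(spec$seeds),
    eval_episodes = spec$eval_episodes,
    acc_decision_mean = mean(acc[, "decision"]),
    acc_decision_sd = if (nrow(acc) > 1) sd(acc[, "decision"]) else NA_real_,
    acc_episode_mean = mean(acc[, "episode"]),
    acc_episode_sd = if (nrow(acc) > 1) sd(acc[, "episode"]) else NA_real_,
    acc_bit_mean = mean(acc[, "bit"]),
    acc_bit_sd = if (nrow(acc) > 1) sd(acc[, "bit"]) else NA_real_,
    mean_rate_hz = mean(rates))
  if (!is.null(out_dir))
    write.csv(summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
  list(fits = fits, evaluations = evals, summary = summary)
}

#' Published experiment configurations
#'
#' Returns ready-made [experiment_spec()]s. `"paper"` variants carry the
#' full published schedules (these need hours of compute and are marked
#' `desk_scale = FALSE`); `"smoke"` variants are scaled-down versions
#' (shorter episodes, smaller networks, fewer iterations) that train to
#' far-above-chance performance within minutes on one CPU.
#'
#' @param name one of `"store_recall_1d_200ms"`, `"store_recall_1d_200ms_lif"`,
#'   `"store_recall_20d"`, `"12ax"`, `"duplication_reversal"`.
#' @param scale `"paper"` or `"smoke"`.
#' @param seeds seeds to run.
#' @return An [experiment_spec()].
#' @export
paper_experiment <- function(name = c("store_recall_1d_200ms",
                                      "store_recall_1d_200ms_lif",
                                      "store_recall_20d", "12ax",
                                      "duplication_reversal"),
                             scale = c("paper", "smoke"), seeds = 1:5) {
  name <- match.arg(name)
  scale <- match.arg(scale)
  full <- switch(name,
    store_recall_1d_200ms = experiment_spec(
      task = "store_recall_1d",
      task_args = list(n_steps = 12, step_ms = 50),
      network = list(n_rec = 60, frac_sfa = 1, beta = 2500, tau_a = 200,
                     t_refr = 3),
      train = list(iterations = 400, batch_size = 64, lr = 0.01,
                   lr_decay = 0.3, decay_every = 100, reg_coeff = 0.001,
                   target_rate = 10),
      seeds = seeds, eval_episodes = 2048, label = name),
    store_recall_1d_200ms_lif = experiment_spec(
      task = "store_recall_1d",
      task_args = list(n_steps = 12, step_ms = 50),
      network = list(n_rec = 60, frac_sfa = 0, t_refr = 3),
      train = list(iterations = 400, batch_size = 64, lr = 0.01,
                   lr_decay = 0.3, decay_every = 100, reg_coeff = 0.001,
                   target_rate = 10),
      seeds = seeds, eval_episodes = 2048, label = name),
    store_recall_20d = experiment_spec(
      task = "store_recall_20d",
      network = list(n_rec = 500, frac_sfa = 1, beta = 4000, tau_a = 800,
                     t_refr = 3),
      train = list(iterations = 4000, batch_size = 256, lr = 0.01,
                   lr_decay = 0.8, decay_every = 200, lr_ramp = TRUE,
                   lr_ramp_from = 1e-5, lr_ramp_iters = 200,
                   reg_coeff = 0.001, target_rate = 10,
                   entropy_coeff = 0.3, stop_error = 0.01),
      seeds = seeds, eval_episodes = 512, label = name,
      desk_scale = FALSE),
    `12ax` = experiment_spec(
      task = "12ax",
      network = list(n_rec = 200, frac_sfa = 0.5, beta = 1700,
                     tau_a_dist = list(distribution = "uniform", lower = 1,
                                       upper = 13500),
                     v_th = 30, t_refr = 5),
      train = list(iterations = 10000, batch_size = 20, lr = 0.001,
                   decay_every = Inf, reg_coeff = 15, target_rate = 10),
      seeds = seeds, eval_episodes = 2000, label = name,
      desk_scale = FALSE),
    duplication_reversal = experiment_spec(
      task = "duplication_reversal",
      network = list(n_rec = 320, frac_sfa = 0.6, beta = 1700,
                     tau_a_dist = list(distribution = "uniform", lower = 1,
                                       upper = 6000),
                     v_th = 30, t_refr = 5),
      train = list(iterations = 50000, batch_size = 50, lr = 0.001,
                   decay_every = Inf, reg_coeff = 5, target_rate = 20),
      seeds = seeds, eval_episodes = 50000, label = name,
      desk_scale = FALSE))
  if (scale == "paper") return(full)
  smoke <- switch(name,
    store_recall_1d_200ms = ,
    store_recall_1d_200ms_lif = {
      full$train$iterations <- 150
      full$eval_episodes <- 256
      full
    },
    store_recall_20d = experiment_spec(
      task = "store_recall_20d",
      task_args = list(n_steps = 5, step_ms = 100, p_cmd = 0.4),
      network = list(n_rec = 120, frac_sfa = 1, beta = 2500, tau_a = 400,
                     t_refr = 3),
      train = list(iterations = 500, batch_size = 32, lr = 0.01,
                   lr_decay = 0.8, decay_every = 150, reg_coeff = 0.001,
                   target_rate = 10, entropy_coeff = 0.3),
      seeds = seeds, eval_episodes = 192, label = paste0(name, "_smoke")),
    `12ax` = experiment_spec(
      task = "12ax",
      task_args = list(n_symbols = 20, step_ms = 50, digit_range = c(1, 23)),
      network = list(n_rec = 60, frac_sfa = 0.5, beta = 1700,
                     tau_a_dist = list(distribution = "uniform", lower = 1,
                                       upper = 2000),
                     v_th = 30, t_refr = 5),
      train = list(iterations = 1000, batch_size = 8, lr = 0.01,
                   decay_every = Inf, reg_coeff = 5, target_rate = 10),
      seeds = seeds, eval_episodes = 150, label = paste0(name, "_smoke")),
    duplication_reversal = experiment_spec(
      task = "duplication_reversal",
      task_args = list(string_len = 3, n_letters = 8, step_ms = 150),
      network = list(n_rec = 120, frac_sfa = 0.6, beta = 1700,
                     tau_a_dist = list(distribution = "uniform", lower = 1,
                                       upper = 3000),
                     v_th = 30, t_refr = 5),
      train = list(iterations = 300, batch_size = 32, lr = 0.005,
                   decay_every = Inf, reg_coeff = 5, target_rate = 20),
      seeds = seeds, eval_episodes = 128, label = paste0(name, "_smoke")))
  smoke
}
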