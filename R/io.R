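# Plain-text serialisation: JSON checkpoints for networks, and a directory
# of CSV datasets with a JSON sidecar for trial records.

#' Write a network checkpoint
#'
#' Serialises all weights and parameters to a single JSON file that
#' [read_snn()] restores exactly (weights at full double precision).
#'
#' @param network an [snn_network()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_snn <- function(network, path) {
  obj <- list(
    n_in = network$n_in, n_rec = network$n_rec, n_out = network$n_out,
    Win = network$Win, Wrec = network$Wrec, Wout = network$Wout,
    bout = network$bout,
    cell = unclass(network$cell)[c("tau_m", "v_th", "t_refr", "dt")],
    beta = network$sfa$beta, tau_a = network$sfa$tau_a,
    sfa_mask = network$sfa_mask, tau_out = network$tau_out,
    self_connections = network$self_connections, w0 = network$w0,
    stp = if (is.null(network$stp)) NULL else unclass(network$stp))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a network checkpoint written by [write_snn()]
#'
#' @param path JSON checkpoint path.
#' @return An [snn_network()].
#' @export
read_snn <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  net <- snn_network(n_in = o$n_in, n_rec = o$n_rec, n_out = o$n_out,
                     tau_m = o$cell$tau_m, v_th = o$cell$v_th,
                     t_refr = o$cell$t_refr, dt = o$cell$dt,
                     tau_out = o$tau_out, w0 = o$w0,
                     self_connections = o$self_connections,
                     sfa_mask = as.logical(o$sfa_mask), beta = 0,
                     tau_a = o$tau_a,
                     stp = if (length(o$stp) == 0)
                       NULL else do.call(stp_params, o$stp))
  net$Win <- matrix(o$Win, o$n_rec, o$n_in, byrow = FALSE)
  net$Wrec <- matrix(o$Wrec, o$n_rec, o$n_rec)
  net$Wout <- matrix(o$Wout, o$n_out, o$n_rec)
  net$bout <- as.numeric(o$bout)
  net$sfa <- sfa_params(beta = as.numeric(o$beta),
                        tau_a = as.numeric(o$tau_a), dt = o$cell$dt)
  net
}

#' Save simulated trial records as plain-text datasets
#'
#' Writes one CSV per dataset (inputs, spikes, thresholds, readouts,
#' targets, rates) into a directory, flattened as episode x unit x time
#' tables, plus a `config.json` sidecar describing shapes and the
#' generating task.
#'
#' @param records an `snn_records`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_records <- function(records, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  flat <- function(a) {
    d <- dim(a)
    out <- matrix(aperm(a, c(3, 1, 2)), d[1] * d[3], d[2])
    df <- data.frame(episode = rep(seq_len(d[1]), each = d[3]),
                     t = rep(seq_len(d[3]), times = d[1]))
    cbind(df, as.data.frame(out))
  }
  write.csv(flat(records$x), file.path(dir, "inputs.csv"), row.names = FALSE)
  write.csv(flat(records$z), file.path(dir, "spikes.csv"), row.names = FALSE)
  write.csv(flat(records$A), file.path(dir, "thresholds.csv"),
            row.names = FALSE)
  write.csv(flat(records$y), file.path(dir, "readouts.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(records$rates), file.path(dir, "rates.csv"),
            row.names = FALSE)
  if (!is.null(records$decisions)) {
    d <- records$decisions
    df <- data.frame(episode = d$b, decision = d$k)
    df$predicted <- if (is.matrix(d$predicted) && ncol(d$predicted) > 1)
      apply(d$predicted, 1, paste, collapse = "") else as.vector(d$predicted)
    df$target <- if (is.matrix(d$targets) && ncol(d$targets) > 1)
      apply(d$targets, 1, paste, collapse = "") else as.vector(d$targets)
    write.csv(df, file.path(dir, "decisions.csv"), row.names = FALSE)
  }
  cfg <- list(n_episodes = dim(records$z)[1], n_rec = dim(records$z)[2],
              n_in = dim(records$x)[2], n_out = dim(records$y)[2],
              T = dim(records$z)[3],
              task = records$batch$meta$step_ms %||% NA,
              datasets = c("inputs", "spikes", "thresholds", "readouts",
                           "rates"))
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load datasets written by [save_records()]
#'
#' @param dir directory containing the CSV datasets and `config.json`.
#' @return A list of arrays (`x`, `z`, `A`, `y`, `rates`) with the original
#'   episode x unit x time shapes.
#' @export
load_records <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  unflat <- function(path, n_units) {
    df <- read.csv(path)
    m <- as.matrix(df[, -(1:2), drop = FALSE])
    aperm(array(m, dim = c(cfg$T, cfg$n_episodes, n_units)), c(2, 3, 1))
  }
  list(x = unflat(file.path(dir, "inputs.csv"), cfg$n_in),
       z = unflat(file.path(dir, "spikes.csv"), cfg$n_rec),
       A = unflat(file.path(dir, "thresholds.csv"), cfg$n_rec),
       y = unflat(file.path(dir, "readouts.csv"), cfg$n_out),
       rates = as.matrix(read.csv(file.path(dir, "rates.csv"))),
       config = cfg)
}
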