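# Procedural task generators. Each constructor returns an `snn_task`: a light
# object holding the input/output geometry, the readout specification, and a
# `sample(n)` closure producing `snn_batch` objects (Poisson spike rasters,
# decision windows, targets, and symbol-level metadata).

new_task <- function(name, n_in, n_out, readout, loss, metric, sample,
                     config = list()) {
  structure(list(name = name, n_in = n_in, n_out = n_out, readout = readout,
                 loss = loss, metric = metric, sample = sample,
                 config = config), class = "snn_task")
}

#' @export
print.snn_task <- function(x, ...) {
  cat("snn_task '", x$name, "': ", x$n_in, " input channels, ", x$n_out,
      " readouts, ", x$readout$mode, " readout\n", sep = "")
  invisible(x)
}

new_batch <- function(x, mode, win_id, n_dec, targets, threshold = 0.5,
                      meta = list()) {
  structure(list(x = x, mode = mode, win_id = win_id, n_dec = n_dec,
                 targets = targets, threshold = threshold, meta = meta),
            class = "snn_batch")
}

# Bernoulli approximation of Poisson spiking: each channel fires with
# probability rate*dt per step. `rates` is B x n_in x n_steps in Hz; each
# task step is expanded to step_ms/dt simulation steps.
poisson_raster <- function(rates, step_ms, dt = 1) {
  B <- dim(rates)[1]; n_in <- dim(rates)[2]; n_steps <- dim(rates)[3]
  sub <- as.integer(round(step_ms / dt))
  T_ <- n_steps * sub
  p <- rates * dt / 1000
  x <- array(0, dim = c(B, n_in, T_))
  for (s in seq_len(n_steps)) {
    ps <- p[, , s]
    idx <- ((s - 1) * sub + 1):(s * sub)
    draws <- array(rbinom(B * n_in * sub, 1, rep(ps, sub)),
                   dim = c(B, n_in, sub))
    x[, , idx] <- draws
  }
  x
}

step_window_id <- function(n_steps, step_ms, dt, decision_steps) {
  # win_id vector over simulation steps for one episode
  sub <- as.integer(round(step_ms / dt))
  w <- integer(n_steps * sub)
  for (k in seq_along(decision_steps)) {
    s <- decision_steps[k]
    w[((s - 1) * sub + 1):(s * sub)] <- k
  }
  w
}

## ---------------------------------------------------------------------------
## STORE-RECALL (1-D and 20-D)

sample_commands <- function(n_steps, p_cmd) {
  # Alternating STORE/RECALL activations; resample until the episode contains
  # at least one complete STORE -> RECALL pair so that every episode carries a
  # decision.
  repeat {
    cmd <- character(n_steps); cmd[] <- "none"
    expecting <- "store"
    for (s in seq_len(n_steps)) {
      if (runif(1) < p_cmd) {
        cmd[s] <- expecting
        expecting <- if (expecting == "store") "recall" else "store"
      }
    }
    if (any(cmd == "recall")) return(cmd)
  }
}

#' One-dimensional STORE-RECALL working-memory task
#'
#' Episodes are sequences of `n_steps` presentation steps of `step_ms` ms.
#' A binary value stream is population-coded on 20 input channels; 10
#' channels signal STORE and 10 signal RECALL. STORE and RECALL activate
#' interchangeably (a RECALL can only follow a STORE) with probability
#' `p_cmd` per step; active populations fire Poisson spikes at `rate_hi` Hz,
#' inactive ones are silent, and the value channels are silent during RECALL.
#' The target at each RECALL is the bit shown during the most recent STORE.
#' A single sigmoid readout is averaged over the recall window and
#' thresholded at 0.5.
#'
#' The default geometry (12 steps of 50 ms) gives an expected STORE-RECALL
#' delay of roughly 200 ms; longer memory spans use 20/40/80/120 steps of
#' 200 ms.
#'
#' @param n_steps presentation steps per episode.
#' @param step_ms step duration, ms.
#' @param p_cmd per-step probability of the next command activation.
#' @param rate_hi firing rate of an active population, Hz.
#' @param dt simulation step, ms.
#' @return An `snn_task` with a `sample(n)` closure.
#' @export
store_recall_task <- function(n_steps = 12, step_ms = 50, p_cmd = 0.09,
                              rate_hi = 50, dt = 1) {
  n_in <- 40
  sub <- as.integer(round(step_ms / dt))
  sample_fun <- function(n) {
    x_rates <- array(0, dim = c(n, n_in, n_steps))
    cmd_mat <- matrix("none", n, n_steps)
    val_mat <- matrix(0L, n, n_steps)
    win_id <- matrix(0L, n, n_steps * sub)
    K <- 0L
    targets_list <- vector("list", n)
    n_dec <- integer(n)
    for (b in seq_len(n)) {
      cmd <- sample_commands(n_steps, p_cmd)
      vals <- sample(0:1, n_steps, replace = TRUE)
      cmd_mat[b, ] <- cmd; val_mat[b, ] <- vals
      stored <- NA_integer_
      dec_steps <- integer(0); tg <- integer(0)
      for (s in seq_len(n_steps)) {
        if (cmd[s] == "store") {
          stored <- vals[s]
          x_rates[b, 1:10, s] <- rate_hi
          # the value population fires together with the STORE command
          x_rates[b, if (vals[s] == 0) 21:30 else 31:40, s] <- rate_hi
        } else if (cmd[s] == "recall") {
          x_rates[b, 11:20, s] <- rate_hi
          dec_steps <- c(dec_steps, s); tg <- c(tg, stored)
        }
      }
      win_id[b, ] <- step_window_id(n_steps, step_ms, dt, dec_steps)
      targets_list[[b]] <- tg
      n_dec[b] <- length(tg)
    }
    K <- max(n_dec)
    targets <- array(NA_real_, dim = c(n, K, 1))
    for (b in seq_len(n))
      if (n_dec[b] > 0) targets[b, seq_len(n_dec[b]), 1] <- targets_list[[b]]
    x <- poisson_raster(x_rates, step_ms, dt)
    new_batch(x, "sigmoid", win_id, n_dec, targets,
              meta = list(cmd = cmd_mat, values = val_mat,
                          step_ms = step_ms, n_steps = n_steps))
  }
  new_task("store_recall_1d", n_in, 1,
           readout_spec("trace-sigmoid", trace_tau = 20, window = step_ms),
           loss = "bce", metric = "decision", sample = sample_fun,
           config = list(n_steps = n_steps, step_ms = step_ms, p_cmd = p_cmd,
                         rate_hi = rate_hi, dt = dt))
}

#' Random bit-string dictionary with a Hamming-distance guarantee
#'
#' Draws `n` random bit strings of length `bits`. Without `ref`, the strings
#' keep a pairwise Hamming distance of at least `min_dist` (the held-out
#' test dictionary). With `ref`, each string keeps that distance from every
#' row of `ref` (fresh training dictionaries, random otherwise).
#'
#' @param n number of strings.
#' @param bits string length.
#' @param min_dist minimum Hamming distance.
#' @param ref optional reference dictionary (matrix, strings in rows).
#' @param max_tries bounded rejection budget; exceeded -> error.
#' @return An `n x bits` 0/1 matrix.
#' @export
hamming_dictionary <- function(n, bits = 20, min_dist = 5, ref = NULL,
                               max_tries = 100000) {
  out <- matrix(NA_integer_, 0, bits)
  tries <- 0
  while (nrow(out) < n) {
    tries <- tries + 1
    if (tries > max_tries)
      stop("hamming_dictionary: could not build dictionary within ",
           max_tries, " tries")
    cand <- sample(0:1, bits, replace = TRUE)
    against <- if (is.null(ref)) out else ref
    if (nrow(against) == 0 ||
        min(colSums(abs(t(against) - cand))) >= min_dist)
      out <- rbind(out, cand, deparse.level = 0)
  }
  out
}

#' Twenty-dimensional STORE-RECALL task with a generalisation split
#'
#' A 20-bit feature vector is shown at every step (4 input neurons per bit,
#' 2 per binary state), with 4 neurons each for the STORE and RECALL commands
#' (88 channels in total). Active populations fire at 400 Hz. STORE/RECALL
#' activate interchangeably with probability 0.2 per step; the value
#' populations are silent during RECALL. Targets are the 20 bits shown at the
#' most recent STORE, read out by 20 sigmoid neurons.
#'
#' Generalisation is enforced through dictionaries: the task owns a fixed
#' test dictionary of 20 strings with pairwise Hamming distance >= 5, and
#' every training batch draws a fresh dictionary of 40 strings, each at
#' Hamming distance >= 5 from every test string. `sample(n, test = TRUE)`
#' draws episodes from the test dictionary.
#'
#' @param n_steps presentation steps per episode.
#' @param step_ms step duration, ms.
#' @param p_cmd per-step command probability.
#' @param rate_hi active-population rate, Hz.
#' @param n_bits feature-vector length.
#' @param dict_seed seed fixing the test dictionary.
#' @param train_dict_size strings per training dictionary.
#' @param dt simulation step, ms.
#' @return An `snn_task`; the test dictionary is in `$config$test_dict`.
#' @export
store_recall_task_20d <- function(n_steps = 10, step_ms = 200, p_cmd = 0.2,
                                  rate_hi = 400, n_bits = 20, dict_seed = 42,
                                  train_dict_size = 40, dt = 1) {
  n_in <- 8 + 4 * n_bits
  sub <- as.integer(round(step_ms / dt))
  test_dict <- with_seed(dict_seed,
                         hamming_dictionary(20, bits = n_bits, min_dist = 5))
  # channel layout: 1:4 STORE, 5:8 RECALL, then per bit i: 4 channels,
  # first 2 code state 0, last 2 code state 1
  bit_channels <- function(i, state) 8 + (i - 1) * 4 + (if (state == 0) 1:2 else 3:4)
  sample_fun <- function(n, test = FALSE) {
    dict <- if (test) test_dict else
      hamming_dictionary(train_dict_size, bits = n_bits, min_dist = 5,
                         ref = test_dict)
    x_rates <- array(0, dim = c(n, n_in, n_steps))
    win_id <- matrix(0L, n, n_steps * sub)
    n_dec <- integer(n)
    targets_list <- vector("list", n)
    cmd_mat <- matrix("none", n, n_steps)
    shown <- array(NA_integer_, dim = c(n, n_steps, n_bits))
    for (b in seq_len(n)) {
      cmd <- sample_commands(n_steps, p_cmd)
      cmd_mat[b, ] <- cmd
      stored <- rep(NA_integer_, n_bits)
      dec_steps <- integer(0); tg <- list()
      for (s in seq_len(n_steps)) {
        str <- dict[sample.int(nrow(dict), 1), ]
        if (cmd[s] == "store") {
          stored <- str
          x_rates[b, 1:4, s] <- rate_hi
        } else if (cmd[s] == "recall") {
          x_rates[b, 5:8, s] <- rate_hi
          dec_steps <- c(dec_steps, s); tg <- c(tg, list(stored))
        }
        if (cmd[s] != "recall") {
          shown[b, s, ] <- str
          for (i in seq_len(n_bits))
            x_rates[b, bit_channels(i, str[i]), s] <- rate_hi
        }
      }
      win_id[b, ] <- step_window_id(n_steps, step_ms, dt, dec_steps)
      n_dec[b] <- length(tg)
      targets_list[[b]] <- tg
    }
    K <- max(n_dec)
    targets <- array(NA_real_, dim = c(n, K, n_bits))
    for (b in seq_len(n))
      for (k in seq_len(n_dec[b])) targets[b, k, ] <- targets_list[[b]][[k]]
    x <- poisson_raster(x_rates, step_ms, dt)
    new_batch(x, "sigmoid", win_id, n_dec, targets,
              meta = list(cmd = cmd_mat, shown = shown, dict = dict,
                          step_ms = step_ms, n_steps = n_steps))
  }
  new_task("store_recall_20d", n_in, n_bits,
           readout_spec("trace-sigmoid", trace_tau = 20, window = step_ms),
           loss = "bce", metric = "bit", sample = sample_fun,
           config = list(n_steps = n_steps, step_ms = step_ms, p_cmd = p_cmd,
                         rate_hi = rate_hi, n_bits = n_bits,
                         test_dict = test_dict, dt = dt))
}

## ---------------------------------------------------------------------------
## 12AX continuous-performance task

ax_alphabet <- c("1", "2", "A", "B", "C", "X", "Y", "Z")

# One realization of the generating expression:
# [12][ABCXYZ]{1,10}((A[CZ]{0,6}X|B[CZ]{0,6}Y)|([ABC][XYZ])){1,2}
# with every choice uniform.
sample_12ax_phrase <- function() {
  out <- sample(c("1", "2"), 1)
  out <- c(out, sample(c("A", "B", "C", "X", "Y", "Z"),
                       sample.int(10, 1), replace = TRUE))
  for (i in seq_len(sample.int(2, 1))) {
    if (runif(1) < 0.5) {
      if (runif(1) < 0.5)
        grp <- c("A", sample(c("C", "Z"), sample(0:6, 1), replace = TRUE), "X")
      else
        grp <- c("B", sample(c("C", "Z"), sample(0:6, 1), replace = TRUE), "Y")
    } else {
      grp <- c(sample(c("A", "B", "C"), 1), sample(c("X", "Y", "Z"), 1))
    }
    out <- c(out, grp)
  }
  out
}

#' Target labels for a 12AX symbol sequence
#'
#' Returns `"R"` for every symbol that terminates a context-dependent target
#' subsequence -- an `X` completing `A...X` when the most recent digit was 1,
#' or a `Y` completing `B...Y` when it was 2, with only `C`/`Z` distractors
#' allowed in between -- and `"L"` otherwise.
#'
#' @param symbols character vector over the alphabet 1 2 A B C X Y Z.
#' @return Character vector of `"L"`/`"R"`, one per symbol.
#' @examples
#' label_12ax(c("1", "A", "X"))       # L L R
#' label_12ax(c("2", "A", "X"))       # L L L (wrong context)
#' @export
label_12ax <- function(symbols) {
  stopifnot(all(symbols %in% ax_alphabet))
  context <- ""
  pending <- ""
  out <- character(length(symbols))
  for (i in seq_along(symbols)) {
    s <- symbols[i]
    r <- FALSE
    if (s %in% c("1", "2")) {
      context <- s; pending <- ""
    } else if (s == "A" || s == "B") {
      pending <- s
    } else if (s %in% c("C", "Z")) {
      # distractors leave the pending letter alive
    } else { # X or Y
      r <- (s == "X" && context == "1" && pending == "A") ||
           (s == "Y" && context == "2" && pending == "B")
      pending <- ""
    }
    out[i] <- if (r) "R" else "L"
  }
  out
}

#' The 12AX context-dependent sequence task
#'
#' Each episode is a stream of `n_symbols` symbols from
#' \{1, 2, A, B, C, X, Y, Z\}, built by concatenating random realizations of
#' the task's generating expression and truncating at `n_symbols`; episodes
#' are rejected unless they contain between 4 and 23 digits. Each symbol is
#' presented for `step_ms` ms through one-hot population coding
#' (`neurons_per_symbol` Poisson channels at `rate_hi` Hz). After every
#' symbol the network answers L or R; the readout sees the mean network
#' activity over the symbol's window (softmax over two readouts).
#'
#' @param n_symbols symbols per episode.
#' @param step_ms symbol presentation time, ms.
#' @param rate_hi firing rate of the active symbol population, Hz.
#' @param neurons_per_symbol one-hot population size.
#' @param digit_range admissible digit counts per episode.
#' @param dt simulation step, ms.
#' @return An `snn_task`.
#' @export
task_12ax <- function(n_symbols = 90, step_ms = 500, rate_hi = 50,
                      neurons_per_symbol = 5, digit_range = c(4, 23),
                      dt = 1) {
  n_in <- length(ax_alphabet) * neurons_per_symbol
  sub <- as.integer(round(step_ms / dt))
  sample_episode <- function() {
    repeat {
      sym <- character(0)
      while (length(sym) < n_symbols) sym <- c(sym, sample_12ax_phrase())
      sym <- sym[seq_len(n_symbols)]
      ndig <- sum(sym %in% c("1", "2"))
      if (ndig >= digit_range[1] && ndig <= digit_range[2]) return(sym)
    }
  }
  sample_fun <- function(n) {
    x_rates <- array(0, dim = c(n, n_in, n_symbols))
    targets <- matrix(NA_integer_, n, n_symbols)
    syms <- matrix("", n, n_symbols)
    for (b in seq_len(n)) {
      sym <- sample_episode()
      syms[b, ] <- sym
      lab <- label_12ax(sym)
      targets[b, ] <- ifelse(lab == "R", 2L, 1L)
      for (s in seq_len(n_symbols)) {
        ch <- (match(sym[s], ax_alphabet) - 1) * neurons_per_symbol +
          seq_len(neurons_per_symbol)
        x_rates[b, ch, s] <- rate_hi
      }
    }
    win_row <- step_window_id(n_symbols, step_ms, dt, seq_len(n_symbols))
    win_id <- matrix(rep(win_row, each = n), n, n_symbols * sub)
    x <- poisson_raster(x_rates, step_ms, dt)
    new_batch(x, "softmax_winmean", win_id, rep(n_symbols, n), targets,
              meta = list(symbols = syms, step_ms = step_ms))
  }
  new_task("12ax", n_in, 2,
           readout_spec("window-mean-softmax", window = step_ms),
           loss = "ce", metric = "episode", sample = sample_fun,
           config = list(n_symbols = n_symbols, step_ms = step_ms,
                         rate_hi = rate_hi,
                         neurons_per_symbol = neurons_per_symbol, dt = dt))
}

## ---------------------------------------------------------------------------
## Duplication / reversal of symbol strings

#' Duplication/reversal symbolic computation task
#'
#' Episodes present a task cue (duplicate or reverse), a string of
#' `string_len` random symbols from an alphabet of `n_letters`, an
#' end-of-string marker, and `string_len` output-prompt slots; every slot
#' lasts `step_ms` ms. Inputs are one-hot population codes over
#' `n_letters + 4` symbols (letters, EOS `*`, prompt `?`, two cues):
#' the active population fires at `rate_hi` Hz, all others at `rate_lo` Hz.
#' During each prompt slot the network must output one symbol of the input
#' string (duplicate) or of its reversal (reverse); the readout with maximal
#' value at the end of the slot wins (softmax during training).
#'
#' @param string_len symbols per string.
#' @param n_letters alphabet size.
#' @param step_ms slot duration, ms.
#' @param rate_hi,rate_lo high/low Poisson rates, Hz.
#' @param neurons_per_symbol one-hot population size.
#' @param dt simulation step, ms.
#' @return An `snn_task`.
#' @export
duplication_task <- function(string_len = 5, n_letters = 31, step_ms = 500,
                             rate_hi = 200, rate_lo = 2,
                             neurons_per_symbol = 5, dt = 1) {
  n_sym <- n_letters + 4
  n_in <- n_sym * neurons_per_symbol
  id_eos <- n_letters + 1; id_prompt <- n_letters + 2
  id_dup <- n_letters + 3; id_rev <- n_letters + 4
  n_slots <- 2 * string_len + 2
  sub <- as.integer(round(step_ms / dt))
  sample_fun <- function(n) {
    x_rates <- array(rate_lo, dim = c(n, n_in, n_slots))
    targets <- matrix(NA_integer_, n, string_len)
    tasks <- character(n)
    strings <- matrix(0L, n, string_len)
    for (b in seq_len(n)) {
      str <- sample.int(n_letters, string_len, replace = TRUE)
      tk <- sample(c("duplicate", "reverse"), 1)
      tasks[b] <- tk; strings[b, ] <- str
      slots <- c(if (tk == "duplicate") id_dup else id_rev, str, id_eos,
                 rep(id_prompt, string_len))
      for (s in seq_len(n_slots)) {
        ch <- (slots[s] - 1) * neurons_per_symbol + seq_len(neurons_per_symbol)
        x_rates[b, ch, s] <- rate_hi
      }
      targets[b, ] <- if (tk == "duplicate") str else rev(str)
    }
    out_slots <- (string_len + 3):n_slots
    win_row <- step_window_id(n_slots, step_ms, dt, out_slots)
    win_id <- matrix(rep(win_row, each = n), n, n_slots * sub)
    x <- poisson_raster(x_rates, step_ms, dt)
    new_batch(x, "softmax_end", win_id, rep(string_len, n), targets,
              meta = list(task = tasks, strings = strings, step_ms = step_ms,
                          out_slots = out_slots))
  }
  new_task("duplication_reversal", n_in, n_letters,
           readout_spec("trace-softmax", trace_tau = 250, window = step_ms),
           loss = "ce", metric = "episode", sample = sample_fun,
           config = list(string_len = string_len, n_letters = n_letters,
                         step_ms = step_ms, rate_hi = rate_hi,
                         rate_lo = rate_lo, dt = dt))
}

## ---------------------------------------------------------------------------
## Sequential MNIST threshold-crossing encoder

#' Threshold-crossing spike encoding of a grayscale image
#'
#' The image is streamed pixel by pixel in a row-wise scanline (1 ms per
#' pixel). Each of the `n_channels` input neurons owns one threshold, evenly
#' spaced in (0, 1); channel i spikes at pixel t exactly when its threshold
#' lies strictly between the previous and the current gray value (crossings
#' in either direction). The first pixel has no predecessor and produces no
#' spikes. The encoding is deterministic.
#'
#' @param image a 28 x 28 (or any) numeric matrix with values in `[0, 1]`,
#'   or an already-flattened numeric vector.
#' @param n_channels number of threshold channels.
#' @return A `T x n_channels` binary spike matrix (T = number of pixels).
#' @export
encode_smnist <- function(image, n_channels = 80) {
  px <- if (is.matrix(image)) as.vector(t(image)) else as.numeric(image)
  if (any(!is.finite(px)) || any(px < 0) || any(px > 1))
    stop("encode_smnist: pixel values must lie in [0, 1]")
  thr <- seq_len(n_channels) / (n_channels + 1)
  T_ <- length(px)
  out <- matrix(0, T_, n_channels)
  prev <- px[1]
  for (t in seq_len(T_)) {
    lo <- pmin(prev, px[t]); hi <- pmax(prev, px[t])
    out[t, ] <- as.numeric(thr > lo & thr < hi)
    prev <- px[t]
  }
  out
}

#' Sequential MNIST task from user-supplied images
#'
#' Wraps [encode_smnist()] into an `snn_task`. The MNIST images themselves
#' are not shipped; pass any array of images in `[0, 1]` with integer labels
#' in 0..9. Classification happens at the final time step (softmax over 10
#' readouts fed by 20 ms readout traces).
#'
#' @param images numeric array `n x 28 x 28` (or a list of matrices).
#' @param labels integer vector of digits 0-9.
#' @param n_channels threshold channels, see [encode_smnist()].
#' @return An `snn_task` whose `sample(n)` draws images at random.
#' @export
smnist_task <- function(images, labels, n_channels = 80) {
  get_img <- function(i) if (is.list(images)) images[[i]] else images[i, , ]
  n_img <- if (is.list(images)) length(images) else dim(images)[1]
  stopifnot(length(labels) == n_img)
  T_ <- length(as.vector(get_img(1)))
  sample_fun <- function(n) {
    idx <- sample.int(n_img, n, replace = n > n_img)
    x <- array(0, dim = c(n, n_channels, T_))
    for (b in seq_len(n)) x[b, , ] <- t(encode_smnist(get_img(idx[b]), n_channels))
    win_id <- matrix(0L, n, T_); win_id[, T_] <- 1L
    targets <- matrix(as.integer(labels[idx]) + 1L, n, 1)
    new_batch(x, "softmax_end", win_id, rep(1L, n), targets,
              meta = list(index = idx))
  }
  new_task("smnist", n_channels, 10,
           readout_spec("trace-softmax", trace_tau = 20, window = T_),
           loss = "ce", metric = "decision", sample = sample_fun,
           config = list(n_channels = n_channels))
}
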