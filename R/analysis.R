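# Interpretive analyses: the hand-wired negative-imprinting circuit,
# cross-period SVM decoding of memory content, three-way ANOVA neuron
# categorisation with omega-squared effect sizes, and peak-activity sorting.

#' Negative-imprinting demonstration circuit
#'
#' Builds the minimal hand-wired working-memory circuit: two neurons with
#' strong SFA (beta such that each spike raises the threshold by ~2.5 mV,
#' tau_a = 1200 ms, baseline threshold 5 mV, no recurrent connections) driven
#' by four input populations of 10 Poisson neurons each (STORE, RECALL, and
#' the two values). The value input "right" is routed to neuron NL and
#' "left" to NR: the neuron that fires during STORE acquires a raised
#' threshold (a "negative imprint"), so during RECALL -- which excites both
#' neurons equally -- the *other* neuron fires more, and a winner-take-all
#' readout of the two spike counts recovers the stored value.
#'
#' @param value value presented during STORE: `"right"`, `"left"`, or `NULL`
#'   for a control episode without a STORE (symmetric circuit).
#' @param seed integer seed for the Poisson inputs.
#' @param store_ms,recall_ms onset times of the 500 ms STORE and RECALL
#'   windows.
#' @param duration_ms episode length.
#' @param rate_hi input population rate, Hz.
#' @return A list with the `snn_records` object (`record`), a data frame of
#'   per-phase spike `counts` for NL and NR, the stored value, and the
#'   `answer` decoded from the RECALL spike counts.
#' @export
negative_imprinting_demo <- function(value = "right", seed = 1,
                                     store_ms = 200, recall_ms = 1200,
                                     duration_ms = 1800, rate_hi = 50) {
  stopifnot(is.null(value) || value %in% c("right", "left"))
  pops <- list(store = 1:10, recall = 11:20, right = 21:30, left = 31:40)
  net <- snn_network(n_in = 40, n_rec = 2, n_out = 2, frac_sfa = 1,
                     beta = 3000, tau_a = 1200, tau_m = 20, v_th = 5,
                     t_refr = 3, seed = 0)
  # hand-set weights (not trained): coincidence detection of STORE + value,
  # shared RECALL drive; cross-wiring routes "right" to NL
  # a weight w delivers ~0.5*w mV of steady drive per active 10-neuron
  # population at 50 Hz: STORE (3 mV) or a value (6 mV) alone stays near or
  # below threshold, together they drive spiking (9 mV); RECALL alone drives
  # 8 mV, above the resting threshold but below a freshly imprinted one
  Win <- matrix(0, 2, 40)  # stored in volts; dynamics convert to mV
  Win[1, pops$store] <- 6e-3; Win[2, pops$store] <- 6e-3  # NL row 1, NR row 2
  Win[1, pops$right] <- 12e-3; Win[2, pops$left] <- 12e-3
  Win[1, pops$recall] <- 16e-3; Win[2, pops$recall] <- 16e-3
  net$Win <- Win
  net$Wrec <- matrix(0, 2, 2)
  net$Wout <- rbind(c(1, 0), c(0, 1)); net$bout <- c(0, 0)

  T_ <- duration_ms
  x <- with_seed(seed, {
    rates <- matrix(0, 40, T_)
    if (!is.null(value)) {
      sw <- store_ms:(store_ms + 499)
      rates[pops$store, sw] <- rate_hi
      rates[pops[[value]], sw] <- rate_hi
    }
    rw <- recall_ms:(recall_ms + 499)
    rates[pops$recall, rw] <- rate_hi
    array(rbinom(40 * T_, 1, rates / 1000), dim = c(1, 40, T_))
  })
  rec <- simulate(net, x = x)
  phase <- function(w) rowSums(rec$z[1, , w, drop = FALSE][, , , drop = TRUE])
  store_w <- if (is.null(value)) integer(0) else store_ms:(store_ms + 499)
  recall_w <- recall_ms:(recall_ms + 499)
  counts <- data.frame(
    neuron = c("NL", "NR"),
    store = if (length(store_w)) phase(store_w) else c(0, 0),
    recall = phase(recall_w))
  answer <- if (counts$recall[2] > counts$recall[1]) "right"
            else if (counts$recall[1] > counts$recall[2]) "left" else "tie"
  list(record = rec, counts = counts, stored = value, answer = answer)
}

## ---------------------------------------------------------------------------
## Cross-period decoding

#' Period-wise spike-count features from simulated records
#'
#' Extracts per-episode, per-neuron spike counts from a named period of
#' STORE-RECALL episodes: the STORE window, the 200 ms immediately preceding
#' RECALL ("delay"), or the RECALL window. Episodes lacking the period are
#' dropped.
#'
#' @param records an `snn_records` from a STORE-RECALL batch.
#' @param period `"store"`, `"delay"`, or `"recall"`.
#' @param pre_ms length of the pre-RECALL window, ms.
#' @return A list with feature matrix `x` (episodes x neurons) and the kept
#'   episode indices `episode`.
#' @export
period_features <- function(records, period = c("store", "delay", "recall"),
                            pre_ms = 200) {
  period <- match.arg(period)
  batch <- records$batch
  stopifnot(!is.null(batch$meta$cmd))
  cmd <- batch$meta$cmd
  step_ms <- batch$meta$step_ms
  B <- dim(records$z)[1]
  feats <- list(); eps <- integer(0)
  for (b in seq_len(B)) {
    st <- which(cmd[b, ] == "store"); rc <- which(cmd[b, ] == "recall")
    rc <- rc[rc > min(st)][1]
    if (length(st) == 0 || is.na(rc)) next
    st <- max(st[st < rc])
    w <- switch(period,
      store = ((st - 1) * step_ms + 1):(st * step_ms),
      recall = ((rc - 1) * step_ms + 1):(rc * step_ms),
      delay = ((rc - 1) * step_ms - pre_ms + 1):((rc - 1) * step_ms))
    if (min(w) < 1) next
    feats[[length(feats) + 1]] <- rowSums(records$z[b, , w])
    eps <- c(eps, b)
  }
  list(x = do.call(rbind, feats), episode = eps)
}

#' Cross-period decoding of memory content with an SVM
#'
#' Trains a support vector machine to classify the stored memory content
#' from per-neuron spike counts in one task period and evaluates it on
#' (possibly different) episodes and a (possibly different) period. The SVM
#' hyperparameters -- kernel in \{linear, polynomial, RBF\} and cost in
#' \{0.1, 1, 10, 100, 1000\} -- are chosen by cross-validated grid search on
#' the training features. Train and test episodes are disjoint by
#' construction.
#'
#' @param train_x,train_y training features (episodes x neurons) and labels.
#' @param test_x,test_y held-out evaluation features and labels.
#' @param kernels,costs the hyperparameter grid.
#' @param folds cross-validation folds for the grid search.
#' @param seed seed for the fold assignment.
#' @return A list with `accuracy` on the evaluation set, the selected
#'   `kernel` and `cost`, and the grid of cross-validation scores.
#' @export
cross_period_decode <- function(train_x, train_y, test_x, test_y,
                                kernels = c("linear", "polynomial", "radial"),
                                costs = c(0.1, 1, 10, 100, 1000),
                                folds = 5, seed = 1) {
  train_y <- factor(train_y)
  if (nlevels(train_y) < 2)
    stop("cross_period_decode: training labels are degenerate (single class)")
  grid <- expand.grid(kernel = kernels, cost = costs,
                      stringsAsFactors = FALSE)
  n <- nrow(train_x)
  fold <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  cv_acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    acc <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- fold != f
      if (nlevels(droplevels(train_y[tr])) < 2) { acc[f] <- NA; next }
      m <- e1071::svm(train_x[tr, , drop = FALSE], droplevels(train_y[tr]),
                      kernel = grid$kernel[g], cost = grid$cost[g],
                      scale = FALSE)
      pr <- predict(m, train_x[!tr, , drop = FALSE])
      acc[f] <- mean(as.character(pr) == as.character(train_y[!tr]))
    }
    cv_acc[g] <- mean(acc, na.rm = TRUE)
  }
  best <- which.max(cv_acc)
  model <- e1071::svm(train_x, train_y, kernel = grid$kernel[best],
                      cost = grid$cost[best], scale = FALSE)
  pred <- predict(model, test_x)
  list(accuracy = mean(as.character(pred) == as.character(test_y)),
       kernel = grid$kernel[best], cost = grid$cost[best],
       cv = cbind(grid, cv_accuracy = cv_acc))
}

## ---------------------------------------------------------------------------
## Three-way ANOVA categorisation

anova_effects <- c("task", "position", "symbol", "task:position",
                   "task:symbol", "position:symbol", "task:position:symbol")

# Balanced full-factorial three-way ANOVA, vectorised over response columns.
# Returns SS, df, F and p for the 7 effects plus the error term. Requires a
# balanced design (equal replicates per cell).
anova3_balanced <- function(y, task, position, symbol) {
  y <- as.matrix(y)
  f <- list(task = factor(task), position = factor(position),
            symbol = factor(symbol))
  cell <- interaction(f$task, f$position, f$symbol, drop = FALSE)
  counts <- table(cell)
  if (length(unique(counts)) != 1 || any(counts == 0)) {
    tab <- table(counts)
    stop("anova3_balanced: unbalanced design (replicate counts: ",
         paste(names(tab), collapse = "/"), ")")
  }
  N <- nrow(y)
  gm <- colMeans(y)
  ss_total <- colSums(sweep(y, 2, gm)^2)

  mean_by <- function(idx) {
    # group means per response column; rows ordered by factor level
    rowsum(y, idx) / as.vector(table(idx))
  }
  dev <- function(m) sweep(m, 2, gm)
  lv <- vapply(f, nlevels, 0)
  n_rep <- N / prod(lv)

  mA <- mean_by(f$task); mB <- mean_by(f$position); mC <- mean_by(f$symbol)
  ssA <- colSums(dev(mA)^2) * N / lv["task"]
  ssB <- colSums(dev(mB)^2) * N / lv["position"]
  ssC <- colSums(dev(mC)^2) * N / lv["symbol"]

  two_way <- function(f1, f2, m1, m2, ss1, ss2) {
    idx <- interaction(f1, f2, lex.order = TRUE)
    m12 <- mean_by(idx)
    colSums(dev(m12)^2) * N / (nlevels(f1) * nlevels(f2)) - ss1 - ss2
  }
  ssAB <- two_way(f$task, f$position, mA, mB, ssA, ssB)
  ssAC <- two_way(f$task, f$symbol, mA, mC, ssA, ssC)
  ssBC <- two_way(f$position, f$symbol, mB, mC, ssB, ssC)

  mABC <- mean_by(cell)
  ss_cells <- colSums(dev(mABC)^2) * n_rep
  ssABC <- ss_cells - ssA - ssB - ssC - ssAB - ssAC - ssBC
  ss_err <- ss_total - ss_cells

  df <- c(task = lv[["task"]] - 1, position = lv[["position"]] - 1,
          symbol = lv[["symbol"]] - 1)
  df["task:position"] <- df["task"] * df["position"]
  df["task:symbol"] <- df["task"] * df["symbol"]
  df["position:symbol"] <- df["position"] * df["symbol"]
  df["task:position:symbol"] <- df["task"] * df["position"] * df["symbol"]
  df_err <- N - prod(lv)

  ss <- rbind(task = ssA, position = ssB, symbol = ssC, `task:position` = ssAB,
              `task:symbol` = ssAC, `position:symbol` = ssBC,
              `task:position:symbol` = ssABC)
  ms_err <- ss_err / df_err
  Fv <- sweep(ss / df[anova_effects], 2, ms_err, "/")
  pv <- matrix(pf(Fv, df[anova_effects], df_err, lower.tail = FALSE),
               nrow(Fv), ncol(Fv), dimnames = dimnames(Fv))
  list(ss = ss, df = df[anova_effects], ss_err = ss_err, df_err = df_err,
       ss_total = ss_total, ms_err = ms_err, F = Fv, p = pv)
}

#' Categorise neurons by condition selectivity (three-way ANOVA)
#'
#' For every neuron, tests whether its firing rate depends on the task
#' (duplicate/reverse), the serial position (1-5), the symbol identity, or
#' any interaction of these, using a balanced full-factorial three-way
#' ANOVA. The effect size is
#' `omega^2 = (SS_effect - df_effect * MS_error) / (SS_total + MS_error)`;
#' a neuron is assigned to every effect category with `p < p_threshold` and
#' `omega^2 > omega_threshold` (so one neuron may hold several categories).
#' Neurons whose overall mean rate lies outside `rate_range` are discarded
#' before the analysis. For each categorised neuron the preferred condition
#' is the (task, position, symbol) triple with the largest Welch t-statistic
#' (its rates against all remaining samples) at `p < p_threshold`.
#'
#' @param data a data frame with columns `task`, `position`, `symbol` and
#'   one rate column per neuron (all remaining numeric columns), balanced
#'   over the 2 x 5 x 31 (by default) conditions -- see
#'   [balance_conditions()].
#' @param p_threshold significance threshold.
#' @param omega_threshold large-effect-size threshold.
#' @param rate_range admissible mean firing rates, Hz (set to `c(-Inf, Inf)`
#'   to keep all neurons); rates are taken as the rate columns' means.
#' @return An object of class `effect_report`: a list with the tidy `table`
#'   (neuron, effect, SS, df, F, p, omega_sq, selected), the logical
#'   `categories` matrix (neuron x effect), the `preferred` condition table,
#'   and the indices of `kept` neurons.
#' @export
anova_categorize <- function(data, p_threshold = 0.001,
                             omega_threshold = 0.14, rate_range = c(2, 60)) {
  fac_cols <- c("task", "position", "symbol")
  stopifnot(all(fac_cols %in% names(data)))
  rate_cols <- setdiff(names(data), fac_cols)
  y <- as.matrix(data[rate_cols])
  mean_rates <- colMeans(y)
  kept <- which(mean_rates >= rate_range[1] & mean_rates <= rate_range[2])
  if (length(kept) == 0) stop("anova_categorize: no neuron passes the rate filter")
  y <- y[, kept, drop = FALSE]

  an <- anova3_balanced(y, data$task, data$position, data$symbol)
  omega <- sweep(an$ss - an$df[anova_effects] * rep(an$ms_err,
                                                    each = nrow(an$ss)),
                 2, an$ss_total + an$ms_err, "/")
  dimnames(omega) <- dimnames(an$ss)
  selected <- an$p < p_threshold & omega > omega_threshold

  tab <- data.frame(
    neuron = rep(colnames(y), each = length(anova_effects)),
    effect = rep(anova_effects, times = ncol(y)),
    SS = as.vector(an$ss), df = rep(an$df, times = ncol(y)),
    F = as.vector(an$F), p = as.vector(an$p),
    omega_sq = as.vector(omega), selected = as.vector(selected),
    row.names = NULL)

  pref <- preferred_conditions(y, data, which(colSums(selected) > 0),
                               p_threshold)
  structure(list(table = tab, categories = t(selected),
                 omega_sq = t(omega), p = t(an$p),
                 preferred = pref, kept = rate_cols[kept],
                 mean_rates = mean_rates),
            class = "effect_report")
}

# Welch t-statistic of each condition triple against all other samples;
# vectorised over conditions via per-cell means and variances.
preferred_conditions <- function(y, data, neuron_idx, p_threshold) {
  if (length(neuron_idx) == 0)
    return(data.frame(neuron = character(0), task = character(0),
                      position = character(0), symbol = character(0),
                      t = numeric(0), p = numeric(0)))
  cell <- interaction(data$task, data$position, data$symbol, sep = "\r",
                      lex.order = TRUE, drop = FALSE)
  n1 <- as.vector(table(cell))
  N <- nrow(y)
  out <- lapply(seq_along(neuron_idx), function(ii) {
    j <- neuron_idx[ii]
    v <- y[, j]
    s1 <- as.vector(rowsum(v, cell)); m1 <- s1 / n1
    q1 <- as.vector(rowsum(v^2, cell))
    var1 <- (q1 - n1 * m1^2) / (n1 - 1)
    n2 <- N - n1
    m2 <- (sum(v) - s1) / n2
    q2 <- sum(v^2) - q1
    var2 <- (q2 - n2 * m2^2) / (n2 - 1)
    se <- sqrt(var1 / n1 + var2 / n2)
    tstat <- (m1 - m2) / se
    dfw <- (var1 / n1 + var2 / n2)^2 /
      ((var1 / n1)^2 / (n1 - 1) + (var2 / n2)^2 / (n2 - 1))
    pw <- 2 * pt(abs(tstat), dfw, lower.tail = FALSE)
    ok <- which(pw < p_threshold)
    if (length(ok) == 0) return(NULL)
    best <- ok[which.max(tstat[ok])]
    lv <- strsplit(levels(cell)[best], "\r", fixed = TRUE)[[1]]
    data.frame(neuron = colnames(y)[j], task = lv[1], position = lv[2],
               symbol = lv[3], t = tstat[best], p = pw[best])
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' @export
print.effect_report <- function(x, ...) {
  cat("effect_report: ", nrow(x$categories), " neurons analysed (",
      sum(rowSums(x$categories) > 0), " categorised)\n", sep = "")
  cnt <- colSums(x$categories)
  for (e in names(cnt)) cat(sprintf("  %-22s %d\n", e, cnt[e]))
  invisible(x)
}

#' Build a balanced condition/rate table for the ANOVA
#'
#' Converts simulated duplication/reversal records into one data point per
#' episode: a random serial position of the input period is drawn, the
#' spike count of every neuron in that 500 ms slot becomes its rate sample,
#' and the point is labelled with (task, position, symbol). The table is
#' then balanced by randomly discarding excess points so every condition has
#' the same number of replicates.
#'
#' @param records an `snn_records` from a duplication/reversal batch (or a
#'   list of them).
#' @param n_per_condition replicates per condition to keep (`NULL` = the
#'   minimum available count).
#' @param seed seed for position choice and subsampling.
#' @return A data frame with `task`, `position`, `symbol` and one rate
#'   column per neuron (Hz), balanced across conditions.
#' @export
balance_conditions <- function(records, n_per_condition = NULL, seed = 1) {
  if (inherits(records, "snn_records")) records <- list(records)
  with_seed(seed, {
    rows <- list()
    for (rec in records) {
      batch <- rec$batch
      stopifnot(!is.null(batch$meta$strings))
      step_ms <- batch$meta$step_ms
      B <- dim(rec$z)[1]
      slen <- ncol(batch$meta$strings)
      for (b in seq_len(B)) {
        pos <- sample.int(slen, 1)  # one point per episode, input period
        slot <- 1 + pos             # slot 1 is the task cue
        w <- ((slot - 1) * step_ms + 1):(slot * step_ms)
        counts <- rowSums(rec$z[b, , w, drop = FALSE][, , , drop = TRUE])
        rows[[length(rows) + 1]] <- c(
          list(task = batch$meta$task[b], position = pos,
               symbol = batch$meta$strings[b, pos]),
          as.list(counts / (step_ms / 1000)))
      }
    }
    df <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(r, col.names = c("task", "position", "symbol",
                                     paste0("n", seq_len(length(r) - 3))))))
    cell <- interaction(df$task, df$position, df$symbol, drop = FALSE)
    counts <- table(cell)
    keep_n <- n_per_condition %||% min(counts)
    if (min(counts) < keep_n)
      stop("balance_conditions: fewest-sampled condition has only ",
           min(counts), " points (need ", keep_n, ")")
    idx <- unlist(lapply(split(seq_len(nrow(df)), cell), function(i)
      i[sample.int(length(i), keep_n)]))
    df[sort(idx), , drop = FALSE]
  })
}

## ---------------------------------------------------------------------------
## Peak-activity sorting

#' Sort neurons by the time of their peak activity
#'
#' Smooths trial-averaged activity with a boxcar, finds each neuron's peak
#' time bin (ties broken towards the earliest bin), and returns the neuron
#' ordering together with the peak-normalised activity matrix. The ordering
#' is invariant to uniform rescaling of a neuron's rate.
#'
#' @param activity trial-averaged activity, neurons x time bins.
#' @param smooth_bins boxcar width in bins (50 ms at 1 ms bins by default).
#' @return A list with `order` (neuron indices sorted by peak time),
#'   `peak_bin`, and the smoothed, peak-normalised, row-sorted matrix
#'   `normalized`.
#' @export
sort_by_peak <- function(activity, smooth_bins = 50) {
  activity <- as.matrix(activity)
  if (smooth_bins > 1) {
    kern <- rep(1 / smooth_bins, smooth_bins)
    sm <- t(apply(activity, 1, function(r)
      stats::filter(r, kern, sides = 2)))
    sm[is.na(sm)] <- 0
  } else sm <- activity
  peak_bin <- apply(sm, 1, which.max)
  ord <- order(peak_bin)
  mx <- apply(sm, 1, max)
  norm <- sweep(sm, 1, ifelse(mx > 0, mx, 1), "/")
  list(order = ord, peak_bin = peak_bin, normalized = norm[ord, , drop = FALSE])
}
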