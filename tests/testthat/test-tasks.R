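# Procedural task generators.

test_that("1-D STORE-RECALL episodes are well formed", {
  task <- store_recall_task(n_steps = 12, step_ms = 50)
  set.seed(1)
  b <- task$sample(50)
  expect_equal(dim(b$x), c(50, 40, 600))
  cmd <- b$meta$cmd
  for (e in 1:50) {
    st <- which(cmd[e, ] == "store"); rc <- which(cmd[e, ] == "recall")
    # every episode carries at least one complete pair, commands alternate
    expect_gte(length(st), 1)
    expect_gte(length(rc), 1)
    expect_lt(min(st), min(rc))
    both <- sort(c(st, rc))
    expect_true(all(diff(match(cmd[e, both], c("store", "recall"))) != 0))
    # recall target equals the value at the most recent store
    for (k in seq_along(rc)) {
      last_store <- max(st[st < rc[k]])
      expect_equal(b$targets[e, k, 1], b$meta$values[e, last_store])
    }
  }
  # decision mask covers exactly the recall windows (50 ms each)
  expect_equal(unname(rowSums(b$win_id > 0)), b$n_dec * 50L)
})

test_that("1-D STORE-RECALL delays lie in the stated range for 200 ms steps", {
  task <- store_recall_task(n_steps = 20, step_ms = 200)
  set.seed(2)
  b <- task$sample(200)
  delays <- c()
  for (e in 1:200) {
    cmd <- b$meta$cmd[e, ]
    st <- which(cmd == "store"); rc <- which(cmd == "recall")
    for (r in rc) delays <- c(delays, (r - max(st[st < r])) * 200)
  }
  expect_gte(min(delays), 200)
  expect_lte(max(delays), 3600)
})

test_that("active input populations fire near their nominal Poisson rate", {
  task <- store_recall_task(n_steps = 12, step_ms = 50, rate_hi = 50)
  set.seed(3)
  b <- task$sample(100)
  # collect spikes of the STORE population during store steps
  n_spk <- 0; n_ms <- 0
  for (e in 1:100) {
    st <- which(b$meta$cmd[e, ] == "store")
    for (s in st) {
      w <- ((s - 1) * 50 + 1):(s * 50)
      n_spk <- n_spk + sum(b$x[e, 1:10, w])
      n_ms <- n_ms + 10 * 50
    }
  }
  rate <- 1000 * n_spk / n_ms
  se <- 1000 * sqrt(0.05 * 0.95 / n_ms)
  expect_lt(abs(rate - 50), 3 * se)
})

test_that("generators are deterministic under a fixed seed", {
  task <- store_recall_task(n_steps = 8, step_ms = 50)
  b1 <- sfanet:::with_seed(9, task$sample(3))
  b2 <- sfanet:::with_seed(9, task$sample(3))
  expect_identical(b1$x, b2$x)
  expect_identical(b1$targets, b2$targets)
  t12 <- task_12ax(n_symbols = 15, step_ms = 50)
  c1 <- sfanet:::with_seed(4, t12$sample(2))
  c2 <- sfanet:::with_seed(4, t12$sample(2))
  expect_identical(c1$x, c2$x)
})

test_that("Hamming dictionary respects the distance constraints exhaustively", {
  set.seed(5)
  ref <- hamming_dictionary(20, bits = 20, min_dist = 5)
  # pairwise within the reference dictionary
  for (i in 1:19) for (j in (i + 1):20)
    expect_gte(sum(ref[i, ] != ref[j, ]), 5)
  train <- hamming_dictionary(40, bits = 20, min_dist = 5, ref = ref)
  for (i in 1:40) for (j in 1:20)
    expect_gte(sum(train[i, ] != ref[j, ]), 5)
  expect_error(hamming_dictionary(1000, bits = 4, min_dist = 4,
                                  max_tries = 200), "tries")
})

test_that("20-D STORE-RECALL batches code values correctly and silence them at recall", {
  task <- store_recall_task_20d(dict_seed = 1)
  set.seed(6)
  b <- task$sample(12)
  expect_equal(dim(b$x), c(12, 88, 2000))
  for (e in 1:12) {
    cmd <- b$meta$cmd[e, ]
    st <- which(cmd == "store"); rc <- which(cmd == "recall")
    expect_gte(length(rc), 1)
    for (k in seq_along(rc)) {
      last_store <- max(st[st < rc[k]])
      expect_equal(b$targets[e, k, ], b$meta$shown[e, last_store, ])
      # value channels silent during the recall step (no Poisson baseline)
      w <- ((rc[k] - 1) * 200 + 1):(rc[k] * 200)
      expect_equal(sum(b$x[e, 9:88, w]), 0)
      # command channels active
      expect_gt(sum(b$x[e, 5:8, w]), 0)
    }
  }
  # every training string is >= 5 bits from every test string
  for (i in seq_len(nrow(b$meta$dict)))
    expect_gte(min(colSums(abs(t(task$config$test_dict) - b$meta$dict[i, ]))), 5)
  # test batches draw from the held-out dictionary
  bt <- task$sample(4, test = TRUE)
  expect_identical(bt$meta$dict, task$config$test_dict)
})

test_that("12AX labels follow the context-dependent rule on hand examples", {
  expect_equal(label_12ax(c("1", "A", "X")), c("L", "L", "R"))
  expect_equal(label_12ax(c("2", "A", "X")), c("L", "L", "L"))
  expect_equal(label_12ax(c("2", "B", "C", "Y")), c("L", "L", "L", "R"))
  expect_equal(label_12ax(c("1", "B", "Y")), c("L", "L", "L"))
  expect_equal(label_12ax(c("1", "A", "B", "X")), c("L", "L", "L", "L"))
  expect_equal(label_12ax(c("1", "A", "C", "Z", "X")),
               c("L", "L", "L", "L", "R"))
  expect_equal(label_12ax(c("1", "A", "X", "X")), c("L", "L", "R", "L"))
  expect_equal(label_12ax(c("1", "A", "2", "X")), c("L", "L", "L", "L"))
})

test_that("12AX labels agree with an independent backward-scan oracle", {
  # oracle: a symbol X (Y) earns R iff the most recent non-distractor symbol
  # before it is A (B) and the most recent digit is 1 (2); implemented by
  # scanning backwards from each position, independent of the generator FSM
  oracle <- function(sym) {
    out <- rep("L", length(sym))
    for (i in seq_along(sym)) {
      s <- sym[i]
      if (s != "X" && s != "Y") next
      digit <- NA; lastrel <- NA
      for (j in rev(seq_len(i - 1))) {
        if (is.na(lastrel) && !(sym[j] %in% c("C", "Z"))) lastrel <- sym[j]
        if (sym[j] %in% c("1", "2")) { digit <- sym[j]; break }
      }
      if (!is.na(lastrel) && !is.na(digit) &&
          ((s == "X" && digit == "1" && lastrel == "A") ||
           (s == "Y" && digit == "2" && lastrel == "B")))
        out[i] <- "R"
    }
    out
  }
  set.seed(8)
  alph <- c("1", "2", "A", "B", "C", "X", "Y", "Z")
  n_checked <- 0
  for (r in 1:500) {
    sym <- sample(alph, 20, replace = TRUE)
    expect_identical(label_12ax(sym), oracle(sym))
    n_checked <- n_checked + length(sym)
  }
  expect_gte(n_checked, 1e4)
})

test_that("12AX episodes have 90 symbols and 4-23 digits", {
  task <- task_12ax(n_symbols = 90, step_ms = 50) # short windows for speed
  set.seed(9)
  b <- task$sample(6)
  for (e in 1:6) {
    sym <- b$meta$symbols[e, ]
    expect_length(sym, 90)
    nd <- sum(sym %in% c("1", "2"))
    expect_gte(nd, 4); expect_lte(nd, 23)
    lab <- label_12ax(sym)
    expect_equal(b$targets[e, ], ifelse(lab == "R", 2L, 1L))
  }
  expect_equal(b$n_dec, rep(90L, 6))
})

test_that("duplication/reversal targets are the string or its reversal", {
  task <- duplication_task(string_len = 5, n_letters = 8, step_ms = 50)
  set.seed(10)
  b <- task$sample(30)
  for (e in 1:30) {
    str <- b$meta$strings[e, ]
    tg <- b$targets[e, ]
    if (b$meta$task[e] == "duplicate") expect_equal(tg, str)
    else expect_equal(tg, rev(str))
  }
  # palindromes share one target under both tasks
  pal <- c(2L, 5L, 3L, 5L, 2L)
  expect_identical(pal, rev(pal))
  # high/low coding: active population well above the 2 Hz background
  on_rate <- mean(b$x[1, (b$meta$strings[1, 1] - 1) * 5 + 1:5,
                      ((1 * 50) + 1):(2 * 50)])
  expect_gt(on_rate, 0.1) # ~200 Hz = 0.2 spikes/ms
})

test_that("sMNIST threshold-crossing encoder follows the crossing rule", {
  # constant image: no spikes anywhere
  expect_equal(sum(encode_smnist(matrix(0.4, 28, 28))), 0)
  # a 0 -> 1 step crosses every threshold: all 80 channels spike once
  px <- c(0, 1, 1, 0.5)
  r <- encode_smnist(px)
  expect_equal(sum(r[1, ]), 0)
  expect_equal(sum(r[2, ]), 80)            # upward crossing of all thresholds
  expect_equal(sum(r[3, ]), 0)             # no change
  expect_equal(sum(r[4, ]), sum(seq_len(80) / 81 > 0.5 & seq_len(80) / 81 < 1))
  # determinism
  set.seed(11)
  img <- matrix(runif(784), 28, 28)
  expect_identical(encode_smnist(img), encode_smnist(img))
  # row-wise scanline: transposing the image changes the raster
  expect_false(identical(encode_smnist(img), encode_smnist(t(img))))
  expect_error(encode_smnist(matrix(2, 28, 28)), "\\[0, 1\\]")
})

test_that("smnist_task wraps the encoder into decision batches", {
  set.seed(12)
  imgs <- array(runif(3 * 28 * 28), dim = c(3, 28, 28))
  task <- smnist_task(imgs, labels = c(3, 1, 7))
  b <- task$sample(3)
  expect_equal(dim(b$x), c(3, 80, 784))
  expect_true(all(b$targets %in% c(4L, 2L, 8L)))
  expect_equal(b$n_dec, rep(1L, 3))
})
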