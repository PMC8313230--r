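# Network assembly and batched simulation.

test_that("weight initialisation has the prescribed scale and is seeded", {
  w <- init_weights(n_in = 100, n_rec = 100, n_out = 4, seed = 11, w0 = 1)
  # empirical SD of entries ~ w0/sqrt(n_afferent) within a few percent
  expect_equal(sd(w$Win), 1 / 10, tolerance = 0.05)
  expect_equal(mean(w$Win), 0, tolerance = 3 * 0.1 / sqrt(1e4))
  expect_identical(w$bout, numeric(4))
  # determinism
  w2 <- init_weights(100, 100, 4, seed = 11, w0 = 1)
  expect_identical(w, w2)
  # no self-connections by default
  expect_true(all(diag(w$Wrec) == 0))
  w3 <- init_weights(10, 10, 1, seed = 1, self_connections = TRUE)
  expect_true(any(diag(w3$Wrec) != 0))
})

test_that("input_current is the delayed weighted spike sum", {
  net <- tiny_network(n_in = 3, n_rec = 4, n_out = 1, seed = 3)
  T_ <- 20
  xin <- matrix(0, T_, 3); zrec <- matrix(0, T_, 4)
  # all-zero spikes give zero current
  expect_equal(input_current(xin, zrec, net, t = 10), numeric(4))
  # single input spike at t through weight column arrives at t + 1
  xin[5, 2] <- 1
  expect_equal(input_current(xin, zrec, net, t = 6), 1000 * net$Win[, 2])
  expect_equal(input_current(xin, zrec, net, t = 5), numeric(4))
  expect_equal(input_current(xin, zrec, net, t = 7), numeric(4))
  # random sparse history equals the dense matrix-product oracle
  set.seed(2)
  xin <- matrix(rbinom(T_ * 3, 1, 0.2), T_, 3)
  zrec <- matrix(rbinom(T_ * 4, 1, 0.2), T_, 4)
  for (t in c(2, 7, 20)) {
    oracle <- 1000 * (net$Win %*% xin[t - 1, ] + net$Wrec %*% zrec[t - 1, ])
    expect_equal(input_current(xin, zrec, net, t), drop(oracle),
                 tolerance = 1e-12)
  }
  expect_error(input_current(xin[, 1:2], zrec, net, 5), "shape")
})

test_that("compiled simulator reproduces the single-step kernel reference", {
  for (seed in 1:3) {
    net <- tiny_network(n_in = 5, n_rec = 7, n_out = 2, seed = seed)
    x <- random_raster(80, 5, rate_hz = 150, seed = seed + 10)
    ref <- ref_simulate(net, x)
    fw <- sfanet:::forward_pass(net, as_batch_array(x), record_grad = TRUE)
    expect_identical(unname(t(ref$z)), unname(fw$z[1, , ]))
    for (nm in c("A", "pd", "v", "vp", "s", "y")) {
      expect_equal(unname(t(ref[[nm]])), unname(fw[[nm]][1, , ]),
                   tolerance = 1e-12)
    }
  }
})

test_that("compiled simulator matches the kernel reference with STP synapses", {
  stp <- stp_params(U = 0.3, F = 300, D = 150)
  net <- tiny_network(n_in = 5, n_rec = 6, n_out = 2, seed = 4, stp = stp)
  x <- random_raster(80, 5, rate_hz = 200, seed = 9)
  ref <- ref_simulate(net, x)
  fw <- sfanet:::forward_pass(net, as_batch_array(x))
  expect_identical(unname(t(ref$z)), unname(fw$z[1, , ]))
  expect_equal(unname(t(ref$y)), unname(fw$y[1, , ]), tolerance = 1e-12)
})

test_that("beta = 0 makes the SFA network equal a plain LIF network bit for bit", {
  net_sfa <- snn_network(6, 10, 2, frac_sfa = 1, beta = 0, tau_a = 200,
                         seed = 5)
  net_lif <- snn_network(6, 10, 2, frac_sfa = 0, seed = 5)
  # same seed gives identical weights; only the SFA assignment differs
  expect_identical(net_sfa$Win, net_lif$Win)
  x <- array(random_raster(120, 6, rate_hz = 300, seed = 2), dim = c(120, 6))
  fa <- sfanet:::forward_pass(net_sfa, as_batch_array(x))
  fl <- sfanet:::forward_pass(net_lif, as_batch_array(x))
  expect_identical(fa$z, fl$z)
  expect_identical(fa$v, fl$v)
})

test_that("batched and single-episode simulation agree", {
  net <- tiny_network(n_in = 4, n_rec = 6, n_out = 2, seed = 6)
  set.seed(31)
  B <- 5; T_ <- 60
  x <- array(rbinom(B * 4 * T_, 1, 0.15), dim = c(B, 4, T_))
  full <- sfanet:::forward_pass(net, x)
  for (b in seq_len(B)) {
    single <- sfanet:::forward_pass(net, x[b, , , drop = FALSE])
    expect_identical(full$z[b, , ], single$z[1, , ])
    expect_equal(full$y[b, , ], single$y[1, , ], tolerance = 1e-12)
  }
})

test_that("zero weights and zero input give a silent network at bias level", {
  net <- tiny_network(n_in = 3, n_rec = 5, n_out = 2, seed = 7)
  net$Win[] <- 0; net$Wrec[] <- 0; net$bout <- c(0.3, -0.2)
  x <- array(0, dim = c(1, 3, 50))
  fw <- sfanet:::forward_pass(net, x)
  expect_true(all(fw$z == 0))
  expect_equal(fw$y[1, 1, ], rep(0.3, 50))
  expect_equal(fw$y[1, 2, ], rep(-0.2, 50))
})

test_that("a single spike drives an exponential readout trace", {
  net <- snn_network(1, 1, 1, frac_sfa = 0, tau_out = 20, seed = 1)
  net$Win <- matrix(0.4, 1, 1) # one strong input spike -> one network spike
  net$Wrec <- matrix(0, 1, 1)
  net$Wout <- matrix(1, 1, 1); net$bout <- 0
  x <- array(0, dim = c(1, 1, 100)); x[1, 1, 5] <- 1
  fw <- sfanet:::forward_pass(net, x)
  ts <- which(fw$z[1, 1, ] > 0)
  expect_length(ts, 1)
  kappa <- exp(-1 / 20)
  k <- 15:60
  trace <- fw$y[1, 1, k]
  expected <- kappa^(k - ts)
  expect_equal(trace, expected, tolerance = 1e-12)
})

test_that("logged firing rates match an offline recount of the raster", {
  net <- tiny_network(n_in = 4, n_rec = 6, n_out = 2, seed = 8)
  set.seed(3)
  x <- array(rbinom(3 * 4 * 200, 1, 0.2), dim = c(3, 4, 200))
  rec <- simulate(net, x = x)
  for (b in 1:3)
    for (j in 1:6)
      expect_equal(rec$rates[b, j], sum(rec$z[b, j, ]) / 0.2, tolerance = 1e-12)
})

test_that("readout decisions: softmax sums to one, sigmoid lies in (0,1)", {
  task <- store_recall_task(n_steps = 8, step_ms = 50)
  net <- snn_network(task$n_in, 20, 1, frac_sfa = 1, beta = 1000,
                     tau_a = 200, seed = 2)
  set.seed(5)
  rec <- simulate(net, batch = task$sample(4))
  act <- rec$decisions$activations
  expect_true(all(act > 0 & act < 1))
  dup <- duplication_task(string_len = 2, n_letters = 4, step_ms = 50)
  net2 <- snn_network(dup$n_in, 20, 4, frac_sfa = 1, beta = 1000,
                      tau_a = 200, tau_out = 250, seed = 2)
  set.seed(5)
  rec2 <- simulate(net2, batch = dup$sample(3))
  expect_equal(rowSums(rec2$decisions$activations), rep(1, 6),
               tolerance = 1e-12)
})

test_that("success_rate scores decisions, episodes and bits", {
  pred <- rbind(c(1, 2, 1), c(2, 2, 1))
  targ <- rbind(c(1, 2, 1), c(2, 1, 1))
  expect_equal(success_rate(pred, targ, "decision"), 5 / 6)
  # one wrong symbol fails the whole episode regardless of the others
  expect_equal(success_rate(pred, targ, "episode"), 0.5)
  expect_error(success_rate(pred, targ[, 1:2]), "shapes")
  # bit-level arrays
  p3 <- array(c(1, 0, 1, 1), dim = c(1, 2, 2))
  t3 <- array(c(1, 0, 0, 1), dim = c(1, 2, 2))
  expect_equal(success_rate(p3, t3, "bit"), 0.75)
  expect_equal(success_rate(p3, t3, "decision"), 0.5)
  # NA padding is ignored
  predn <- rbind(c(1, NA), c(2, 2))
  targn <- rbind(c(1, NA), c(2, 2))
  expect_equal(success_rate(predn, targn, "decision"), 1)
  expect_equal(success_rate(predn, targn, "episode"), 1)
})

test_that("random softmax predictions essentially never yield full episodes", {
  # with 8 symbols and 90 decisions per episode, the chance of an all-correct
  # episode is 8^-90; a random readout must score an episode rate of 0
  set.seed(1)
  pred <- matrix(sample(1:8, 20 * 90, replace = TRUE), 20, 90)
  targ <- matrix(sample(1:8, 20 * 90, replace = TRUE), 20, 90)
  expect_equal(success_rate(pred, targ, "episode"), 0)
  expect_equal(success_rate(pred, targ, "decision"), 1 / 8, tolerance = 0.25)
})

test_that("network and record serialisation round-trip", {
  net <- tiny_network(n_in = 3, n_rec = 5, n_out = 2, seed = 9)
  tmp <- tempfile(fileext = ".json")
  write_snn(net, tmp)
  net2 <- read_snn(tmp)
  expect_equal(net2$Win, net$Win, tolerance = 1e-12)
  expect_equal(net2$Wrec, net$Wrec, tolerance = 1e-12)
  expect_equal(net2$sfa$beta, net$sfa$beta, tolerance = 1e-12)
  expect_identical(net2$sfa_mask, net$sfa_mask)
  # near-identical dynamics after the round trip (weights at JSON precision)
  x <- random_raster(50, 3, rate_hz = 200, seed = 1)
  f1 <- sfanet:::forward_pass(net, as_batch_array(x))
  f2 <- sfanet:::forward_pass(net2, as_batch_array(x))
  expect_equal(f1$z, f2$z, tolerance = 1e-12)

  set.seed(2)
  rec <- simulate(net2, x = array(rbinom(2 * 3 * 50, 1, 0.2),
                                  dim = c(2, 3, 50)))
  d <- tempfile()
  save_records(rec, d)
  back <- load_records(d)
  expect_equal(back$z, rec$z, tolerance = 1e-12)
  expect_equal(back$A, rec$A, tolerance = 1e-9)
  unlink(d, recursive = TRUE); unlink(tmp)
})
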