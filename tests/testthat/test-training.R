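# Losses and the surrogate-gradient BPTT training machinery.

make_sigmoid_batch <- function(x, win_steps, targets_bits) {
  T_ <- nrow(x)
  win_id <- matrix(0L, 1, T_); win_id[1, win_steps] <- 1L
  structure(list(x = as_batch_array(x), mode = "sigmoid", win_id = win_id,
                 n_dec = 1L,
                 targets = array(targets_bits, dim = c(1, 1, length(targets_bits))),
                 threshold = 0.5, meta = list()), class = "snn_batch")
}

test_that("rate regulariser penalises squared deviation from the target", {
  # every neuron exactly at target -> 0
  T_ <- 1000
  z <- array(0, dim = c(1, 3, T_))
  for (j in 1:3) z[1, j, seq(1, T_, by = 100)] <- 1 # 10 Hz each
  expect_equal(rate_regularizer(z, target_rate = 10, coeff = 0.001), 0)
  # one neuron at 20 Hz: coeff * (20 - 10)^2
  z[1, 2, seq(51, T_, by = 100)] <- 1
  expect_equal(rate_regularizer(z, 10, 0.001), 0.001 * 100)
  # linear in the coefficient
  expect_equal(rate_regularizer(z, 10, 0.002), 2 * rate_regularizer(z, 10, 0.001))
})

test_that("task losses reach their closed-form values", {
  # uniform softmax over 10 classes: ln 10 per decision
  y <- array(0, dim = c(2, 10, 5))
  win_id <- matrix(0L, 2, 5); win_id[, 5] <- 1L
  batch <- structure(list(x = array(0, dim = c(2, 1, 5)), mode = "softmax_end",
                          win_id = win_id, n_dec = c(1L, 1L),
                          targets = matrix(c(3L, 7L), 2, 1), meta = list()),
                     class = "snn_batch")
  lt <- sfanet:::loss_task(list(y = y, z = array(0, dim = c(2, 2, 5))),
                           batch, NULL)
  expect_equal(lt$loss, log(10), tolerance = 1e-12)
  # softmax probability 1 on the true class -> loss 0
  y[1, 3, 5] <- 1e4; y[2, 7, 5] <- 1e4
  lt2 <- sfanet:::loss_task(list(y = y), batch, NULL)
  expect_equal(lt2$loss, 0, tolerance = 1e-6)
  expect_true(all(lt2$acc == 1))
  # 20 sigmoid bits at exactly 0.5: 20 ln 2 per recall
  y3 <- array(0, dim = c(1, 20, 8))
  b3 <- structure(list(x = array(0, dim = c(1, 1, 8)), mode = "sigmoid",
                       win_id = matrix(c(0L, 0L, 1L, 1L, 1L, 1L, 0L, 0L), 1),
                       n_dec = 1L,
                       targets = array(rep(c(0, 1), 10), dim = c(1, 1, 20)),
                       threshold = 0.5, meta = list()), class = "snn_batch")
  lt3 <- sfanet:::loss_task(list(y = y3), b3, NULL)
  expect_equal(lt3$loss, 20 * log(2), tolerance = 1e-12)
})

test_that("custom backward equals the forward-mode autodiff oracle", {
  # 3 neurons, 10 steps, full comparison of all weight gradients at 1e-6
  # relative tolerance
  net <- tiny_network(n_in = 4, n_rec = 3, n_out = 2, seed = 2,
                      self_connections = TRUE)
  net$bout <- c(0.1, -0.2)
  x <- random_raster(10, 4, rate_hz = 400, seed = 5)
  batch <- make_sigmoid_batch(x, 5:10, c(1, 0))
  cfg <- train_config(gamma = 0.3, reg_coeff = 0.01, target_rate = 10)
  bg <- sfanet:::bptt_gradients(net, batch, cfg)
  og <- oracle_gradients(net, x, batch, gamma = 0.3, reg_coeff = 0.01,
                         target_rate = 10)
  for (nm in c("Win", "Wrec", "Wout", "bout")) {
    scale <- max(abs(og[[nm]]))
    expect_gt(scale, 0)
    expect_lt(max(abs(bg$grads[[nm]] - og[[nm]])) / scale, 1e-6)
  }
})

test_that("gamma = 0 kills every weight gradient through the spike function", {
  net <- tiny_network(n_in = 4, n_rec = 5, n_out = 1, seed = 3)
  x <- random_raster(60, 4, rate_hz = 300, seed = 6)
  batch <- make_sigmoid_batch(x, 40:60, 1)
  cfg0 <- train_config(gamma = 0, reg_coeff = 0.01)
  bg <- sfanet:::bptt_gradients(net, batch, cfg0)
  expect_true(all(bg$grads$Win == 0))
  expect_true(all(bg$grads$Wrec == 0))
  # the readout path does not cross a spike derivative and survives
  expect_gt(max(abs(bg$grads$Wout)), 0)
})

test_that("a weight with no path to the loss gets zero gradient", {
  net <- tiny_network(n_in = 3, n_rec = 4, n_out = 1, seed = 4)
  # neuron 4 projects nowhere: no readout weight, no recurrent output
  net$Wout[, 4] <- 0
  net$Wrec[, 4] <- 0
  x <- random_raster(50, 3, rate_hz = 300, seed = 2)
  batch <- make_sigmoid_batch(x, 30:50, 1)
  cfg <- train_config(gamma = 0.3, reg_coeff = 0) # no rate regularisation
  bg <- sfanet:::bptt_gradients(net, batch, cfg)
  expect_equal(max(abs(bg$grads$Win[4, ])), 0)
  expect_equal(max(abs(bg$grads$Wrec[4, ])), 0)
})

test_that("training is deterministic given the seed and untouched at 0 iterations", {
  task <- store_recall_task(n_steps = 6, step_ms = 50)
  cfg <- train_config(iterations = 4, batch_size = 4, seed = 7)
  f1 <- snn(task, train = cfg, n_rec = 12)
  f2 <- snn(task, train = cfg, n_rec = 12)
  expect_identical(f1$curve, f2$curve)
  expect_identical(f1$network$Win, f2$network$Win)
  net <- snn_network(task$n_in, 12, 1, seed = 1)
  f0 <- snn(task, train = train_config(iterations = 0, seed = 1),
            network = net)
  expect_identical(f0$network$Win, net$Win)
  expect_identical(f0$iterations_run, 0L)
})

test_that("learning-rate schedule decays stepwise and can ramp", {
  cfg <- train_config(lr = 0.01, lr_decay = 0.3, decay_every = 100)
  expect_equal(sfanet:::schedule_lr(cfg, 1), 0.01)
  expect_equal(sfanet:::schedule_lr(cfg, 100), 0.01)
  expect_equal(sfanet:::schedule_lr(cfg, 101), 0.003)
  expect_equal(sfanet:::schedule_lr(cfg, 301), 0.01 * 0.3^3)
  cfgr <- train_config(lr = 0.01, lr_ramp = TRUE, lr_ramp_from = 1e-5,
                       lr_ramp_iters = 200, decay_every = Inf)
  expect_equal(sfanet:::schedule_lr(cfgr, 1), 1e-5)
  expect_equal(sfanet:::schedule_lr(cfgr, 200), 0.01)
  expect_equal(sfanet:::schedule_lr(cfgr, 300), 0.01)
  lrs <- vapply(1:200, function(i) sfanet:::schedule_lr(cfgr, i), 0)
  expect_true(all(diff(lrs) > 0)) # monotonically increasing ramp
})

test_that("rate regularisation alone drives rates towards the target", {
  # train with the task loss weighted to zero: only the regulariser remains
  task <- store_recall_task(n_steps = 8, step_ms = 50)
  net <- snn_network(task$n_in, 30, 1, frac_sfa = 1, beta = 1000,
                     tau_a = 200, seed = 2)
  cfg <- train_config(iterations = 120, batch_size = 16, lr = 0.01,
                      lr_decay = 0.5, decay_every = 40, reg_coeff = 1,
                      target_rate = 10, task_weight = 0, seed = 3)
  fit <- snn(task, train = cfg, network = net)
  expect_gt(fit$curve$mean_rate[1], 20) # starts well above target
  set.seed(5)
  rec <- simulate(fit$network, batch = task$sample(64))
  expect_lt(abs(mean(rec$rates) - 10), 1) # pulled to within 1 Hz of target
})

test_that("bptt_step applies one Adam update and reports the loss breakdown", {
  task <- store_recall_task(n_steps = 6, step_ms = 50)
  net <- snn_network(task$n_in, 15, 1, seed = 5)
  set.seed(1)
  batch <- task$sample(4)
  cfg <- train_config()
  step <- bptt_step(net, batch, cfg)
  expect_false(identical(step$network$Win, net$Win))
  expect_equal(step$loss$total,
               step$loss$task_loss + step$loss$rate_reg -
                 step$loss$entropy_bonus)
  # STP networks are rejected
  nets <- snn_network(task$n_in, 15, 1, seed = 5,
                      stp = stp_params(0.3, 100, 100))
  expect_error(bptt_step(nets, batch, cfg), "STP")
})

test_that("gradient flow across a 500 ms gap requires the adaptation variable", {
  # a single neuron is driven to spike early; 500 ms later a probe brings it
  # near threshold while the loss window is active. With beta > 0 the early
  # input weight influences the loss through the threshold trace; with
  # beta = 0 the influence decays with the membrane constant and vanishes.
  build <- function(beta) {
    net <- snn_network(n_in = 2, n_rec = 1, n_out = 1, frac_sfa = 1,
                       beta = beta, tau_a = 1200, tau_m = 20, v_th = 10,
                       t_refr = 3, seed = 1)
    net$Win <- matrix(c(0.35, 0.0105), 1, 2) # early driver; near-threshold probe
    net$Wrec <- matrix(0, 1, 1)
    net$Wout <- matrix(1, 1, 1); net$bout <- 0
    net
  }
  T_ <- 610
  x <- matrix(0, T_, 2)
  x[10, 1] <- 1                 # early pulse through weight 1
  x[530:T_, 2] <- 1             # sustained probe drive near threshold
  batch <- make_sigmoid_batch(x, 540:T_, 1)
  cfg <- train_config(gamma = 0.3, reg_coeff = 0)
  g_sfa <- sfanet:::bptt_gradients(build(2000), batch, cfg)$grads$Win[1, 1]
  g_lif <- sfanet:::bptt_gradients(build(0), batch, cfg)$grads$Win[1, 1]
  expect_gt(abs(g_sfa), 1e-6)
  expect_lt(abs(g_lif), 1e-10)
  expect_gt(abs(g_sfa) / max(abs(g_lif), 1e-300), 1e4)
})
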