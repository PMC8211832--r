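# Losses and training mechanics.

test_that("binary cross-entropy has its closed-form values", {
  expect_lt(loss_bce(c(1, 0), c(1, 0)), 1e-10)
  expect_equal(loss_bce(rep(0.5, 10), rep(c(0, 1), 5)), log(2))
  expect_equal(loss_bce(0.9, 1), -log(0.9))
  expect_error(loss_bce(0.5, 0.3), "binary")
})

test_that("Gaussian NLL has its closed-form values and variance gradient sign", {
  expect_equal(loss_nll_gaussian(0, 1 / (2 * pi), 0), 0)
  expect_equal(loss_nll_gaussian(0, 1, 0), 0.5 * log(2 * pi))
  # two variables sum; agents average
  mu <- matrix(0, 2, 2); s2 <- matrix(1, 2, 2); x <- matrix(0, 2, 2)
  expect_equal(loss_nll_gaussian(mu, s2, x), log(2 * pi))
  expect_error(loss_nll_gaussian(0, -1, 0), "positive")
  # far from the mean, increasing the variance lowers the NLL until s2 = dev^2
  dev <- 3
  nll_at <- function(s2) loss_nll_gaussian(0, s2, dev)
  expect_gt(nll_at(1), nll_at(4))
  expect_gt(nll_at(1e4), nll_at(dev^2))
})

test_that("weighted NLL uses inverse length-class frequencies with mean-one weights", {
  nll <- c(1, 2, 3, 4)
  expect_equal(loss_weighted_nll(nll, c(5, 5, 5, 5)), mean(nll))
  # frequencies 3:1 -> weights 1:3 before normalization
  w_raw <- c(1 / 3, 1 / 3, 1 / 3, 1)
  w <- w_raw / mean(w_raw)
  expect_equal(loss_weighted_nll(nll, c(7, 7, 7, 9)), mean(w * nll))
  expect_error(loss_weighted_nll(numeric(0), integer(0)), "empty")
})

test_that("training runs, logs, and decays the learning rate on plateaus", {
  ds <- generate_dataset("vicsek", config = sim_config("vicsek", n = 8),
                         n_samples = 24, seed = 1)
  m <- an_model(tiny_vicsek_cfg(), seed = 2)
  # an impossible improvement tolerance forces a plateau every `patience`
  # epochs, so the rate decays deterministically
  tc <- train_config(epochs = 5, seed = 3, batch_size = 8L, patience = 2L,
                     improve_tol = 1e6)
  m <- train_agentnet(m, ds, tc)
  expect_equal(nrow(m$log), 5)
  # epoch 1 counts as an improvement from nothing; decays land after epochs
  # 3 and 5 (logged rates show the value used during each epoch)
  expect_equal(m$log$lr, 5e-4 * 0.7^c(0, 0, 0, 1, 1))
  expect_true(all(is.finite(m$log$train_loss)))
  expect_false(is.null(m$norm))
  # training reduces the loss on this easy low-noise task
  expect_lt(m$log$train_loss[5], m$log$train_loss[1] + 0.05)
})

test_that("training configs validate their inputs", {
  expect_error(train_config(lr = -1), "positive")
  expect_error(train_config(decay = 1.2), "decay")
  expect_error(train_config(nonsense = 1), "nonsense")
  expect_error(train_config(loss = "hinge"), "loss")
})

test_that("recurrent multi-step training accepts both feedback modes", {
  cfg <- sim_config("aoup", n = 4, burn_steps = 5L, windows_per_run = 4L,
                    obs_steps = 3L, target_steps = 2L)
  ds <- generate_dataset("aoup", config = cfg, n_samples = 8, seed = 4)
  for (fb in c("teacher", "sample")) {
    m <- an_model(tiny_aoup_cfg(), seed = 5)
    tc <- train_config(epochs = 2, seed = 6, batch_size = 4L, feedback = fb)
    m <- train_agentnet(m, ds, tc)
    expect_equal(nrow(m$log), 2)
    expect_true(all(is.finite(m$log$val_loss)))
  }
})

test_that("rollouts sample forward and honor the degenerate-variance limit", {
  m <- an_model(tiny_vicsek_cfg(), seed = 7)
  st <- matrix(rnorm(5 * 4), 5, 4)
  r0 <- rollout(m, st, n_steps = 0)
  expect_equal(dim(r0$trajectory)[2], 0)

  r <- rollout(m, st, n_steps = 3, seed = 1)
  expect_equal(dim(r$trajectory), c(5, 3, 4))
  expect_length(r$attention, 3)

  # squeezing the variance head makes samples equal the mean rollout
  m2 <- m
  for (q in 1:2) {
    b <- paste0("s2", q, "_b2")
    m2$params[[b]][length(m2$params[[b]])] <- -50
  }
  rs <- rollout(m2, st, n_steps = 3, seed = 2)
  rm <- rollout(m2, st, n_steps = 3, seed = 3, mean_rollout = TRUE)
  expect_equal(rs$trajectory, rm$trajectory, tolerance = 1e-2)

  # recurrent models support long horizons (42 steps from an 8-step window)
  ma <- an_model(tiny_aoup_cfg(), seed = 8)
  obs <- array(rnorm(6 * 8 * 4, sd = 0.1), c(6, 8, 4))
  rr <- rollout(ma, obs, n_steps = 42, globals = 5, seed = 9)
  expect_equal(dim(rr$trajectory), c(6, 42, 4))
  expect_length(rr$attention, 42)
  expect_true(all(is.finite(rr$trajectory)))
})

test_that("training aborts with a diagnostic when the loss diverges", {
  ds <- generate_dataset("vicsek", config = sim_config("vicsek", n = 6),
                         n_samples = 12, seed = 8)
  m <- an_model(tiny_vicsek_cfg(), seed = 9)
  m$params$enc_W1[] <- NaN                     # poisoned weights
  tc <- train_config(epochs = 1, seed = 10, batch_size = 6L)
  expect_error(train_agentnet(m, ds, tc), "diverged|non-finite")
})

test_that("training grows neighbor attention while suppressing non-neighbors", {
  ca <- trained_ca()
  log <- ca$model$log
  expect_gt(tail(log$att_neighbor, 1), log$att_neighbor[1])
  expect_lt(tail(log$att_outside, 1), 0.05)
  expect_lt(tail(log$att_outside, 1), tail(log$att_neighbor, 1) / 10)
})

test_that("attention discriminates true flocking neighbors almost perfectly", {
  vm <- trained_vicsek()
  expect_gt(vm$auc, 0.95)
})
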