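# Dynamic-node machinery: hidden-state registry, masked sequence forward,
# and the synthetic occlusion generator.

test_that("entering agents get MLP-initialized hidden chains of the right size", {
  m <- an_model(tiny_aoup_cfg(), seed = 1)
  reg <- hidden_registry()
  init_hidden(m, reg, "a", c(0.1, 0.2, 0.3, 0.4))
  expect_length(reg$hidden[["a"]], m$config$lstm_dims)
  expect_length(reg$cell[["a"]], m$config$lstm_dims)
  # identical entry states give identical initial hiddens (shared MLPs)
  init_hidden(m, reg, "b", c(0.1, 0.2, 0.3, 0.4))
  expect_equal(reg$hidden[["a"]], reg$hidden[["b"]])
  # re-initializing a live chain is refused
  expect_error(init_hidden(m, reg, "a", c(0, 0, 0, 0)), "already")
})

test_that("gradients flow into the init MLPs during training", {
  cfg <- tiny_aoup_cfg()
  m <- an_model(cfg, seed = 2)
  set.seed(3)
  st <- array(rnorm(1 * 3 * 4 * 4), c(1, 3, 4, 4))
  loss_fn <- function(params) {
    res <- agentnet:::an_forward_sequence(m, st, obs_steps = 3, n_predict = 1,
                                          globals = matrix(2, 1),
                                          feedback = "teacher", params = params)
    tgt <- matrix(aperm(st[, , 4, , drop = FALSE] - st[, , 3, , drop = FALSE],
                        c(2, 1, 3, 4)), ncol = 4)
    per <- agentnet:::ad_nll_terms(res$mu[[1]], res$s2[[1]], tgt)
    agentnet:::ad_sum(per)
  }
  agentnet:::ad_begin()
  leaves <- lapply(m$params, agentnet:::ad_leaf)
  g <- agentnet:::ad_grad(loss_fn(leaves), leaves)
  agentnet:::ad_end()
  names(g) <- names(m$params)
  expect_gt(max(abs(g$inith_W1)), 0)
  expect_gt(max(abs(g$initc_W1)), 0)
})

test_that("an all-present mask reproduces the plain recurrent forward exactly", {
  m <- an_model(tiny_aoup_cfg(), seed = 4)
  set.seed(5)
  st <- array(rnorm(2 * 4 * 5 * 4), c(2, 4, 5, 4))
  gl <- matrix(c(2, 3), 2, 1)
  plain <- agentnet:::an_forward_sequence(m, st, obs_steps = 3, n_predict = 2,
                                          globals = gl, feedback = "teacher")
  mask <- array(TRUE, c(2, 4, 5))
  masked <- agentnet:::an_forward_sequence(m, st, obs_steps = 3, n_predict = 2,
                                           globals = gl, mask = mask,
                                           feedback = "teacher")
  for (k in seq_along(plain$steps)) {
    expect_equal(agentnet:::ad_val(masked$mu[[k]]),
                 agentnet:::ad_val(plain$mu[[k]]), tolerance = 1e-14)
    expect_equal(agentnet:::ad_val(masked$s2[[k]]),
                 agentnet:::ad_val(plain$s2[[k]]), tolerance = 1e-14)
  }
})

test_that("absent agents are excluded from attention and predictions", {
  m <- an_model(tiny_aoup_cfg(), seed = 6)
  set.seed(7)
  st <- array(rnorm(1 * 4 * 4 * 4), c(1, 4, 4, 4))
  mask <- array(TRUE, c(1, 4, 4))
  mask[1, 3, 3:4] <- FALSE                      # agent 3 disappears at step 3
  res <- agentnet:::an_forward_sequence(m, st, obs_steps = 3, n_predict = 1,
                                        globals = matrix(2, 1), mask = mask,
                                        feedback = "teacher",
                                        collect_attention = TRUE)
  att <- res$attention[[1]]
  expect_true(all(is.na(att[3, , ])))           # contributes to no alpha
  expect_true(all(is.na(att[, 3, ])))
  expect_false(3 %in% res$rows[[1]])            # and receives no prediction

  # predictions for the agents that remain are unchanged by adding an
  # always-absent agent to the roster
  st5 <- array(0, c(1, 5, 4, 4)); st5[, 1:4, , ] <- st
  mask5 <- array(FALSE, c(1, 5, 4)); mask5[, 1:4, ] <- mask
  res5 <- agentnet:::an_forward_sequence(m, st5, obs_steps = 3, n_predict = 1,
                                         globals = matrix(2, 1), mask = mask5,
                                         feedback = "teacher")
  expect_equal(agentnet:::ad_val(res5$mu[[1]]),
               agentnet:::ad_val(res$mu[[1]]), tolerance = 1e-14)
})

test_that("an agent entering mid-sequence starts a fresh hidden chain", {
  m <- an_model(tiny_aoup_cfg(), seed = 8)
  reg <- hidden_registry()
  frame1 <- matrix(rnorm(2 * 4), 2, 4)
  out1 <- step_registry(m, reg, frame1, ids = c("a", "b"),
                        present = c(TRUE, FALSE), step = 1L)
  expect_equal(nrow(out1$hidden), 1)
  expect_null(reg$hidden[["b"]])               # never seen, no entry
  frame2 <- matrix(rnorm(2 * 4), 2, 4)
  out2 <- step_registry(m, reg, frame2, ids = c("a", "b"),
                        present = c(TRUE, TRUE), step = 2L)
  expect_equal(nrow(out2$hidden), 2)
  expect_equal(reg$last_seen[["b"]], 2L)
  # the newcomer's chain is one LSTM step old; the veteran's is two
  expect_false(isTRUE(all.equal(reg$hidden[["a"]], reg$hidden[["b"]])))
  # present agents may not carry broken states
  frame3 <- frame2; frame3[1, 2] <- NA
  expect_error(step_registry(m, reg, frame3, ids = c("a", "b"),
                             present = c(TRUE, TRUE), step = 3L),
               "non-finite")
})

test_that("synthetic occlusion masks behave like the configured distribution", {
  expect_true(all(synth_occlusion(2, 5, 10, occlusion_rate = 0)))
  m1 <- synth_occlusion(3, 40, 60, median_length = 12, seed = 1)
  m2 <- synth_occlusion(3, 40, 60, median_length = 12, seed = 1)
  expect_identical(m1, m2)
  # visible intervals are contiguous
  runs_ok <- apply(m1, c(1, 2), function(v) {
    r <- rle(v)$values
    sum(r) <= 1
  })
  expect_true(all(runs_ok))
  # empirical median length near the target
  lens <- apply(synth_occlusion(40, 50, 400, median_length = 25, seed = 2),
                c(1, 2), sum)
  expect_gt(stats::median(lens), 25 * 0.7)
  expect_lt(stats::median(lens), 25 * 1.4)
})
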