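# Reverse-mode engine: analytic gradients against finite differences, and
# the equivalence of the optimized forward paths.

test_that("gradients of the static stochastic network match finite differences", {
  cfg <- tiny_vicsek_cfg()
  m <- an_model(cfg, seed = 2)
  set.seed(1)
  n <- 5; B <- 2
  X <- matrix(rnorm(B * n * 4), B * n, 4)
  Y <- matrix(rnorm(B * n * 2), B * n, 2)
  loss_fn <- function(params) {
    res <- agentnet:::an_forward_core(params, cfg, X, n, B)
    mu <- do.call(agentnet:::ad_cbind, res$mu)
    s2 <- do.call(agentnet:::ad_cbind, res$s2)
    per <- agentnet:::ad_nll_terms(mu, s2, Y)
    agentnet:::ad_scale(agentnet:::ad_sum(per), 1 / nrow(Y))
  }
  expect_lt(fd_grad_check(m$params, loss_fn), 1e-4)
})

test_that("gradients of the binary-output network (deduped path) match finite differences", {
  cfg <- tiny_ca_cfg()
  m <- an_model(cfg, seed = 3)
  g1 <- ca_grid(5, 5, seed = 4); g2 <- ca_grid(5, 5, seed = 5)
  X <- rbind(cbind(g1$coords$x, g1$coords$y, ca_state(g1)),
             cbind(g2$coords$x, g2$coords$y, ca_state(g2)))
  Y <- matrix(c(ca_state(ca_step(g1)), ca_state(ca_step(g2))), ncol = 1)
  loss_fn <- function(params) {
    res <- agentnet:::an_forward_core(params, cfg, X, 25, 2, dedupe = TRUE)
    agentnet:::ad_bce_logits(res$logits[[1]], Y)
  }
  expect_lt(fd_grad_check(m$params, loss_fn), 1e-4)
})

test_that("gradients of the recurrent network match finite differences", {
  cfg <- tiny_aoup_cfg()
  m <- an_model(cfg, seed = 6)
  set.seed(2)
  S <- 2; n <- 4; Tn <- 5
  st <- array(rnorm(S * n * Tn * 4), c(S, n, Tn, 4))
  gl <- matrix(c(2.5, 3), 2, 1)
  loss_fn <- function(params) {
    res <- agentnet:::an_forward_sequence(m, st, obs_steps = 3, n_predict = 2,
                                          globals = gl, feedback = "teacher",
                                          params = params)
    tot <- NULL
    for (kk in seq_along(res$steps)) {
      t1 <- res$steps[kk]
      tgt <- matrix(aperm(st[, , t1, , drop = FALSE] -
                            st[, , t1 - 1, , drop = FALSE], c(2, 1, 3, 4)),
                    ncol = 4)
      per <- agentnet:::ad_nll_terms(res$mu[[kk]], res$s2[[kk]], tgt)
      l <- agentnet:::ad_scale(agentnet:::ad_sum(per), 1 / nrow(tgt))
      tot <- if (is.null(tot)) l else agentnet:::ad_add(tot, l)
    }
    agentnet:::ad_scale(tot, 1 / length(res$steps))
  }
  expect_lt(fd_grad_check(m$params, loss_fn, probes = 1L), 5e-4)
})

test_that("deduplicated and dense forward paths equal the naive computation", {
  cfg <- tiny_ca_cfg()
  m <- an_model(cfg, seed = 7)
  g <- ca_grid(6, 6, seed = 8)
  X <- cbind(g$coords$x, g$coords$y, ca_state(g))
  r_plain <- agentnet:::an_forward_core(m$params, cfg, X, 36, 1,
                                        dedupe = FALSE,
                                        collect_attention = TRUE)
  r_dedup <- agentnet:::an_forward_core(m$params, cfg, X, 36, 1,
                                        dedupe = TRUE,
                                        collect_attention = TRUE)
  expect_equal(agentnet:::ad_val(r_plain$logits[[1]]),
               agentnet:::ad_val(r_dedup$logits[[1]]), tolerance = 1e-12)
  expect_equal(r_plain$alpha, r_dedup$alpha, tolerance = 1e-12)

  # the gather/rowsum aggregation (used with target subsets) agrees with the
  # dense per-frame matmul aggregation (used with full targets)
  cfgv <- tiny_vicsek_cfg()
  mv <- an_model(cfgv, seed = 9)
  set.seed(10)
  Xv <- matrix(rnorm(6 * 4), 6, 4)
  full <- agentnet:::an_forward_core(mv$params, cfgv, Xv, 6, 1)   # dense path
  sub <- agentnet:::an_forward_core(mv$params, cfgv, Xv, 6, 1,
                                    targets = matrix(1:5, 1))     # gather path
  expect_equal(agentnet:::ad_val(full$mu[[1]])[1:5, , drop = FALSE],
               agentnet:::ad_val(sub$mu[[1]]), tolerance = 1e-12)
})

test_that("fused activation kernels agree with their reference formulas", {
  x <- matrix(seq(-30, 30, length.out = 101), ncol = 1)
  f <- agentnet:::.mish_fused(x)
  expect_equal(f$y, x * tanh(log1p(exp(pmin(x, 30)))), tolerance = 1e-10)
  expect_equal(agentnet:::.sigmoid_fused(x), matrix(plogis(x), ncol = 1),
               tolerance = 1e-12)
})
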