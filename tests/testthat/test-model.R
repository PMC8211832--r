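# The variable-wise attention network: architecture contracts and the
# properties that define it.

test_that("mish has its defining values", {
  expect_equal(mish(0), 0)
  x <- c(-3, -0.5, 0.2, 4)
  expect_equal(mish(x), x * tanh(log(1 + exp(x))))
})

test_that("encoding is state-determined and produces key/query/value slices", {
  m <- an_model(tiny_vicsek_cfg(), seed = 1)
  st <- rbind(c(0, 0, 1, 0), c(2, 1, 0, 1), c(0, 0, 1, 0))  # rows 1 and 3 equal
  kqv <- an_encode(m, st)
  expect_equal(dim(kqv$key), c(3, 4))
  expect_equal(kqv$key[1, ], kqv$key[3, ])
  expect_equal(kqv$value[1, ], kqv$value[3, ])
  expect_false(isTRUE(all.equal(kqv$key[1, ], kqv$key[2, ])))
  expect_error(an_encode(m, st[, 1:3]), "state variables")
})

test_that("attention weights are sigmoid, unnormalized, and in (0, 1)", {
  expect_equal(an_attention_weight(0), 0.5)
  expect_gt(an_attention_weight(20), 1 - 1e-8)
  expect_lt(an_attention_weight(-20), 1e-8)

  m <- an_model(tiny_vicsek_cfg(), seed = 2)
  st <- matrix(rnorm(6 * 4), 6, 4)
  f <- an_forward(m, st)
  a <- f$attention
  expect_equal(dim(a), c(6, 6, 2))
  expect_true(all(is.na(a[cbind(1:6, 1:6, 1)])))      # self excluded
  off <- a[!is.na(a)]
  expect_true(all(off > 0 & off < 1))
  # per-target sums are unconstrained (no softmax); just confirm they are
  # not forced to one
  sums <- apply(a[, , 1], 1, sum, na.rm = TRUE)
  expect_false(isTRUE(all.equal(sums, rep(1, 6))))
})

test_that("attention coefficients are asymmetric and permutation-consistent", {
  m <- an_model(tiny_vicsek_cfg(), seed = 3)
  st <- matrix(rnorm(5 * 4), 5, 4)
  kqv <- an_encode(m, st)
  a12 <- an_attention_coefficient(m, kqv$key[1, ], kqv$query[2, ])
  a21 <- an_attention_coefficient(m, kqv$key[2, ], kqv$query[1, ])
  expect_length(a12, 2)
  expect_false(isTRUE(all.equal(a12, a21)))
  # the frame-level forward agrees with the pairwise computation
  f <- an_forward(m, st)
  expect_equal(f$attention[1, 2, ], plogis(a12), tolerance = 1e-12)
})

test_that("aggregation averages attention-weighted values over sources", {
  v <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2, byrow = TRUE)
  expect_equal(an_aggregate(v, c(0, 0, 0)), c(0, 0))
  expect_equal(an_aggregate(v, c(1, 0, 0)), v[1, ] / 3)
  # duplicating a source changes the context only through the denominator
  v2 <- rbind(v, v[3, ])
  a2 <- c(0.5, 0.5, 0.5, 0.5)
  base <- an_aggregate(v, c(0.5, 0.5, 0.5))
  expect_equal(an_aggregate(v2, a2), (base * 3 + 0.5 * v[3, ]) / 4)
})

test_that("forward is permutation-equivariant and rejects NaN input", {
  m <- an_model(tiny_vicsek_cfg(), seed = 4)
  st <- matrix(rnorm(7 * 4), 7, 4)
  f1 <- an_forward(m, st)
  perm <- c(3, 1, 7, 5, 2, 6, 4)
  f2 <- an_forward(m, st[perm, ])
  expect_equal(f2$mu, f1$mu[perm, ], tolerance = 1e-12)
  expect_equal(f2$s2, f1$s2[perm, ], tolerance = 1e-12)
  expect_equal(f2$attention, f1$attention[perm, perm, ], tolerance = 1e-12)
  st[2, 3] <- NaN
  expect_error(an_forward(m, st), "finite")
})

test_that("identical agents receive identical predictive distributions", {
  m <- an_model(tiny_vicsek_cfg(), seed = 5)
  st <- matrix(rnorm(4 * 4), 4, 4)
  st[3, ] <- st[1, ]
  f <- an_forward(m, st)
  expect_equal(f$mu[1, ], f$mu[3, ], tolerance = 1e-12)
  expect_equal(f$s2[1, ], f$s2[3, ], tolerance = 1e-12)
})

test_that("variance heads are strictly positive", {
  m <- an_model(tiny_vicsek_cfg(), seed = 6)
  st <- matrix(rnorm(5 * 4) * 10, 5, 4)
  f <- an_forward(m, st)
  expect_true(all(f$s2 > 0))
  expect_equal(ncol(f$mu), 2)                 # two means + two variances
  expect_equal(ncol(f$s2), 2)
})

test_that("each attention channel feeds only its own output variable", {
  # pushing one variable's attention MLP output bias to -inf zeroes that
  # channel's alpha; only that variable's prediction may change
  m <- an_model(tiny_vicsek_cfg(), seed = 7)
  st <- matrix(rnorm(6 * 4), 6, 4)
  base <- an_forward(m, st)
  m2 <- m
  nb <- length(m2$params$att1_b2)              # final attention layer bias
  m2$params$att1_b2[nb] <- -1e4
  f2 <- an_forward(m2, st)
  expect_true(all(f2$attention[, , 1] < 1e-8, na.rm = TRUE))
  expect_false(isTRUE(all.equal(f2$mu[, 1], base$mu[, 1])))
  expect_equal(f2$mu[, 2], base$mu[, 2], tolerance = 1e-12)   # untouched channel
  expect_equal(f2$s2[, 2], base$s2[, 2], tolerance = 1e-12)
})

test_that("with all attention suppressed, predictions use the self pathway only", {
  m <- an_model(tiny_vicsek_cfg(), seed = 8)
  for (q in 1:2) {
    bnm <- paste0("att", q, "_b2")
    m$params[[bnm]][length(m$params[[bnm]])] <- -1e4
  }
  st <- matrix(rnorm(5 * 4), 5, 4)
  f1 <- an_forward(m, st)
  st2 <- st
  st2[2:5, ] <- st2[2:5, ] + rnorm(16)         # perturb everyone but agent 1
  f2 <- an_forward(m, st2)
  expect_equal(f1$mu[1, ], f2$mu[1, ], tolerance = 1e-9)
})

test_that("single-agent frames predict from the self pathway with zero context", {
  m <- an_model(tiny_vicsek_cfg(), seed = 9)
  st <- matrix(rnorm(4), 1, 4)
  f <- an_forward(m, st)
  expect_equal(dim(f$mu), c(1, 2))
  expect_true(all(is.finite(f$mu)))
})

test_that("the particle preset appends the global variable to attention input", {
  cfg <- model_config("aoup")
  expect_equal(cfg$att_layers[1], 2 * cfg$attention_dims + 1)
  expect_error(model_config("aoup", att_layers = c(32L, 16L, 8L, 1L)),
               "attention MLP input width")
})

test_that("the architecture presets match the reference dimensions", {
  ca <- model_config("ca")
  expect_equal(c(ca$input_dims, ca$n_out, ca$attention_dims), c(3, 1, 16))
  expect_equal(ca$att_layers, c(32, 32, 16, 1))
  vm <- model_config("vicsek")
  expect_equal(vm$att_layers, c(32, 64, 32, 1))
  ao <- model_config("aoup")
  expect_equal(ao$att_layers, c(33, 16, 8, 1))
  expect_true(ao$recurrent && ao$stochastic)
  cs <- model_config("swift")
  expect_equal(c(cs$input_dims, cs$n_out, cs$attention_dims), c(7, 6, 96))
  m <- an_model(model_config("ca"), seed = 1)
  expect_equal(dim(m$params$enc_W1), c(3, 256))
  expect_equal(dim(m$params$enc_W2), c(256, 48))
  expect_equal(dim(m$params$dec1_W1), c(32, 128))
})

test_that("the standalone decode and head stages reproduce the forward pass", {
  m <- an_model(tiny_vicsek_cfg(), seed = 10)
  st <- matrix(rnorm(4 * 4), 4, 4)
  f <- an_forward(m, st)
  kqv <- an_encode(m, st)
  # rebuild agent 1's variable-1 prediction by hand
  alpha <- f$attention[1, -1, 1]
  ctx <- an_aggregate(kqv$value[-1, , drop = FALSE], alpha)
  dec <- an_decode(m, kqv$value[1, ], ctx * 3, q = 1L)  # decoder sees the sum
  heads <- an_gaussian_heads(m, dec, q = 1L)
  expect_equal(unname(heads["mu"]), f$mu[1, 1], tolerance = 1e-10)
  expect_equal(unname(heads["s2"]), f$s2[1, 1], tolerance = 1e-10)
  expect_gt(heads["s2"], 0)
  expect_error(an_decode(m, kqv$value[1, ], ctx[1:2]), "width")
})
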