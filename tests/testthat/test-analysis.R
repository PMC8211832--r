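# Analysis estimators on constructed inputs with known answers.

test_that("displacement errors follow their definitions", {
  p <- array(0, c(1, 2, 2))
  t1 <- p
  expect_equal(ade_fde(p, t1), c(ade = 0, fde = 0))
  # constant offset d at every step
  t2 <- p; t2[1, , 1] <- 0.7
  expect_equal(ade_fde(p, t2), c(ade = 0.7, fde = 0.7))
  # per-step errors 0.3 then 0.5
  t3 <- p; t3[1, , 1] <- c(0.3, 0.5)
  expect_equal(ade_fde(p, t3), c(ade = 0.4, fde = 0.5))
  expect_error(ade_fde(p, array(0, c(2, 2, 2))), "matching")
  # per-agent trajectory ends
  p2 <- array(0, c(2, 3, 2))
  t4 <- p2; t4[1, , 1] <- c(1, 1, 9); t4[2, , 1] <- c(2, 2, 2)
  out <- ade_fde(p2, t4, lengths = c(2, 3))
  expect_equal(unname(out["fde"]), mean(c(1, 2)))
})

test_that("displacement errors are invariant under joint rigid motions", {
  set.seed(1)
  p <- array(rnorm(5 * 4 * 2), c(5, 4, 2))
  t1 <- array(rnorm(5 * 4 * 2), c(5, 4, 2))
  base <- ade_fde(p, t1)
  th <- 0.8; Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rot <- function(a) {
    out <- a
    for (s in 1:4) out[, s, ] <- a[, s, ] %*% Rm + rep(c(3, -2), each = 5)
    out
  }
  expect_equal(ade_fde(rot(p), rot(t1)), base, tolerance = 1e-12)
})

test_that("linear extrapolation continues the last observed velocity", {
  w <- array(0, c(2, 3, 2))
  w[1, , 1] <- c(0, 1, 2)                      # unit velocity in x
  pred <- linear_extrapolation(w, 4)
  expect_equal(pred[1, , 1], 3:6)
  expect_equal(pred[2, , 1], rep(0, 4))        # stationary stays put
  expect_error(linear_extrapolation(array(0, c(2, 1, 2)), 3), "two observed")
  # constant-velocity truth gives exactly zero error
  truth <- array(0, c(1, 4, 2)); truth[1, , 1] <- 3:6
  expect_equal(unname(ade_fde(pred[1, , , drop = FALSE], truth)["ade"]), 0)
  # circular motion: error grows with horizon
  th <- seq(0, 2 * pi, length.out = 40)
  circ <- array(0, c(1, 40, 2))
  circ[1, , 1] <- cos(th); circ[1, , 2] <- sin(th)
  pr <- linear_extrapolation(circ[, 1:5, , drop = FALSE], 30)
  err <- sqrt((pr[1, , 1] - circ[1, 6:35, 1])^2 + (pr[1, , 2] - circ[1, 6:35, 2])^2)
  expect_gt(err[30], err[5])
})

test_that("attention-force fits recover constructed relationships", {
  set.seed(2)
  force <- runif(200, 0, 1)
  fit <- attention_force_fit(0.28 * force, force)
  expect_equal(fit$slope, 0.28, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  noise_fit <- attention_force_fit(runif(200), force)
  expect_lt(noise_fit$r_squared, 0.1)
})

test_that("lattice spacing is recovered from constructed patterns", {
  # perfect triangular lattice with spacing a
  a <- 1.3
  tri <- as.matrix(expand.grid(i = 0:7, j = 0:7))
  lat <- cbind(tri[, 1] * a + tri[, 2] * a / 2, tri[, 2] * a * sqrt(3) / 2)
  est <- hexagonal_periodicity(lat, R = 1)
  expect_true(est$confident)
  expect_lt(abs(est$spacing - a), 1 / 20 + 1e-9)    # within one bin width

  # jittered lattice still within 5%
  set.seed(3)
  jit <- lat + matrix(rnorm(nrow(lat) * 2, sd = 0.05 * a), ncol = 2)
  est2 <- hexagonal_periodicity(jit, R = 1)
  expect_lt(abs(est2$spacing - a) / a, 0.05)

  # scale equivariance (binning scaled alongside)
  lam <- 2.5
  est3 <- hexagonal_periodicity(lat * lam, R = lam)
  expect_equal(est3$spacing / lam, est$spacing, tolerance = 1e-9)

  # a uniform random gas has no structured peak
  gas <- matrix(runif(400, 0, 20), ncol = 2)
  expect_false(hexagonal_periodicity(gas, R = 1)$confident)
})

test_that("sector recovery reads off constructed attention maps", {
  set.seed(4)
  n <- 20000
  rel_x <- runif(n, -2.5, 2.5); rel_y <- runif(n, -2.5, 2.5)
  r <- sqrt(rel_x^2 + rel_y^2); ang <- atan2(rel_y, rel_x)
  inside <- r < 1 & abs(ang) < 60 * pi / 180
  map <- data.frame(rel_x = rel_x, rel_y = rel_y,
                    alpha = ifelse(inside, 1, 0))
  rec <- sector_recovery(map)
  expect_false(rec$flagged)
  expect_equal(rec$radius, 1, tolerance = 0.08)
  expect_equal(rec$angular_width, 120, tolerance = 0.08 * 120)

  # full-disc attention covers (almost) the whole circle
  disc <- data.frame(rel_x = rel_x, rel_y = rel_y,
                     alpha = ifelse(r < 2, 1, 0))
  rec2 <- sector_recovery(disc)
  expect_gt(rec2$angular_width, 320)

  # an all-zero map is flagged
  rec3 <- sector_recovery(data.frame(rel_x = 1, rel_y = 0, alpha = 0))
  expect_true(rec3$flagged)
})

test_that("velocity-correlation maps hit their analytic limits", {
  # everyone shares one velocity: cosine similarity 1 everywhere
  S <- 4; n <- 12
  st <- array(0, c(S, n, 4))
  set.seed(5)
  st[, , 1] <- runif(S * n, -2, 2); st[, , 2] <- runif(S * n, -2, 2)
  st[, , 3] <- 1; st[, , 4] <- 0.5
  vc <- velocity_correlation_map(st, bin_width = 1, extent = 3)
  expect_equal(range(vc$cos_sim[!is.na(vc$cos_sim)]), c(1, 1), tolerance = 1e-12)

  # independent random velocities average near zero
  st[, , 3] <- rnorm(S * n); st[, , 4] <- rnorm(S * n)
  st2 <- array(0, c(40, n, 4))
  st2[, , 1] <- runif(40 * n, -2, 2); st2[, , 2] <- runif(40 * n, -2, 2)
  st2[, , 3] <- rnorm(40 * n); st2[, , 4] <- rnorm(40 * n)
  vc2 <- velocity_correlation_map(st2, bin_width = 2, extent = 4)
  expect_lt(max(abs(vc2$cos_sim), na.rm = TRUE), 0.35)
})

test_that("attention maps align sources to the target heading", {
  m <- an_model(tiny_vicsek_cfg(), seed = 6)
  # two agents: target at origin heading +y, source straight ahead of it
  st <- array(0, c(1, 2, 4))
  st[1, 1, ] <- c(0, 0, 0, 1)                   # heading +y
  st[1, 2, ] <- c(0, 0.5, 1, 0)
  map <- attention_map(m, st)
  row1 <- map[1, ]                              # source seen from the target
  expect_equal(row1$rel_x, 0.5, tolerance = 1e-12)  # ahead = +x after alignment
  expect_equal(row1$rel_y, 0, tolerance = 1e-12)
  expect_true(all(map$alpha > 0 & map$alpha < 1))

  # binning a constant field returns that constant in every occupied bin
  cmap <- data.frame(rel_x = runif(500, -1, 1), rel_y = runif(500, -1, 1),
                     alpha = 0.42)
  hm <- attention_heatmap(cmap, bin_width = 0.5, extent = 1)
  vals <- hm$grid$alpha[!is.na(hm$grid$alpha)]
  expect_equal(range(vals), c(0.42, 0.42))
})
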