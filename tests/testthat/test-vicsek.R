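# Vision-cone Vicsek simulator.

# Hand-built state: explicit positions/velocities.
manual_state <- function(x, y, vx, vy, ...) {
  st <- vicsek_state(length(x), ...)
  st$x <- x; st$y <- y; st$vx <- vx; st$vy <- vy
  st
}

test_that("vision-cone membership follows distance and bearing", {
  # agent 1 heads +x; 2 ahead, 3 behind, 4 ahead but out of range
  st <- manual_state(x = c(0, 0.5, -0.5, 1.5), y = rep(0, 4),
                     vx = c(1, 0, 0, 0), vy = c(0, 1, 1, 1))
  nb <- vicsek_neighbors(st, 1)
  expect_true(2 %in% nb)
  expect_false(3 %in% nb)
  expect_false(4 %in% nb)

  # under the full-cone convention (120 deg total) a source at 70 deg bearing
  # is invisible; under the half-angle convention (120 deg each side) it is
  # visible
  ang <- 70 * pi / 180
  st2 <- manual_state(x = c(0, 0.5 * cos(ang)), y = c(0, 0.5 * sin(ang)),
                      vx = c(1, 0), vy = c(0, 1))
  expect_false(2 %in% vicsek_neighbors(st2, 1))
  st3 <- st2
  attr(st3, "angle_convention") <- "half"
  expect_true(2 %in% vicsek_neighbors(st3, 1))

  # zero-speed agents have no heading and see nobody
  st4 <- manual_state(x = c(0, 0.5), y = c(0, 0), vx = c(0, 1), vy = c(0, 0))
  expect_length(vicsek_neighbors(st4, 1), 0)
})

test_that("the update averages self and neighbors, then moves", {
  # isolated agent with zero noise keeps its velocity
  st <- manual_state(x = c(0, 10), y = c(0, 10), vx = c(0.4, 0.2),
                     vy = c(0, 0), sigma = 0)
  nxt <- vicsek_step(st)
  expect_equal(nxt$vx, c(0.4, 0.2))
  expect_equal(nxt$x, c(0.4, 10.2))

  # two mutually visible agents with v = (1,0) and (0,1) both end at (.5,.5):
  # agent 2 sits 45 deg below agent 1's heading (+x) and agent 1 sits 45 deg
  # left of agent 2's heading (+y), both inside the 120 deg cone
  st2 <- manual_state(x = c(0, 0.3 * cos(-pi / 4)),
                      y = c(0, 0.3 * sin(-pi / 4)), vx = c(1, 0),
                      vy = c(0, 1), sigma = 0)
  nxt2 <- vicsek_step(st2)
  expect_equal(nxt2$vx, c(0.5, 0.5))
  expect_equal(nxt2$vy, c(0.5, 0.5))
})

test_that("noise draws are reproducible under a fixed seed", {
  st <- vicsek_state(20, seed = 7)
  a <- vicsek_step(st, seed = 3)
  b <- vicsek_step(st, seed = 3)
  expect_identical(a, b)
  c2 <- vicsek_step(st, seed = 4)
  expect_false(identical(a$x, c2$x))
})

test_that("noiseless updates are convex combinations of frame velocities", {
  set.seed(11)
  for (rep in 1:20) {
    st <- vicsek_state(30, sigma = 0)
    nxt <- vicsek_step(st)
    expect_true(all(nxt$vx >= min(st$vx) - 1e-12 & nxt$vx <= max(st$vx) + 1e-12))
    expect_true(all(nxt$vy >= min(st$vy) - 1e-12 & nxt$vy <= max(st$vy) + 1e-12))
  }
})

test_that("initial states fill the configured disc", {
  st <- vicsek_state(500, region_radius = sqrt(5), seed = 5)
  expect_true(all(st$x^2 + st$y^2 <= 5 + 1e-12))
  spd <- sqrt(st$vx^2 + st$vy^2)
  expect_true(all(spd >= 0.2 - 1e-12 & spd <= 1 + 1e-12))
})
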