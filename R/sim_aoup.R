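# Active Ornstein-Uhlenbeck particles (AOUP) with soft-core repulsion.
#
# Overdamped Langevin dynamics for particle positions x_i:
#
#   gamma dx_i/dt = F_ext(x_i) + F_int_i + sqrt(2 gamma T) eta_i + gamma f_i
#
# with harmonic confinement F_ext = -k x, pairwise soft-core repulsion
# F_int_i = -grad_i sum_j V(r_ij), V(r) = exp(-r^3 / R^3), and a hidden
# propulsion force f_i following an Ornstein-Uhlenbeck process
#
#   tau df_i/dt = -f_i + sqrt(2 D_a) w_i .
#
# Both equations are integrated by Euler-Maruyama with step `dt`.  The
# stationary propulsion obeys E|f|^2 = 2 D_a / tau (the squared propulsion
# speed U0^2).  The exported per-step "velocity" is the displacement over one
# step, v^{t+1} = x^{t+1} - x^t; the propulsion f is a hidden variable and is
# never exported to training data.

#' Create an AOUP particle state
#'
#' Particles start uniformly in a disc of radius `init_radius`; propulsions
#' start from their stationary distribution.
#'
#' @param n Number of particles.
#' @param R Soft-core interaction length (the system's global variable).
#' @param gamma Drag coefficient.
#' @param Temp Temperature of the thermal bath.
#' @param tau Propulsion correlation time.
#' @param D_a Active diffusion constant; the mean squared propulsion speed is
#'   `U0^2 = 2 * D_a / tau`.
#' @param k Harmonic confinement spring constant.
#' @param dt Integration time step.
#' @param init_radius Radius of the initial disc.
#' @param seed Optional RNG seed.
#' @return Object of class `aoup_state`: list with numeric vectors `x`, `y`,
#'   `vx`, `vy` (last step's displacement), hidden propulsion `fx`, `fy`, and
#'   the parameter list `params`.
#' @export
#' @examples
#' st <- aoup_state(10, R = 2, seed = 1)
#' st <- aoup_step(st)
aoup_state <- function(n, R = 2, gamma = 1, Temp = 1, tau = 1, D_a = 1,
                       k = 0.1, dt = 0.05, init_radius = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ang <- runif(n, 0, 2 * pi)
  rad <- init_radius * sqrt(runif(n))
  structure(list(
    x = rad * cos(ang), y = rad * sin(ang),
    vx = numeric(n), vy = numeric(n),
    fx = rnorm(n, 0, sqrt(D_a / tau)), fy = rnorm(n, 0, sqrt(D_a / tau)),
    params = list(R = R, gamma = gamma, Temp = Temp, tau = tau, D_a = D_a,
                  k = k, dt = dt)
  ), class = "aoup_state")
}

#' Soft-core pair force
#'
#' Force exerted on particle `i` by particle `j` under the repulsive
#' soft-core potential `V(r) = exp(-r^3 / R^3)`: the analytic negative
#' gradient `-grad_i V`, pointing from `j` toward `i` with magnitude
#' `3 r^2 exp(-r^3/R^3) / R^3`.  The magnitude vanishes as `r -> 0`, so
#' coincident particles feel zero force (the analytic limit).
#'
#' @param pos_i,pos_j Length-2 numeric positions.
#' @param R Interaction length.
#' @return Length-2 force vector on `i`.
#' @export
#' @examples
#' aoup_pair_force(c(0, 0), c(1, 0), R = 2)
aoup_pair_force <- function(pos_i, pos_j, R) {
  d <- pos_i - pos_j
  r <- sqrt(sum(d * d))
  if (r == 0) return(c(0, 0))
  mag <- 3 * r^2 * exp(-r^3 / R^3) / R^3
  mag * d / r
}

# Vectorized pairwise forces: returns list(Fx, Fy) of net force per particle,
# plus the n x n magnitude matrix when `magnitudes = TRUE`.
aoup_net_forces <- function(x, y, R, magnitudes = FALSE) {
  dx <- outer(x, x, "-")            # [i, j] = x_i - x_j
  dy <- outer(y, y, "-")
  r2 <- dx * dx + dy * dy
  diag(r2) <- Inf
  r <- sqrt(r2)
  fac <- 3 * r * exp(-(r2 * r) / R^3) / R^3   # magnitude / r
  diag(fac) <- 0
  out <- list(Fx = rowSums(fac * dx), Fy = rowSums(fac * dy))
  if (magnitudes) out$mag <- fac * r
  out
}

#' One Euler-Maruyama update of the propulsion process
#'
#' `f <- f - (dt/tau) f + (sqrt(2 D_a)/tau) sqrt(dt) N(0, 1)` per component.
#'
#' @param f Numeric vector or matrix of propulsion components.
#' @param tau Correlation time.
#' @param D_a Active diffusion constant.
#' @param dt Time step (should be well below `tau`).
#' @param seed Optional RNG seed.
#' @return Updated propulsion of the same shape.
#' @export
ou_propulsion_step <- function(f, tau, D_a, dt, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  f - (dt / tau) * f + sqrt(2 * D_a) / tau * sqrt(dt) * rnorm(length(f))
}

#' Advance an AOUP state one step
#'
#' Updates the hidden propulsion, then computes the step displacement from
#' summed pair forces, the harmonic trap, thermal noise, and propulsion, and
#' finally moves the particles.
#'
#' @param state An [aoup_state()].
#' @param seed Optional RNG seed.
#' @return The next-step `aoup_state`.
#' @export
aoup_step <- function(state, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- state$params
  n <- length(state$x)
  f <- aoup_net_forces(state$x, state$y, p$R)
  state$fx <- ou_propulsion_step(state$fx, p$tau, p$D_a, p$dt)
  state$fy <- ou_propulsion_step(state$fy, p$tau, p$D_a, p$dt)
  sd_th <- sqrt(2 * p$Temp / p$gamma) * sqrt(p$dt)
  state$vx <- (f$Fx - p$k * state$x) / p$gamma * p$dt +
    sd_th * rnorm(n) + state$fx * p$dt
  state$vy <- (f$Fy - p$k * state$y) / p$gamma * p$dt +
    sd_th * rnorm(n) + state$fy * p$dt
  state$x <- state$x + state$vx
  state$y <- state$y + state$vy
  state
}

#' Run an AOUP simulation
#'
#' @param state An [aoup_state()].
#' @param steps Number of integration steps.
#' @param snapshot_every Keep a position snapshot every this many steps
#'   (0 = none).
#' @param snapshot_after Fraction of the run to discard before snapshotting.
#' @param seed Optional RNG seed.
#' @return List with the final `state` and `snapshots`, a list of n x 2
#'   position matrices.
#' @export
aoup_simulate <- function(state, steps, snapshot_every = 0L,
                          snapshot_after = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  snaps <- list()
  burn <- floor(snapshot_after * steps)
  for (s in seq_len(steps)) {
    state <- aoup_step(state)
    if (snapshot_every > 0L && s > burn && s %% snapshot_every == 0L) {
      snaps[[length(snaps) + 1L]] <- cbind(x = state$x, y = state$y)
    }
  }
  list(state = state, snapshots = snaps)
}
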