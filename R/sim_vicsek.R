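# Vision-cone Vicsek flocking model.
#
# Each agent carries position (x, y) and velocity (vx, vy).  At every step it
# replaces its velocity by the average velocity of itself and all agents it
# can see -- those closer than the interaction radius `r_c` and within its
# vision cone -- plus independent Gaussian noise per component, then moves by
# the new velocity.  The vision cone of total opening `theta_c` (degrees) is
# centered on the agent's heading; the `angle_convention` switch selects
# whether `theta_c` is the full cone ("full", default, membership
# |bearing| < theta_c / 2) or the half-angle ("half", |bearing| < theta_c).

#' Create a Vicsek model state
#'
#' Agents are placed uniformly in a disc of radius `region_radius` centered at
#' the origin, with uniformly random headings and speeds drawn uniformly from
#' `speed_range`.
#'
#' @param n Number of agents.
#' @param r_c Interaction radius (m).
#' @param theta_c Vision angle in degrees (see `angle_convention`).
#' @param sigma Standard deviation of the per-component velocity noise.
#' @param region_radius Radius of the initial disc; defaults to `sqrt(5)`.
#' @param speed_range Range of initial speeds (m/step).
#' @param angle_convention `"full"`: `theta_c` is the total cone opening;
#'   `"half"`: `theta_c` is the half-angle on each side of the heading.
#' @param seed Optional RNG seed.
#' @return Object of class `vicsek_state`: a data frame with columns
#'   `x`, `y`, `vx`, `vy` and the model parameters stored as attributes.
#' @export
#' @examples
#' st <- vicsek_state(20, seed = 1)
#' vicsek_neighbors(st, 1)
vicsek_state <- function(n, r_c = 1, theta_c = 120, sigma = 0.1,
                         region_radius = sqrt(5), speed_range = c(0.2, 1),
                         angle_convention = c("full", "half"), seed = NULL) {
  angle_convention <- match.arg(angle_convention)
  if (!is.null(seed)) set.seed(seed)
  ang <- runif(n, 0, 2 * pi)
  rad <- region_radius * sqrt(runif(n))
  head <- runif(n, 0, 2 * pi)
  spd <- runif(n, speed_range[1], speed_range[2])
  st <- data.frame(x = rad * cos(ang), y = rad * sin(ang),
                   vx = spd * cos(head), vy = spd * sin(head))
  structure(st, class = c("vicsek_state", "data.frame"),
            r_c = r_c, theta_c = theta_c, sigma = sigma,
            angle_convention = angle_convention)
}

vicsek_params <- function(state) {
  list(r_c = attr(state, "r_c"), theta_c = attr(state, "theta_c"),
       sigma = attr(state, "sigma"),
       angle_convention = attr(state, "angle_convention"))
}

# Half-opening of the vision cone in radians under the active convention.
vicsek_half_angle <- function(state) {
  p <- vicsek_params(state)
  th <- p$theta_c * pi / 180
  if (p$angle_convention == "full") th / 2 else th
}

#' Agents visible to agent `i`
#'
#' Membership requires distance strictly below `r_c` and absolute bearing
#' (angle between `i`'s heading and the direction to `j`) strictly inside the
#' vision cone.  An agent with zero speed has no defined heading and sees no
#' one (it still averages with itself in [vicsek_step()]).
#'
#' @param state A [vicsek_state()].
#' @param i Agent index.
#' @return Integer vector of neighbor indices (possibly empty).
#' @export
vicsek_neighbors <- function(state, i) {
  which(vicsek_membership(state)[i, ])
}

# Logical n x n matrix; [i, j] TRUE when j is visible to i.  FALSE diagonal.
vicsek_membership <- function(state) {
  p <- vicsek_params(state)
  half <- vicsek_half_angle(state)
  n <- nrow(state)
  dx <- outer(state$x, state$x, function(a, b) b - a)  # [i, j] = x_j - x_i
  dy <- outer(state$y, state$y, function(a, b) b - a)
  r <- sqrt(dx * dx + dy * dy)
  heading <- atan2(state$vy, state$vx)
  bearing <- abs(((atan2(dy, dx) - heading + pi) %% (2 * pi)) - pi)
  speed <- sqrt(state$vx^2 + state$vy^2)
  m <- r < p$r_c & bearing < half & speed > 0
  diag(m) <- FALSE
  m
}

#' Advance a Vicsek state one step
#'
#' Every agent's new velocity is the mean of its own and its visible
#' neighbors' velocities plus `N(0, sigma)` noise per component; positions
#' then advance by the new velocity.
#'
#' @param state A [vicsek_state()].
#' @param seed Optional RNG seed (noise draws are reproducible given a seed).
#' @return The next-step `vicsek_state`.
#' @export
vicsek_step <- function(state, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- vicsek_params(state)
  m <- vicsek_membership(state)
  n <- nrow(state)
  k <- rowSums(m) + 1                        # self always included
  new_vx <- (state$vx + as.vector(m %*% state$vx)) / k + rnorm(n, 0, p$sigma)
  new_vy <- (state$vy + as.vector(m %*% state$vy)) / k + rnorm(n, 0, p$sigma)
  out <- state
  out$vx <- new_vx
  out$vy <- new_vy
  out$x <- state$x + new_vx
  out$y <- state$y + new_vy
  out
}
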