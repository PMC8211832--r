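# Training-set generation from the ground-truth simulators.
#
# Datasets are lists of dense arrays (sample x agent [x time] x variable)
# together with the ground-truth interaction labels that the simulators
# expose, so that attention recovery can be verified against the truth.

#' Generate a training dataset from a simulator
#'
#' * `ca`: one-step grid transitions; inputs are per-cell `(x, y, c)`,
#'   targets the next-step cell states.
#' * `vicsek`: one-step transitions from freshly randomized states; inputs
#'   `(x, y, vx, vy)`, targets the next-step position change per agent;
#'   ground-truth neighbor membership is attached as labels.
#' * `aoup`: windows of `obs_steps + target_steps` consecutive steps cut from
#'   equilibrated runs whose interaction length `R` is drawn uniformly from
#'   `R_range` per run and exported as the sample's global variable; the
#'   hidden propulsion is never exported.
#'
#' @param system `"ca"`, `"vicsek"` or `"aoup"`.
#' @param config A matching [sim_config()]; defaults for the system if `NULL`.
#' @param n_samples Number of samples (must be positive).
#' @param seed Optional RNG seed; a fixed seed reproduces the dataset exactly.
#' @return Object of class `an_dataset`: list with `system`, `states`,
#'   `targets`, `globals`, `labels`, `config`.  For static systems `states`
#'   is `[sample, agent, variable]`; for `aoup` it is
#'   `[sample, agent, time, variable]` with `obs_steps` observed and
#'   `target_steps` future steps.
#' @export
#' @examples
#' d <- generate_dataset("ca", n_samples = 3, seed = 1)
#' dim(d$states)
generate_dataset <- function(system = c("ca", "vicsek", "aoup"),
                             config = NULL, n_samples, seed = NULL) {
  system <- match.arg(system)
  if (n_samples <= 0) stop("`n_samples` must be positive", call. = FALSE)
  if (is.null(config)) config <- sim_config(system)
  stopifnot(inherits(config, "sim_config"), config$system == system)
  if (!is.null(seed)) set.seed(seed)
  switch(system,
    ca = dataset_ca(config, n_samples),
    vicsek = dataset_vicsek(config, n_samples),
    aoup = dataset_aoup(config, n_samples)
  )
}

an_dataset <- function(system, states, targets, globals, labels, config) {
  structure(list(system = system, states = states, targets = targets,
                 globals = globals, labels = labels, config = config),
            class = "an_dataset")
}

#' @export
print.an_dataset <- function(x, ...) {
  d <- dim(x$states)
  cat(sprintf("<an_dataset %s: %d samples, %d agents%s>\n", x$system, d[1],
              d[2], if (length(d) == 4) sprintf(", %d steps", d[3]) else ""))
  invisible(x)
}

dataset_ca <- function(config, n_samples) {
  n <- config$width * config$height
  states <- array(0, c(n_samples, n, 3))
  targets <- array(0, c(n_samples, n, 1))
  g0 <- ca_grid(config$width, config$height, config$p_alive)
  coords <- cbind(g0$coords$x, g0$coords$y)
  for (s in seq_len(n_samples)) {
    g <- ca_grid(config$width, config$height, config$p_alive)
    states[s, , 1:2] <- coords
    states[s, , 3] <- ca_state(g)
    targets[s, , 1] <- ca_state(ca_step(g))
  }
  an_dataset("ca", states, targets, NULL, ca_interaction_matrix(g0), config)
}

dataset_vicsek <- function(config, n_samples) {
  n <- config$n
  states <- array(0, c(n_samples, n, 4))
  targets <- array(0, c(n_samples, n, 2))
  labels <- array(FALSE, c(n_samples, n, n))
  for (s in seq_len(n_samples)) {
    st <- vicsek_state(n, r_c = config$r_c, theta_c = config$theta_c,
                       sigma = config$sigma,
                       region_radius = config$region_radius,
                       speed_range = config$speed_range,
                       angle_convention = config$angle_convention)
    labels[s, , ] <- vicsek_membership(st)
    nxt <- vicsek_step(st)
    states[s, , ] <- cbind(st$x, st$y, st$vx, st$vy)
    targets[s, , ] <- cbind(nxt$x - st$x, nxt$y - st$y)
  }
  an_dataset("vicsek", states, targets, NULL, labels, config)
}

dataset_aoup <- function(config, n_samples) {
  n <- config$n
  win <- config$obs_steps + config$target_steps
  n_runs <- ceiling(n_samples / config$windows_per_run)
  states <- array(0, c(n_samples, n, win, 4))
  globals <- matrix(0, n_samples, 1)
  s <- 0L
  for (run in seq_len(n_runs)) {
    R <- runif(1, config$R_range[1], config$R_range[2])
    st <- aoup_state(n, R = R, gamma = config$gamma, Temp = config$Temp,
                     tau = config$tau, D_a = config$D_a, k = config$k,
                     dt = config$dt, init_radius = config$init_radius)
    for (b in seq_len(config$burn_steps)) st <- aoup_step(st)
    for (w in seq_len(config$windows_per_run)) {
      if (s >= n_samples) break
      s <- s + 1L
      for (t in seq_len(win)) {
        st <- aoup_step(st)
        states[s, , t, ] <- cbind(st$x, st$y, st$vx, st$vy)
      }
      globals[s, 1] <- R
    }
  }
  an_dataset("aoup", states, NULL, globals, NULL, config)
}

# Per-variable mean/sd over all agents and samples (and steps), used to
# standardize network inputs; sds are floored to avoid division by zero for
# constant variables.
norm_stats <- function(x) {
  d <- dim(x)
  flat <- matrix(aperm(x, c(seq_along(d)[-length(d)], length(d))),
                 ncol = d[length(d)])
  list(mean = colMeans(flat), sd = pmax(apply(flat, 2, stats::sd), 1e-8))
}

#' Flatten a dataset to a tidy trajectory table
#'
#' @param dataset An [generate_dataset()] result.
#' @param mask Optional presence mask (`[sample, agent, time]` logical array,
#'   or `[sample, agent]` for static systems) written to the `present` column.
#' @return A data frame with columns `sample_id`, `t`, `agent_id`, one column
#'   per state variable, and `present`.
#' @export
an_trajectory_table <- function(dataset, mask = NULL) {
  st <- dataset$states
  d <- dim(st)
  var_names <- switch(dataset$system,
    ca = c("x", "y", "c"),
    c("x", "y", "vx", "vy"))
  if (length(d) == 3) {
    S <- d[1]; n <- d[2]
    out <- data.frame(
      sample_id = rep(seq_len(S), each = n),
      t = 0L,
      agent_id = rep(seq_len(n), S)
    )
    flat <- matrix(aperm(st, c(2, 1, 3)), ncol = d[3])
    for (v in seq_len(d[3])) out[[var_names[v]]] <- flat[, v]
    out$present <- if (is.null(mask)) TRUE else as.vector(t(mask))
  } else {
    S <- d[1]; n <- d[2]; Tn <- d[3]
    out <- data.frame(
      sample_id = rep(seq_len(S), each = n * Tn),
      t = rep(rep(seq_len(Tn) - 1L, each = n), S),
      agent_id = rep(seq_len(n), S * Tn)
    )
    flat <- matrix(aperm(st, c(2, 3, 1, 4)), ncol = d[4])
    for (v in seq_len(d[4])) out[[var_names[v]]] <- flat[, v]
    out$present <- if (is.null(mask)) TRUE else as.vector(aperm(mask, c(2, 3, 1)))
  }
  out
}
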