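# Diagnostics connecting trained models and simulator ground truth:
# displacement errors, attention-force calibration, lattice-spacing
# estimation, interaction-sector recovery, and heading-aligned maps.

#' Average and final displacement errors
#'
#' ADE is the mean Euclidean error over all agents and predicted steps; FDE
#' is the mean error at each agent's final step (the last step by default,
#' or per-agent trajectory ends given `lengths`).
#'
#' @param predicted,true `n x T x 2` arrays of positions (extra state columns
#'   beyond the first two are ignored).
#' @param lengths Optional integer vector of per-agent trajectory lengths.
#' @return Named numeric vector `c(ade, fde)`.
#' @export
#' @examples
#' p <- array(0, c(1, 2, 2)); t2 <- p; t2[1, , 1] <- c(0.3, 0.5)
#' ade_fde(p, t2)   # ADE 0.4, FDE 0.5
ade_fde <- function(predicted, true, lengths = NULL) {
  if (!all(dim(predicted)[1:2] == dim(true)[1:2])) {
    stop("predicted and true trajectories must have matching agents and steps")
  }
  n <- dim(predicted)[1]; Tn <- dim(predicted)[2]
  dx <- predicted[, , 1, drop = FALSE] - true[, , 1, drop = FALSE]
  dy <- predicted[, , 2, drop = FALSE] - true[, , 2, drop = FALSE]
  err <- sqrt(dx^2 + dy^2)[, , 1, drop = TRUE]
  err <- matrix(err, n, Tn)
  if (is.null(lengths)) lengths <- rep(Tn, n)
  if (any(lengths < 1 | lengths > Tn)) stop("invalid trajectory lengths")
  ade <- mean(unlist(lapply(seq_len(n), function(i) err[i, seq_len(lengths[i])])))
  fde <- mean(err[cbind(seq_len(n), lengths)])
  c(ade = ade, fde = fde)
}

#' Constant-velocity extrapolation baseline
#'
#' Continues every agent from its last observed velocity (the displacement
#' between the two last observed positions).
#'
#' @param window `n x T x d` array with at least two observed steps;
#'   columns 1:2 are positions.
#' @param n_steps Prediction horizon.
#' @return `n x n_steps x 2` array of predicted positions.
#' @export
linear_extrapolation <- function(window, n_steps) {
  d <- dim(window)
  if (length(d) != 3 || d[2] < 2) stop("need at least two observed steps")
  pos <- window[, d[2], 1:2, drop = FALSE][, 1, ]
  vel <- pos - window[, d[2] - 1L, 1:2, drop = FALSE][, 1, ]
  pos <- matrix(pos, d[1], 2); vel <- matrix(vel, d[1], 2)
  out <- array(0, c(d[1], n_steps, 2))
  for (s in seq_len(n_steps)) out[, s, ] <- pos + s * vel
  out
}

#' Ordinary least-squares fit of attention against force magnitude
#'
#' @param alpha Numeric vector of attention weights per pair.
#' @param force Numeric vector of ground-truth force magnitudes per pair.
#' @return List with `slope`, `intercept`, `r_squared`.
#' @export
#' @examples
#' attention_force_fit(0.28 * (1:10), 1:10)$r_squared   # 1
attention_force_fit <- function(alpha, force) {
  stopifnot(length(alpha) == length(force))
  vf <- stats::var(force)
  if (vf == 0) stop("force values are constant; no slope is identified")
  slope <- stats::cov(alpha, force) / vf
  intercept <- mean(alpha) - slope * mean(force)
  va <- stats::var(alpha)
  r2 <- if (va == 0) 1 else slope^2 * vf / va
  list(slope = slope, intercept = intercept, r_squared = r2)
}

#' Attention vs pair force for a trained particle model
#'
#' Runs the model on particle frames, collects the attention weight of every
#' ordered pair for the chosen output variable, computes the ground-truth
#' soft-core pair-force components, and fits attention against the force
#' magnitude.
#'
#' @param model A trained model for the particle system.
#' @param states `[S, n, T, 4]` array of observed windows (or `[S, n, 4]`
#'   single frames), raw units.
#' @param R Interaction length (vector per sample or scalar).
#' @param var Output-variable index whose attention is analyzed (the
#'   x-velocity component by default).
#' @param component `1` for x, `2` for y force components.
#' @return List with `fit` (see [attention_force_fit()]) and `pairs`, a data
#'   frame of `r`, `force`, `alpha`, `alpha_scaled` per pair.
#' @export
aoup_attention_force <- function(model, states, R, var = 3L, component = 1L) {
  dd <- dim(states)
  if (length(dd) == 3) {
    states <- array(states, c(dd[1], dd[2], 1, dd[3]))
    dd <- dim(states)
  }
  S <- dd[1]; n <- dd[2]; Tn <- dd[3]
  if (length(R) == 1) R <- rep(R, S)
  out_r <- out_f <- out_a <- list()
  for (s in seq_len(S)) {
    if (model$config$recurrent) {
      res <- an_forward_sequence(model, states[s, , , , drop = FALSE],
                                 obs_steps = Tn, n_predict = 1L,
                                 globals = matrix(R[s], 1),
                                 feedback = "teacher",
                                 collect_attention = TRUE)
      att <- res$attention[[1]]
      x <- states[s, , Tn, 1]; y <- states[s, , Tn, 2]
    } else {
      att <- an_forward(model, states[s, , Tn, ], globals = R[s])$attention
      x <- states[s, , Tn, 1]; y <- states[s, , Tn, 2]
    }
    frc <- aoup_net_forces(x, y, R[s], magnitudes = TRUE)
    dxy <- if (component == 1L) outer(x, x, "-") else outer(y, y, "-")
    r2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
    diag(r2) <- Inf
    fcomp <- abs(frc$mag * dxy / sqrt(r2))
    a <- att[, , min(var, dim(att)[3])]
    keep <- !is.na(a)
    out_r[[s]] <- sqrt(r2[keep])
    out_f[[s]] <- fcomp[keep]
    out_a[[s]] <- a[keep]
  }
  r <- unlist(out_r); force <- unlist(out_f); alpha <- unlist(out_a)
  fit <- attention_force_fit(alpha, force)
  scale <- if (abs(fit$slope) > 1e-12) 1 / fit$slope else NA_real_
  list(fit = fit,
       pairs = data.frame(r = r, force = force, alpha = alpha,
                          alpha_scaled = alpha * scale))
}

#' Lattice spacing from the pair-distance distribution
#'
#' Estimates the characteristic spacing of a (near-)hexagonal particle
#' pattern as the location of the first peak of the radial pair-distance
#' distribution (counts divided by the annulus radius), refined by quadratic
#' interpolation around the modal bin.  Distances below `r_min` are ignored
#' so that multiply-occupied cluster sites do not masquerade as the lattice
#' peak.  When no bin rises clearly above the background the result is
#' flagged low-confidence.
#'
#' @param positions `n x 2` matrix or a list of such snapshot matrices
#'   (histograms are pooled across snapshots).
#' @param R Interaction length used for the default binning.
#' @param bin_width,r_max,r_min Histogram parameters (defaults `R/20`, `4R`,
#'   `R/2`).
#' @param min_prominence Peak-to-background ratio below which the result is
#'   flagged.
#' @return List with `spacing`, `confident` (logical), and the `profile`
#'   data frame (`r`, `g`).
#' @export
#' @examples
#' lat <- as.matrix(expand.grid(x = 0:5, y = 0:5))  # square lattice, a = 1
#' hexagonal_periodicity(lat, R = 1)$spacing
hexagonal_periodicity <- function(positions, R, bin_width = R / 20,
                                  r_max = 4 * R, r_min = R / 2,
                                  min_prominence = 1.5) {
  if (!is.list(positions)) positions <- list(positions)
  breaks <- seq(0, r_max, by = bin_width)
  counts <- 0
  for (p in positions) {
    d <- as.vector(stats::dist(p[, 1:2]))
    d <- d[d < r_max]
    counts <- counts + graphics::hist(d, breaks = breaks, plot = FALSE)$counts
  }
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  g <- counts / mids
  # light running-mean smoothing suppresses single-bin shot noise before the
  # peak search; the quadratic refinement runs on the smoothed profile
  gs <- as.numeric(stats::filter(g, c(1, 2, 3, 2, 1) / 9, sides = 2))
  gs[is.na(gs)] <- g[is.na(gs)]
  ok <- which(mids >= r_min)
  if (!length(ok) || all(gs[ok] == 0)) {
    return(list(spacing = NA_real_, confident = FALSE,
                profile = data.frame(r = mids, g = g)))
  }
  m <- ok[which.max(gs[ok])]
  peak <- gs[m]
  background <- mean(gs[ok])
  spacing <- mids[m]
  if (m > 1 && m < length(gs)) {
    y1 <- gs[m - 1]; y2 <- gs[m]; y3 <- gs[m + 1]
    denom <- y1 - 2 * y2 + y3
    if (denom < 0) spacing <- mids[m] + 0.5 * (y1 - y3) / denom * bin_width
  }
  list(spacing = spacing,
       confident = background > 0 && peak / background >= min_prominence,
       profile = data.frame(r = mids, g = g))
}

#' Recover the interaction sector from a heading-aligned attention map
#'
#' Thresholds the attention at half its maximum; the interaction radius is
#' the 95th percentile of super-threshold source distances and the angular
#' width is the central (heading-symmetric) interval holding 95% of the
#' super-threshold attention mass.
#'
#' @param map Data frame with heading-aligned relative coordinates `rel_x`,
#'   `rel_y` and attention `alpha` (as returned by [attention_map()]).
#' @param mass Quantile of super-threshold mass covered (default 0.95).
#' @param max_quantile Quantile used as the robust "maximum" attention; maps
#'   pool tens of thousands of pairs, so the literal sample maximum is an
#'   extreme value that would inflate the half-maximum threshold.
#' @return List with `radius`, `angular_width` (degrees), `threshold` and
#'   `flagged` (`TRUE` when no point exceeds the threshold).
#' @export
sector_recovery <- function(map, mass = 0.95, max_quantile = 0.999) {
  thr <- stats::quantile(map$alpha, max_quantile, names = FALSE) / 2
  sel <- map$alpha >= thr & map$alpha > 0
  if (!any(sel)) {
    return(list(radius = NA_real_, angular_width = NA_real_,
                threshold = thr, flagged = TRUE))
  }
  rx <- map$rel_x[sel]; ry <- map$rel_y[sel]; w <- map$alpha[sel]
  r <- sqrt(rx^2 + ry^2)
  ang <- abs(atan2(ry, rx))
  wq <- function(v, w, p) {
    o <- order(v)
    cw <- cumsum(w[o]) / sum(w)
    v[o][which(cw >= p)[1]]
  }
  list(radius = wq(r, w, mass),
       angular_width = 2 * wq(ang, w, mass) * 180 / pi,
       threshold = thr, flagged = FALSE)
}

#' Heading-aligned attention map
#'
#' Runs the model on a batch of frames and expresses every (target, source)
#' pair in the target's heading frame (heading rotated onto the positive
#' x-axis), collecting the attention weight per output variable.  Targets
#' with zero velocity are skipped (no heading).
#'
#' @param model A trained model.
#' @param states `[S, n, d]` array of frames with columns `x, y, vx, vy`.
#' @param globals Optional `[S, g]` globals.
#' @param var Output variable whose attention fills `alpha`.
#' @param max_frames Cap on the number of frames evaluated.
#' @return Data frame with `rel_x`, `rel_y`, `r`, `alpha` (plus
#'   `alpha_<q>` columns for every output variable).
#' @export
attention_map <- function(model, states, globals = NULL, var = 1L,
                          max_frames = Inf) {
  S <- min(dim(states)[1], max_frames)
  rows <- list()
  for (s in seq_len(S)) {
    st <- states[s, , ]
    att <- an_forward(model, st,
                      globals = if (is.null(globals)) NULL else globals[s, ])$attention
    n <- nrow(st)
    speed <- sqrt(st[, 3]^2 + st[, 4]^2)
    for (i in seq_len(n)) {
      if (speed[i] == 0) next
      ct <- st[i, 3] / speed[i]; sn <- st[i, 4] / speed[i]
      dx <- st[-i, 1] - st[i, 1]
      dy <- st[-i, 2] - st[i, 2]
      relx <- ct * dx + sn * dy
      rely <- -sn * dx + ct * dy
      a <- att[i, -i, , drop = FALSE]
      df <- data.frame(rel_x = relx, rel_y = rely,
                       r = sqrt(relx^2 + rely^2))
      for (q in seq_len(dim(att)[3])) df[[paste0("alpha_", q)]] <- a[1, , q]
      rows[[length(rows) + 1L]] <- df
    }
  }
  out <- do.call(rbind, rows)
  out$alpha <- out[[paste0("alpha_", var)]]
  out
}

#' Binned attention heatmap
#'
#' Averages a heading-aligned attention map on a square grid, optionally
#' returning the contour level of the top quantile of attention.
#'
#' @param map Result of [attention_map()].
#' @param bin_width Bin width in state units.
#' @param extent Half-width of the mapped region.
#' @param top_quantile Quantile defining the high-attention contour level.
#' @return List with `grid` (data frame `rel_x`, `rel_y`, `alpha`, `count`;
#'   empty bins carry `NA`) and `contour_level`.
#' @export
attention_heatmap <- function(map, bin_width = 0.2, extent = 3,
                              top_quantile = 0.9999) {
  grid <- bin2d(map$rel_x, map$rel_y, map$alpha, bin_width, extent)
  names(grid)[3] <- "alpha"
  list(grid = grid,
       contour_level = stats::quantile(map$alpha, top_quantile, names = FALSE))
}

# Mean of `v` on a square grid over [-extent, extent]^2; empty bins are NA.
bin2d <- function(x, y, v, bin_width, extent) {
  nb <- ceiling(2 * extent / bin_width)
  ix <- floor((x + extent) / bin_width) + 1L
  iy <- floor((y + extent) / bin_width) + 1L
  keep <- ix >= 1L & ix <= nb & iy >= 1L & iy <= nb
  cell <- (iy[keep] - 1L) * nb + ix[keep]
  sums <- numeric(nb * nb)
  acc <- rowsum(v[keep], cell)
  sums[as.integer(rownames(acc))] <- acc
  counts <- tabulate(cell, nbins = nb * nb)
  centers <- -extent + (seq_len(nb) - 0.5) * bin_width
  data.frame(rel_x = rep(centers, nb),
             rel_y = rep(centers, each = nb),
             value = ifelse(counts > 0, sums / pmax(counts, 1L), NA_real_),
             count = counts)
}

#' Velocity-correlation map in heading-aligned coordinates
#'
#' Bins every ordered pair by the source's position in the target's heading
#' frame and averages the cosine similarity of the two velocity vectors --
#' the conventional correlation analysis that attention maps are contrasted
#' with.
#'
#' @param states `[S, n, 4]` array of frames (`x, y, vx, vy`).
#' @param bin_width,extent Binning parameters.
#' @return Data frame `rel_x`, `rel_y`, `cos_sim`, `count` (empty bins `NA`).
#' @export
velocity_correlation_map <- function(states, bin_width = 0.2, extent = 3) {
  S <- dim(states)[1]
  rx <- ry <- cs <- list()
  for (s in seq_len(S)) {
    st <- states[s, , ]
    n <- nrow(st)
    speed <- sqrt(st[, 3]^2 + st[, 4]^2)
    for (i in seq_len(n)) {
      if (speed[i] == 0) next
      ct <- st[i, 3] / speed[i]; sn <- st[i, 4] / speed[i]
      dx <- st[-i, 1] - st[i, 1]; dy <- st[-i, 2] - st[i, 2]
      vj <- st[-i, 3:4, drop = FALSE]
      nv <- sqrt(rowSums(vj^2))
      ok <- nv > 0
      rx[[length(rx) + 1L]] <- (ct * dx + sn * dy)[ok]
      ry[[length(ry) + 1L]] <- (-sn * dx + ct * dy)[ok]
      cs[[length(cs) + 1L]] <- ((st[i, 3] * vj[, 1] + st[i, 4] * vj[, 2]) /
                                  (speed[i] * nv))[ok]
    }
  }
  df <- data.frame(rel_x = unlist(rx), rel_y = unlist(ry), v = unlist(cs))
  out <- bin2d(df$rel_x, df$rel_y, df$v, bin_width, extent)
  names(out)[3] <- "cos_sim"
  out
}
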