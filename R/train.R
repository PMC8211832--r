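# Losses and the training loop.

#' Binary cross-entropy
#'
#' Mean binary cross-entropy between predicted alive-probabilities and
#' binary labels.
#'
#' @param prob Numeric array of probabilities in (0, 1).
#' @param labels Binary array of the same shape.
#' @param eps Clamping constant guarding `log(0)`.
#' @return Scalar loss.
#' @export
#' @examples
#' loss_bce(c(0.9, 0.1), c(1, 0))   # -log(0.9) averaged with -log(0.9)
loss_bce <- function(prob, labels, eps = 1e-12) {
  if (!all(labels %in% c(0, 1))) stop("labels must be binary (0/1)")
  p <- pmin(pmax(prob, eps), 1 - eps)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

#' Gaussian negative log-likelihood
#'
#' Univariate Gaussian NLL per (agent, variable), summed over variables and
#' averaged over agents: `mean_i sum_q [ 0.5 log(2 pi s2_iq) +
#' (x_iq - mu_iq)^2 / (2 s2_iq) ]`.
#'
#' @param mu,s2 Matrices of predicted means and variances (`n x Q`).
#' @param target Matrix of observed values, same shape.
#' @return Scalar loss.
#' @export
#' @examples
#' loss_nll_gaussian(0, 1, 0)    # 0.5 * log(2 * pi)
loss_nll_gaussian <- function(mu, s2, target) {
  if (any(s2 <= 0)) stop("variances must be strictly positive")
  mu <- as.matrix(mu); s2 <- as.matrix(s2); target <- as.matrix(target)
  per <- 0.5 * log(2 * pi * s2) + (target - mu)^2 / (2 * s2)
  mean(rowSums(per))
}

#' Inverse-frequency weighted NLL
#'
#' Weights per-sample losses inversely to the frequency of each sample's
#' trajectory-length class, normalized so the weights average to one (an
#' all-equal-length batch reproduces the unweighted mean).
#'
#' @param nll Numeric vector of per-sample (or per-step) NLL values.
#' @param lengths Integer vector of trajectory lengths, aligned with `nll`.
#' @return Scalar loss.
#' @export
loss_weighted_nll <- function(nll, lengths) {
  if (!length(nll)) stop("empty batch")
  stopifnot(length(nll) == length(lengths))
  freq <- table(lengths)
  w <- 1 / as.numeric(freq[as.character(lengths)])
  w <- w / mean(w)
  mean(w * nll)
}

# AD-graph Gaussian NLL per element: 0.5 log(2 pi s2) + (x - mu)^2 / (2 s2).
ad_nll_terms <- function(mu, s2, target) {
  dev <- ad_sub(mu, target)
  ad_add(ad_scale(ad_log(ad_scale(s2, 2 * pi)), 0.5),
         ad_scale(ad_mul(ad_square(dev), ad_recip(s2)), 0.5))
}

#' Train a model on a generated dataset
#'
#' Runs Adam with the plateau learning-rate schedule: the learning rate drops
#' to `decay` times its value whenever the validation loss has not improved
#' by more than `improve_tol` for `patience` consecutive epochs.  Losses:
#' binary cross-entropy for the deterministic binary system, Gaussian NLL
#' (summed over variables) for stochastic systems, with multi-step
#' sampled-feedback rollouts for recurrent models.  Input and target
#' standardization statistics are computed from the training split and stored
#' with the model.
#'
#' @param model An [an_model()].
#' @param dataset A matching [generate_dataset()] result.
#' @param config A [train_config()].
#' @param track_attention Record per-epoch mean attention of true-neighbor vs
#'   non-neighbor pairs on a probe validation frame (needs dataset labels).
#' @return The trained model; `model$log` holds the per-epoch data frame
#'   (`epoch`, `lr`, `train_loss`, `val_loss`, and attention tracks when
#'   requested).
#' @export
train_agentnet <- function(model, dataset, config = train_config(),
                           track_attention = FALSE) {
  stopifnot(inherits(model, "agentnet_model"), inherits(dataset, "an_dataset"))
  cfg <- model$config
  if (!is.null(config$seed)) set.seed(config$seed)
  S <- dim(dataset$states)[1]
  n <- dim(dataset$states)[2]
  val_n <- max(1L, round(config$val_fraction * S))
  perm <- sample.int(S)
  val_idx <- perm[seq_len(val_n)]
  tr_idx <- perm[-seq_len(val_n)]

  recurrent <- cfg$recurrent
  d <- if (recurrent) dim(dataset$states)[4] else dim(dataset$states)[3]

  # standardization from the training split
  if (recurrent) {
    tr_states <- dataset$states[tr_idx, , , , drop = FALSE]
    model$norm <- norm_stats(tr_states)
    deltas <- tr_states[, , -1, , drop = FALSE] -
      tr_states[, , -dim(tr_states)[3], , drop = FALSE]
    model$tnorm <- norm_stats(deltas)
  } else {
    model$norm <- norm_stats(dataset$states[tr_idx, , , drop = FALSE])
    if (cfg$stochastic) {
      model$tnorm <- norm_stats(dataset$targets[tr_idx, , , drop = FALSE])
    }
  }

  wall0 <- proc.time()
  state <- adam_init(model$params)
  lr <- config$lr
  lr_factors <- NULL
  if (config$att_lr_factor != 1) {
    lr_factors <- lapply(stats::setNames(nm = names(model$params)),
                         function(nm) if (grepl("^att", nm))
                           config$att_lr_factor else 1)
  }
  best <- Inf
  stall <- 0L
  log <- NULL
  n_batches <- ceiling(length(tr_idx) / config$batch_size)
  loss_kind <- if (config$loss != "auto") config$loss else
    if (cfg$stochastic) "nll" else "bce"

  flat_states <- function(idx) {
    # [b, n, d] -> (b*n) x d, frame-major
    x <- dataset$states[idx, , , drop = FALSE]
    matrix(aperm(x, c(2, 1, 3)), ncol = d)
  }
  flat_targets <- function(idx) {
    y <- dataset$targets[idx, , , drop = FALSE]
    matrix(aperm(y, c(2, 1, 3)), ncol = dim(dataset$targets)[3])
  }
  norm_t <- function(y) {
    if (is.null(model$tnorm)) y else
      sweep(sweep(y, 2, model$tnorm$mean, "-"), 2, model$tnorm$sd, "/")
  }

  batch_loss <- function(idx, params, targets_k = NULL, targets_fixed = NULL) {
    B <- length(idx)
    if (recurrent) {
      st <- dataset$states[idx, , , , drop = FALSE]
      obs <- dataset$config$obs_steps
      npred <- dataset$config$target_steps
      g <- if (is.null(dataset$globals)) NULL else
        dataset$globals[idx, , drop = FALSE]
      res <- an_forward_sequence(model, st, obs_steps = obs,
                                 n_predict = npred, globals = g,
                                 feedback = config$feedback, params = params)
      total <- NULL
      for (kk in seq_along(res$steps)) {
        t1 <- res$steps[kk]
        tgt_raw <- matrix(aperm(st[, , t1, , drop = FALSE] -
                                  st[, , t1 - 1L, , drop = FALSE],
                                c(2, 1, 3, 4)), ncol = d)
        tgt <- norm_t(tgt_raw)[res$rows[[kk]], , drop = FALSE]
        per <- ad_nll_terms(res$mu[[kk]], res$s2[[kk]], tgt)
        l <- ad_scale(ad_sum(per), 1 / nrow(tgt))
        total <- if (is.null(total)) l else ad_add(total, l)
      }
      return(ad_scale(total, 1 / length(res$steps)))
    }
    X <- an_std(flat_states(idx), model$norm)
    g <- if (is.null(dataset$globals)) NULL else
      dataset$globals[idx, , drop = FALSE]
    targets <- targets_fixed
    if (is.null(targets) && !is.null(targets_k) && targets_k < n) {
      targets <- t(vapply(seq_len(B), function(b) sample.int(n, targets_k),
                          integer(targets_k)))
    }
    res <- an_forward_core(params, cfg, X, n, B, globals = g,
                           targets = targets, dedupe = !cfg$stochastic)
    sel_rows <- if (is.null(targets)) seq_len(B * n) else
      as.vector(t(targets)) + rep((seq_len(B) - 1L) * n,
                                  each = ncol(targets))
    if (loss_kind == "bce") {
      Y <- flat_targets(idx)[sel_rows, , drop = FALSE]
      ad_bce_logits(res$logits[[1]], Y)
    } else {
      Y <- norm_t(flat_targets(idx))[sel_rows, , drop = FALSE]
      mu <- do.call(ad_cbind, res$mu)
      s2 <- do.call(ad_cbind, res$s2)
      per <- ad_nll_terms(mu, s2, Y)
      ad_scale(ad_sum(per), 1 / nrow(Y))
    }
  }

  # fixed validation target subset keeps the plateau detector comparable
  # across epochs while controlling evaluation cost
  eval_targets <- NULL
  if (!recurrent && !is.null(config$targets_per_frame) &&
      config$targets_per_frame < n) {
    eval_targets <- t(vapply(seq_along(val_idx), function(b)
      sample.int(n, config$targets_per_frame),
      integer(config$targets_per_frame)))
  }
  eval_loss <- function(idx) {
    tot <- 0; m <- 0L
    pos <- 0L
    for (chunk in split(idx, ceiling(seq_along(idx) / 16))) {
      tf <- if (is.null(eval_targets)) NULL else
        eval_targets[pos + seq_along(chunk), , drop = FALSE]
      pos <- pos + length(chunk)
      l <- ad_val(batch_loss(chunk, model$params, targets_fixed = tf))
      tot <- tot + as.numeric(l) * length(chunk)
      m <- m + length(chunk)
    }
    tot / m
  }

  probe_attention <- function() {
    b <- val_idx[1]
    st <- if (recurrent) dataset$states[b, , 1, ] else dataset$states[b, , ]
    g <- if (is.null(dataset$globals)) NULL else dataset$globals[b, ]
    att <- an_forward(model, st, globals = g)$attention
    lab <- if (dataset$system == "ca") dataset$labels else dataset$labels[b, , ]
    a1 <- att[, , 1]
    c(nbr = mean(a1[lab == 1 & !is.na(a1)], na.rm = TRUE),
      out = mean(a1[lab == 0 & !is.na(a1)], na.rm = TRUE))
  }

  for (epoch in seq_len(config$epochs)) {
    ord <- sample(tr_idx)
    tr_loss <- 0
    for (bi in seq_len(n_batches)) {
      lo <- (bi - 1L) * config$batch_size + 1L
      hi <- min(bi * config$batch_size, length(ord))
      idx <- ord[lo:hi]
      ad_begin()
      leaves <- lapply(model$params, ad_leaf)
      loss <- batch_loss(idx, leaves, targets_k = config$targets_per_frame)
      lv <- as.numeric(ad_val(loss))
      if (!is.finite(lv)) {
        ad_end()
        stop(sprintf("training diverged (non-finite loss) at epoch %d, batch %d",
                     epoch, bi))
      }
      grads <- ad_grad(loss, leaves)
      ad_end()
      names(grads) <- names(model$params)
      upd <- adam_step(model$params, grads, state, lr, lr_factors)
      model$params <- upd$params
      state <- upd$state
      tr_loss <- tr_loss + lv * length(idx)
    }
    tr_loss <- tr_loss / length(tr_idx)
    vl <- eval_loss(val_idx)
    row <- data.frame(epoch = epoch, lr = lr, train_loss = tr_loss,
                      val_loss = vl)
    if (track_attention) {
      pa <- probe_attention()
      row$att_neighbor <- pa["nbr"]
      row$att_outside <- pa["out"]
    }
    log <- rbind(log, row)
    if (config$verbose) {
      message(sprintf("epoch %3d lr %.2e train %.5f val %.5f",
                      epoch, lr, tr_loss, vl))
    }
    if (vl < best - config$improve_tol) {
      best <- vl
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) {
        lr <- lr * config$decay
        stall <- 0L
      }
    }
    if (!is.null(config$early_stop_loss) && vl <= config$early_stop_loss) break
    if ((proc.time() - wall0)[[3]] > config$max_seconds) break
  }
  model$log <- log
  model
}

#' Sample future trajectories from a trained model
#'
#' Iteratively samples each state variable from its predicted Gaussian and
#' feeds the sample back, for any horizon (recurrent models keep their LSTM
#' state; static stochastic models are applied frame by frame).  Attention
#' tensors of every step are returned for inspection.
#'
#' @param model A trained stochastic [an_model()].
#' @param observed `n x d` matrix (static models) or `n x T x d` array
#'   (recurrent models) of observed raw states.
#' @param n_steps Number of steps to roll out.
#' @param globals Optional global-variable vector.
#' @param seed Optional RNG seed.
#' @param mean_rollout Propagate the predicted means instead of samples.
#' @return List with `trajectory` (`n x n_steps x d` array of sampled raw
#'   states) and `attention` (list of `n x n x n_out` arrays per step).
#' @export
rollout <- function(model, observed, n_steps, globals = NULL, seed = NULL,
                    mean_rollout = FALSE) {
  cfg <- model$config
  stopifnot(cfg$stochastic)
  if (!is.null(seed)) set.seed(seed)
  if (n_steps == 0) {
    return(list(trajectory = array(0, c(dim(observed)[1], 0,
                                        cfg$input_dims)),
                attention = list()))
  }
  if (cfg$recurrent) {
    obs <- if (length(dim(observed)) == 2) {
      array(observed, c(1, nrow(observed), 1, ncol(observed)))
    } else {
      array(observed, c(1, dim(observed)))
    }
    n <- dim(obs)[2]
    res <- an_forward_sequence(model, obs, obs_steps = dim(obs)[3],
                               n_predict = n_steps,
                               globals = if (is.null(globals)) NULL else
                                 matrix(globals, 1),
                               feedback = "sample",
                               collect_attention = TRUE)
    d <- dim(obs)[4]
    traj <- array(0, c(n, n_steps, d))
    for (kk in seq_along(res$sampled)) traj[, kk, ] <- res$sampled[[kk]]
    if (mean_rollout) {
      warning("mean_rollout is approximated by samples for recurrent models ",
              "unless variances collapse; returning sampled trajectory")
    }
    return(list(trajectory = traj, attention = res$attention))
  }
  x <- as.matrix(observed)
  n <- nrow(x)
  traj <- array(0, c(n, n_steps, ncol(x)))
  atts <- vector("list", n_steps)
  for (s in seq_len(n_steps)) {
    f <- an_forward(model, x, globals = globals)
    delta <- if (mean_rollout) f$mu else
      f$mu + sqrt(f$s2) * matrix(rnorm(length(f$mu)), n)
    x <- advance_state(x, delta)
    traj[, s, ] <- x
    atts[[s]] <- f$attention
  }
  list(trajectory = traj, attention = atts)
}

# Apply predicted state-variable changes.  When the model predicts as many
# variables as the state has, all variables advance by the prediction; when
# it predicts position changes only (the flocking model: 2 of 4 variables),
# positions advance by the predicted displacement and the velocity becomes
# that displacement per step.
advance_state <- function(x, delta) {
  q <- ncol(delta); d <- ncol(x)
  if (q == d) return(x + delta)
  if (q == 2 && d == 4) {
    x[, 1:2] <- x[, 1:2] + delta
    x[, 3:4] <- delta
    return(x)
  }
  stop("cannot map ", q, " predicted variables onto ", d, " state variables")
}
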