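# Recurrent (LSTM-encoder) forward pass, with optional dynamic agent
# presence.  Each agent carries a 128-dim hidden/cell pair initialized by
# trainable MLPs from its first observed state; at every step the LSTM
# consumes the agent's (standardized) state, the hidden state is projected to
# key/query/value, and the usual variable-wise attention stage predicts the
# Gaussian parameters of the next state change.  Beyond the observed window
# the model feeds its own samples back (or the ground truth under teacher
# forcing), so it can be rolled out indefinitely.
#
# With a presence mask, absent agents keep their stored hidden state but are
# excluded from attention, from other agents' aggregation, and from
# predictions; an agent entering mid-sequence starts a fresh hidden chain
# from the init MLPs.

lstm_cell <- function(params, x, h, c, H) {
  z <- ad_add(ad_linear(x, params$lstm_Wx, params$lstm_b),
              ad_matmul(h, params$lstm_Wh))
  i <- ad_sigmoid(ad_cols(z, 1:H))
  f <- ad_sigmoid(ad_cols(z, (H + 1):(2 * H)))
  o <- ad_sigmoid(ad_cols(z, (2 * H + 1):(3 * H)))
  g <- ad_tanh(ad_cols(z, (3 * H + 1):(4 * H)))
  cn <- ad_add(ad_mul(f, c), ad_mul(i, g))
  hn <- ad_mul(o, ad_tanh(cn))
  list(h = hn, c = cn)
}

# Pair indices among present agents, frame-major.  present: logical length
# B*n (agent-major within frame).  Returns NULL if no frame has >= 2 agents.
masked_pairs <- function(present, n, B) {
  tgt <- integer(0); src <- integer(0); group <- integer(0); n_src <- integer(0)
  self_rows <- integer(0)
  ord <- 0L
  for (b in seq_len(B)) {
    rows <- which(present[((b - 1L) * n + 1L):(b * n)]) + (b - 1L) * n
    m <- length(rows)
    if (m == 0L) next
    self_rows <- c(self_rows, rows)
    n_src <- c(n_src, rep(m - 1L, m))
    if (m >= 2L) {
      tg <- rep(rows, each = m - 1L)
      sr <- unlist(lapply(seq_len(m), function(ii) rows[-ii]), use.names = FALSE)
      tgt <- c(tgt, tg); src <- c(src, sr)
      group <- c(group, rep(ord + seq_len(m), each = m - 1L))
    }
    ord <- ord + m
  }
  list(tgt = tgt, src = src, group = group, n_src = n_src,
       self_rows = self_rows, T_total = ord)
}

# Sequence forward.
#
# states     [B, n, T, d] raw states (T >= obs_steps; under teacher feedback
#            T must cover obs_steps + n_predict - 1 input steps)
# obs_steps  number of observed input steps before predictions start
# n_predict  number of predicted steps
# mask       optional [B, n, T'] presence array, T' >= obs_steps + n_predict
# feedback   "sample" (feed model samples back) or "teacher"
# params     optional AD-leaf parameter list (training); defaults to plain
# raw_output un-standardize mu/s2 into raw state-change units
an_forward_sequence <- function(model, states, obs_steps = dim(states)[3],
                                n_predict = 1L, globals = NULL, mask = NULL,
                                feedback = c("sample", "teacher"),
                                params = NULL, collect_attention = FALSE,
                                raw_output = FALSE) {
  feedback <- match.arg(feedback)
  cfg <- model$config
  stopifnot(cfg$recurrent)
  if (is.null(params)) params <- model$params
  d <- dim(states)[4]; Tn <- dim(states)[3]; n <- dim(states)[2]
  B <- dim(states)[1]
  N <- B * n
  H <- cfg$lstm_dims
  K <- cfg$attention_dims
  n_steps_in <- obs_steps + n_predict - 1L
  if (feedback == "teacher" && Tn < n_steps_in) {
    stop("teacher forcing needs inputs up to the last prediction step")
  }
  if (!is.null(mask)) {
    stopifnot(dim(mask)[3] >= obs_steps + n_predict)
  }
  norm <- model$norm; tnorm <- model$tnorm

  step_mat <- function(t) matrix(aperm(states[, , t, , drop = FALSE],
                                       c(2, 1, 3, 4)), N, d)
  mask_vec <- function(t) if (is.null(mask)) rep(TRUE, N) else
    as.vector(t(mask[, , t]))
  u_frame <- if (is.null(globals)) NULL else as.matrix(globals)

  h <- NULL; c_ <- NULL
  seen <- rep(FALSE, N)
  x_cur <- NULL                         # raw current input (matrix or AD)
  out <- list(steps = integer(0), mu = list(), s2 = list(), rows = list(),
              attention = list(), sampled = list())
  indicator_col <- function(newly) {
    if (cfg$indicator) matrix(as.numeric(newly), N, 1) else NULL
  }

  for (t in seq_len(n_steps_in)) {
    present <- mask_vec(t)
    newly <- present & !seen
    if (t <= obs_steps || feedback == "teacher") {
      x_raw <- step_mat(min(t, Tn))
    } else {
      x_raw <- x_cur                    # fed-back sample (AD under training)
    }
    xs <- if (is.null(norm)) x_raw else
      ad_coltransform(x_raw, 1 / norm$sd, -norm$mean / norm$sd)
    if (cfg$indicator) xs <- ad_cbind(xs, indicator_col(newly))

    # initialize hidden chains for newly present agents
    if (any(newly)) {
      xs_new <- ad_rows(xs, which(newly))
      h0 <- mlp_apply(params, "inith", xs_new, 2L)
      c0 <- mlp_apply(params, "initc", xs_new, 2L)
      if (is.null(h)) {
        h <- matrix(0, N, H); c_ <- matrix(0, N, H)
      }
      h <- ad_scatter_rows(h, which(newly), h0)
      c_ <- ad_scatter_rows(c_, which(newly), c0)
      seen <- seen | newly
    }

    # advance LSTM for present agents only
    idx <- which(present)
    if (length(idx)) {
      upd <- lstm_cell(params, ad_rows(xs, idx), ad_rows(h, idx),
                       ad_rows(c_, idx), H)
      h <- ad_scatter_rows(h, idx, upd$h)
      c_ <- ad_scatter_rows(c_, idx, upd$c)
    }

    if (t >= obs_steps) {
      # predict the state change into step t+1
      enc <- mlp_apply(params, "enc", h, 2L)
      Kmat <- ad_cols(enc, 1:K)
      Qmat <- ad_cols(enc, (K + 1):(2 * K))
      Vmat <- ad_cols(enc, (2 * K + 1):(3 * K))
      mp <- masked_pairs(present, n, B)
      u_pair <- if (is.null(u_frame)) NULL else
        u_frame[ceiling(mp$tgt / n), , drop = FALSE]
      res <- decode_stage(params, cfg, Kmat, Qmat, Vmat,
                          tgt_slot = mp$tgt, src_slot = mp$src,
                          self_slot = mp$self_rows, group = mp$group,
                          T_total = mp$T_total, n_src = mp$n_src,
                          u_pair = u_pair,
                          collect_attention = collect_attention)
      mu <- do.call(ad_cbind, res$mu)
      s2 <- do.call(ad_cbind, res$s2)
      k_pred <- length(out$steps) + 1L
      out$steps[k_pred] <- t + 1L
      out$rows[[k_pred]] <- mp$self_rows
      if (collect_attention) {
        n_att <- ncol(res$alpha)
        att <- array(NA_real_, c(n, n, n_att))
        if (B == 1L && length(mp$tgt)) {
          att[cbind(mp$tgt, mp$src, rep(seq_len(n_att),
                                        each = length(mp$tgt)))] <-
            as.vector(res$alpha)
          out$attention[[k_pred]] <- att
        } else {
          out$attention[[k_pred]] <- list(alpha = res$alpha, tgt = mp$tgt,
                                          src = mp$src)
        }
      }
      if (raw_output) {
        muv <- ad_val(mu); s2v <- ad_val(s2)
        if (!is.null(tnorm)) {
          muv <- sweep(sweep(muv, 2, tnorm$sd, "*"), 2, tnorm$mean, "+")
          s2v <- sweep(s2v, 2, tnorm$sd^2, "*")
        }
        out$mu[[k_pred]] <- muv; out$s2[[k_pred]] <- s2v
      } else {
        out$mu[[k_pred]] <- mu; out$s2[[k_pred]] <- s2
      }

      if (feedback == "sample") {
        eps <- matrix(rnorm(length(ad_val(mu))), nrow(ad_val(mu)))
        samp_n <- ad_add(mu, ad_mul(ad_sqrt(s2), eps))
        # back to raw units, then integrate onto the current raw state
        samp_raw <- if (is.null(tnorm)) samp_n else
          ad_coltransform(samp_n, tnorm$sd, tnorm$mean)
        prev_raw <- x_raw
        nxt_rows <- ad_add(ad_rows(prev_raw, mp$self_rows), samp_raw)
        x_cur <- ad_scatter_rows(ad_val(prev_raw), mp$self_rows, nxt_rows)
        out$sampled[[k_pred]] <- ad_val(x_cur)
      }
    }
  }
  out
}
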