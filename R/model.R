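# The variable-wise graph attention network.
#
# Architecture: a shared encoder maps each agent's (standardized) state to a
# key, query and value (three slices of one final layer); one attention MLP
# per output variable maps concatenated (key_i, query_j, globals) to a scalar
# coefficient a_ij^q squashed by a sigmoid into alpha_ij^q in (0, 1) -- no
# softmax across neighbors, so coefficients are absolute interaction
# strengths; per variable, the alpha^q-weighted values of all other agents
# are averaged and, concatenated with the agent's own value, fed to that
# variable's private decoder (and, for stochastic systems, its private mean
# and variance heads).  The strict per-variable separation makes
# d(output q)/d(alpha^{q'}) identically zero for q' != q.

#' Create a variable-wise attention model
#'
#' @param config A [model_config()].
#' @param seed Optional RNG seed for weight initialization.
#' @return Object of class `agentnet_model`: list with `config`, the flat
#'   named parameter list `params`, and input/target standardization
#'   statistics (`norm`, `tnorm`), filled in by [train_agentnet()].
#' @export
#' @examples
#' m <- an_model(model_config("vicsek"), seed = 1)
an_model <- function(config, seed = NULL) {
  stopifnot(inherits(config, "model_config"))
  if (!is.null(seed)) set.seed(seed)
  K <- config$attention_dims
  params <- list()
  if (config$recurrent) {
    H <- config$lstm_dims
    params$lstm_Wx <- matrix(rnorm(config$input_dims * 4 * H,
                                   sd = sqrt(1 / config$input_dims)),
                             config$input_dims, 4 * H)
    params$lstm_Wh <- matrix(rnorm(H * 4 * H, sd = sqrt(1 / H)), H, 4 * H)
    params$lstm_b <- numeric(4 * H)
    params <- c(params, init_mlp(c(H, config$encoder_hidden, 3L * K), "enc"))
    params <- c(params, init_mlp(c(config$input_dims, 64L, H), "inith"))
    params <- c(params, init_mlp(c(config$input_dims, 64L, H), "initc"))
  } else {
    params <- c(params, init_mlp(c(config$input_dims, config$encoder_hidden,
                                   3L * K), "enc"))
  }
  if (!is.null(config$baseline) && config$baseline != "none") {
    params <- c(params, init_baseline_params(config))
    return(structure(list(config = config, params = params,
                          norm = NULL, tnorm = NULL, log = NULL),
                     class = "agentnet_model"))
  }
  for (q in seq_len(config$n_out)) {
    att <- init_mlp(config$att_layers, paste0("att", q))
    # start with near-zero attention everywhere: the untrained model treats
    # all agents as non-interacting and learns to *grow* weights for true
    # neighbors, rather than having to prune hundreds of spurious ones
    last_b <- paste0("att", q, "_b", length(config$att_layers) - 1L)
    att[[last_b]] <- att[[last_b]] + config$att_bias_init
    params <- c(params, att)
  }
  if (config$decoder_mode == "per_variable") {
    for (q in seq_len(config$n_out)) {
      params <- c(params, init_mlp(c(2L * K, config$decoder_hidden, 1L),
                                   paste0("dec", q)))
      if (config$stochastic) {
        params <- c(params, init_mlp(c(1L, config$head_hidden, 1L),
                                     paste0("mu", q)))
        params <- c(params, init_mlp(c(1L, config$head_hidden, 1L),
                                     paste0("s2", q)))
      }
    }
  } else {
    params <- c(params, init_mlp(c((config$n_out + 1L) * K,
                                   config$decoder_hidden, config$n_out),
                                 "dec1"))
    if (config$stochastic) {
      params <- c(params, init_mlp(c(config$n_out, config$head_hidden,
                                     config$n_out), "mu1"))
      params <- c(params, init_mlp(c(config$n_out, config$head_hidden,
                                     config$n_out), "s21"))
    }
  }
  structure(list(config = config, params = params,
                 norm = NULL, tnorm = NULL, log = NULL),
            class = "agentnet_model")
}

#' @export
print.agentnet_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<agentnet_model %s: %d output variable(s), %d parameters%s>\n",
              x$config$system, x$config$n_out, np,
              if (is.null(x$norm)) " (untrained)" else ""))
  invisible(x)
}

# Standardize raw inputs with the model's stored statistics (identity until
# training has set them).  Works on plain matrices and on AD nodes.
an_std <- function(x, norm) {
  if (is.null(norm)) return(x)
  ad_coltransform(x, 1 / norm$sd, -norm$mean / norm$sd)
}

# Build the pair index template for one frame: each target agent paired with
# every other agent.  `targets` defaults to all agents.
pair_template <- function(n, targets = seq_len(n)) {
  tgt <- rep(targets, each = n - 1L)
  src <- unlist(lapply(targets, function(i) seq_len(n)[-i]), use.names = FALSE)
  list(tgt = tgt, src = src)
}

# Dense per-frame context aggregation: builds each frame's n x n attention
# matrix from the per-pair weights and multiplies it onto the frame's value
# rows, context_i = (1/(n-1)) sum_j alpha_ij v_j.  Mathematically identical
# to the gather/rowsum path but orders of magnitude lighter when every agent
# is a target, because the per-pair value matrix is never materialized.
#
# alpha      AD [P' x 1] per-pair (or per-unique-pair) weights
# V          AD [M x K] value rows
# pair_uid   optional map template-pair -> row of alpha
# src_slot   [n x B] V-row of each agent per frame
# li         linear indices of (tgt, src) template pairs in an n x n matrix
ad_dense_context <- function(alpha, V, pair_uid, src_slot, li, n, B) {
  av <- as.vector(ad_val(alpha))
  if (!is.null(pair_uid)) av <- av[pair_uid]
  Vv <- ad_val(V)
  K <- ncol(Vv)
  P1 <- length(li)                     # pairs per frame
  ctx <- matrix(0, B * n, K)
  Amats <- vector("list", B)
  scal <- 1 / max(n - 1L, 1L)
  for (b in seq_len(B)) {
    A <- matrix(0, n, n)
    A[li] <- av[(b - 1L) * P1 + seq_len(P1)]
    Amats[[b]] <- A
    ctx[(b - 1L) * n + seq_len(n), ] <- scal * (A %*% Vv[src_slot[, b], ,
                                                         drop = FALSE])
  }
  ad_op(ctx, list(alpha, V), function(g) {
    dav <- numeric(B * P1)
    dV <- matrix(0, nrow(Vv), K)
    for (b in seq_len(B)) {
      gb <- g[(b - 1L) * n + seq_len(n), , drop = FALSE] * scal
      rows <- src_slot[, b]
      dA <- tcrossprod(gb, Vv[rows, , drop = FALSE])
      dav[(b - 1L) * P1 + seq_len(P1)] <- dA[li]
      dVb <- crossprod(Amats[[b]], gb)
      acc <- rowsum(dVb, rows)
      ri <- as.integer(rownames(acc))
      dV[ri, ] <- dV[ri, ] + acc
    }
    da <- if (is.null(pair_uid)) dav else {
      acc <- rowsum(dav, pair_uid)
      out <- numeric(nrow(ad_val(alpha)))
      out[as.integer(rownames(acc))] <- acc
      out
    }
    list(matrix(da, ncol = 1), dV)
  })
}

# Attention + aggregation + decoding stage shared by the static and
# recurrent forward passes.
#
# Kmat/Qmat/Vmat  per-slot key/query/value matrices (AD nodes or plain)
# tgt_slot/src_slot  per pair, the encoder-row slot of target and source
# self_slot       per target, the slot holding its own value
# group           per pair, the target ordinal (1..T_total)
# n_src           per target, the number of sources it aggregates over
# u_pair          per pair globals matrix, or NULL
# puid            optional map pair -> unique attention-input row: when given,
#                 the attention MLP runs on unique (tgt_slot, src_slot) rows
#                 only and its outputs are gathered back
attend_decode <- function(params, cfg, Kmat, Qmat, Vmat,
                          tgt_slot, src_slot, self_slot, group, T_total,
                          n_src, u_pair = NULL, puid = NULL,
                          att_tgt = NULL, att_src = NULL,
                          dense = NULL, collect_attention = FALSE) {
  if (is.null(att_tgt)) { att_tgt <- tgt_slot; att_src <- src_slot }
  att_in <- ad_gather_pair(Kmat, Qmat, att_tgt, att_src, u_pair)
  n_att_layers <- n_mlp_layers(cfg$att_layers)
  V_self <- ad_rows(Vmat, self_slot)
  if (is.null(dense)) V_src <- ad_rows(Vmat, src_slot)

  # The decoder consumes the total interaction term (the sum over sources of
  # alpha-weighted values, the pairwise-interaction sum); the inspectable
  # aggregate per agent is its mean over sources -- the two differ by the
  # fixed factor n_src, and feeding the sum keeps the context's gradient
  # scale independent of the (large) number of non-interacting agents.
  alpha_list <- vector("list", cfg$n_out)
  ctx_list <- vector("list", cfg$n_out)
  for (q in seq_len(cfg$n_out)) {
    a <- mlp_apply(params, paste0("att", q), att_in, n_att_layers)
    alpha <- ad_sigmoid(a)
    if (!is.null(dense)) {
      ctx_mean <- ad_dense_context(alpha, Vmat, puid, dense$src_slot,
                                   dense$li, dense$n, dense$B)
      ctx_list[[q]] <- ad_scale(ctx_mean, dense$n - 1L)
      if (collect_attention) {
        av <- as.vector(ad_val(alpha))
        if (!is.null(puid)) av <- av[puid]
        alpha_list[[q]] <- matrix(av, ncol = 1)
      }
      next
    }
    if (!is.null(puid)) alpha <- ad_rows(alpha, puid)
    alpha_list[[q]] <- alpha
    wv <- ad_colscale(V_src, alpha)
    ctx_list[[q]] <- ad_rowsum(wv, group, T_total)
  }

  out <- list()
  if (cfg$decoder_mode == "per_variable") {
    dec <- vector("list", cfg$n_out)
    for (q in seq_len(cfg$n_out)) {
      dec[[q]] <- mlp_apply(params, paste0("dec", q),
                            ad_cbind(V_self, ctx_list[[q]]), 2L)
    }
    if (cfg$stochastic) {
      out$mu <- lapply(seq_len(cfg$n_out), function(q)
        mlp_apply(params, paste0("mu", q), dec[[q]], 2L))
      out$s2 <- lapply(seq_len(cfg$n_out), function(q)
        ad_shift(ad_softplus(mlp_apply(params, paste0("s2", q), dec[[q]], 2L)),
                 1e-6))
    } else {
      out$logits <- dec
    }
  } else {
    dec_in <- do.call(ad_cbind, c(list(V_self), ctx_list))
    dec <- mlp_apply(params, "dec1", dec_in, 2L)
    if (cfg$stochastic) {
      mu <- mlp_apply(params, "mu1", dec, 2L)
      s2 <- ad_shift(ad_softplus(mlp_apply(params, "s21", dec, 2L)), 1e-6)
      out$mu <- lapply(seq_len(cfg$n_out), function(q) ad_cols(mu, q))
      out$s2 <- lapply(seq_len(cfg$n_out), function(q) ad_cols(s2, q))
    } else {
      out$logits <- lapply(seq_len(cfg$n_out), function(q) ad_cols(dec, q))
    }
  }
  if (collect_attention) {
    out$alpha <- do.call(cbind, lapply(alpha_list, ad_val))
  }
  out
}

# Core batched forward pass for non-recurrent systems.
#
# params      parameter list (plain matrices or AD leaves)
# cfg         model_config
# X           (B*n) x input_dims matrix of *standardized* states,
#             frame-major (rows 1..n are frame 1)
# n, B        agents per frame, number of frames
# globals     B x n_globals matrix or NULL
# targets     matrix [B, k] of target agent indices per frame, or NULL (all)
# dedupe      exploit repeated identical state rows (discrete systems)
# collect_attention  also return plain alpha values per pair
an_forward_core <- function(params, cfg, X, n, B, globals = NULL,
                            targets = NULL, dedupe = FALSE,
                            collect_attention = FALSE) {
  K <- cfg$attention_dims
  N <- n * B

  if (dedupe && is.null(globals)) {
    key <- do.call(paste, c(as.data.frame(ad_val(X)), sep = ","))
    ucode <- match(key, key[!duplicated(key)])
    Xu <- ad_val(X)[!duplicated(key), , drop = FALSE]
    enc <- mlp_apply(params, "enc", Xu, 2L)
    slot <- ucode                      # agent row -> encoder row
  } else {
    enc <- mlp_apply(params, "enc", X, 2L)
    slot <- seq_len(N)
    dedupe <- FALSE
  }
  Kmat <- ad_cols(enc, 1:K)
  Qmat <- ad_cols(enc, (K + 1):(2 * K))
  Vmat <- ad_cols(enc, (2 * K + 1):(3 * K))

  if (is.null(targets)) targets <- matrix(rep(seq_len(n), B), B, n, byrow = TRUE)
  k <- ncol(targets)
  tpl <- pair_template(n)              # template for the full target set
  if (ncol(targets) == n && all(targets == rep(seq_len(n), each = B))) {
    off <- rep((seq_len(B) - 1L) * n, each = length(tpl$tgt))
    tgt_rows <- off + rep(tpl$tgt, B)
    src_rows <- off + rep(tpl$src, B)
  } else {
    tgt_rows <- integer(0); src_rows <- integer(0)
    for (b in seq_len(B)) {
      tp <- pair_template(n, targets[b, ])
      tgt_rows <- c(tgt_rows, (b - 1L) * n + tp$tgt)
      src_rows <- c(src_rows, (b - 1L) * n + tp$src)
    }
  }
  group <- rep(seq_len(B * k), each = n - 1L)   # target ordinal per pair
  self_rows <- as.vector(t(targets)) + rep((seq_len(B) - 1L) * n, each = k)
  frame_of_pair <- rep(seq_len(B), each = k * (n - 1L))

  att_tgt <- att_src <- NULL
  puid <- NULL
  if (dedupe) {
    M <- max(slot)
    pkey <- slot[tgt_rows] + (slot[src_rows] - 1L) * M
    ufirst <- !duplicated(pkey)
    puid <- match(pkey, pkey[ufirst])
    att_tgt <- slot[tgt_rows[ufirst]]
    att_src <- slot[src_rows[ufirst]]
  }
  u_pair <- if (is.null(globals)) NULL else globals[frame_of_pair, , drop = FALSE]

  # full-target frames aggregate through dense per-frame matmuls
  dense <- NULL
  if (k == n && (is.null(cfg$baseline) || cfg$baseline == "none")) {
    dense <- list(src_slot = matrix(slot, n, B),
                  li = (tpl$src - 1L) * n + tpl$tgt, n = n, B = B)
  }

  out <- decode_stage(params, cfg, Kmat, Qmat, Vmat,
                      tgt_slot = slot[tgt_rows], src_slot = slot[src_rows],
                      self_slot = slot[self_rows], group = group,
                      T_total = B * k, n_src = rep(n - 1L, B * k),
                      u_pair = u_pair, puid = puid,
                      att_tgt = att_tgt, att_src = att_src,
                      dense = dense, collect_attention = collect_attention)
  out$n <- n; out$B <- B; out$targets <- targets
  out$pair_tgt <- tpl$tgt; out$pair_src <- tpl$src
  out
}

#' Full forward pass on one frame
#'
#' Runs encoder, variable-wise neural attention, aggregation, decoders and
#' (for stochastic systems) Gaussian heads on a single frame of agents, and
#' always returns the attention tensor for inspection.
#'
#' @param model An [an_model()].
#' @param states `n x input_dims` matrix of raw agent states.
#' @param globals Optional numeric vector of global variables.
#' @return List with `attention` (an `n x n x n_out` array, `NA` on the
#'   diagonal) and either `prob` (deterministic binary systems; alive
#'   probability per agent) or `mu` / `s2` matrices (`n x n_out`) holding the
#'   per-variable Gaussian parameters for the next state change.
#' @export
#' @examples
#' m <- an_model(model_config("vicsek"), seed = 1)
#' st <- vicsek_state(5, seed = 1)
#' f <- an_forward(m, as.matrix(as.data.frame(st)))
#' dim(f$attention)
an_forward <- function(model, states, globals = NULL) {
  cfg <- model$config
  states <- as.matrix(states)
  if (any(!is.finite(states))) stop("non-finite values in input states")
  if (ncol(states) != cfg$input_dims) {
    stop(sprintf("expected %d state variables, got %d", cfg$input_dims,
                 ncol(states)))
  }
  n <- nrow(states)
  if (cfg$recurrent) {
    seqres <- an_forward_sequence(model,
                                  array(states, c(1, n, 1, ncol(states))),
                                  obs_steps = 1L, n_predict = 1L,
                                  globals = if (is.null(globals)) NULL else
                                    matrix(globals, 1),
                                  feedback = "teacher",
                                  collect_attention = TRUE, raw_output = TRUE)
    return(list(attention = seqres$attention[[1]],
                mu = seqres$mu[[1]], s2 = seqres$s2[[1]]))
  }
  Xn <- an_std(states, model$norm)
  g <- if (is.null(globals)) NULL else matrix(globals, 1)
  res <- an_forward_core(model$params, cfg, Xn, n, 1L, globals = g,
                         collect_attention = TRUE)
  n_att <- max(ncol(res$alpha), 1L)
  att <- array(NA_real_, c(n, n, n_att))
  if (length(res$pair_tgt)) {
    for (q in seq_len(n_att)) {
      att[cbind(res$pair_tgt, res$pair_src, q)] <- res$alpha[, q]
    }
  }
  out <- list(attention = att)
  if (cfg$stochastic) {
    mu <- do.call(cbind, lapply(res$mu, ad_val))
    s2 <- do.call(cbind, lapply(res$s2, ad_val))
    if (!is.null(model$tnorm)) {
      mu <- sweep(sweep(mu, 2, model$tnorm$sd, "*"), 2, model$tnorm$mean, "+")
      s2 <- sweep(s2, 2, model$tnorm$sd^2, "*")
    }
    out$mu <- mu
    out$s2 <- s2
  } else {
    out$prob <- plogis(ad_val(res$logits[[1]]))
  }
  out
}

#' Encode agent states into key, query and value vectors
#'
#' @param model An [an_model()] (non-recurrent).
#' @param states `n x input_dims` matrix of raw states.
#' @return List of `n x attention_dims` matrices `key`, `query`, `value`.
#' @export
an_encode <- function(model, states) {
  cfg <- model$config
  states <- as.matrix(states)
  if (ncol(states) != cfg$input_dims) {
    stop(sprintf("expected %d state variables, got %d", cfg$input_dims,
                 ncol(states)))
  }
  stopifnot(!cfg$recurrent)
  enc <- mlp_apply(model$params, "enc", an_std(states, model$norm), 2L)
  K <- cfg$attention_dims
  list(key = enc[, 1:K, drop = FALSE],
       query = enc[, (K + 1):(2 * K), drop = FALSE],
       value = enc[, (2 * K + 1):(3 * K), drop = FALSE])
}

#' Attention coefficients for one (target, source) pair
#'
#' Evaluates each output variable's attention MLP on the concatenated
#' (key of the target, query of the source, globals) features.
#'
#' @param model An [an_model()].
#' @param key_i Key vector of the target agent.
#' @param query_j Query vector of the source agent.
#' @param globals Optional numeric vector of globals.
#' @return Numeric vector of raw coefficients `a_ij`, one per output variable.
#' @export
an_attention_coefficient <- function(model, key_i, query_j, globals = NULL) {
  cfg <- model$config
  x <- matrix(c(key_i, query_j, globals), 1)
  if (ncol(x) != cfg$att_layers[1]) {
    stop(sprintf("attention input width %d does not match configured %d",
                 ncol(x), cfg$att_layers[1]))
  }
  nl <- n_mlp_layers(cfg$att_layers)
  vapply(seq_len(cfg$n_out), function(q)
    as.numeric(mlp_apply(model$params, paste0("att", q), x, nl)), numeric(1))
}

#' Sigmoid attention weight
#'
#' Maps raw attention coefficients to weights in (0, 1).  Deliberately not a
#' softmax: weights are absolute per-pair interaction strengths and their sum
#' over neighbors is unconstrained.
#'
#' @param a Numeric vector/array of raw coefficients.
#' @return Values in (0, 1), same shape.
#' @export
#' @examples
#' an_attention_weight(0)    # 0.5
an_attention_weight <- function(a) plogis(a)

#' Aggregate neighbor values with attention weights
#'
#' The per-variable context of a target agent is the mean over all other
#' agents of their attention-weighted values: `mean_j alpha_ij * v_j`.
#'
#' @param values `n x d` matrix of value vectors (sources).
#' @param alpha Length-`n` attention weights aligned with rows of `values`
#'   (the self entry must already be excluded by the caller).
#' @return Length-`d` context vector; zero when there are no sources.
#' @export
an_aggregate <- function(values, alpha) {
  if (length(alpha) == 0 || nrow(values) == 0) return(numeric(ncol(values)))
  colMeans(values * alpha)
}

#' Decode one variable's context into its raw output
#'
#' Applies output variable `q`'s private decoder to the concatenated
#' (own value, aggregated context) features -- the strictly per-variable
#' stage that ties attention channel `q` to output `q` alone.
#'
#' @param model An [an_model()] with per-variable decoders.
#' @param self_value Value vector of the target agent.
#' @param context Aggregated context vector for variable `q`.
#' @param q Output-variable index.
#' @return The decoded scalar (deterministic systems: the output logit).
#' @export
an_decode <- function(model, self_value, context, q = 1L) {
  cfg <- model$config
  stopifnot(cfg$decoder_mode == "per_variable")
  x <- matrix(c(self_value, context), 1)
  if (ncol(x) != 2L * cfg$attention_dims) {
    stop(sprintf("decoder input width %d does not match 2 x attention_dims = %d",
                 ncol(x), 2L * cfg$attention_dims))
  }
  as.numeric(mlp_apply(model$params, paste0("dec", q), x, 2L))
}

#' Gaussian statistic heads for one variable
#'
#' Maps variable `q`'s decoded output through its private mean and variance
#' heads; the variance is strictly positive (softplus with a small floor).
#'
#' @param model A stochastic [an_model()].
#' @param decoded Decoded output of variable `q` (see [an_decode()]).
#' @param q Output-variable index.
#' @return Named vector `c(mu, s2)` in standardized-target units.
#' @export
an_gaussian_heads <- function(model, decoded, q = 1L) {
  cfg <- model$config
  stopifnot(cfg$stochastic, cfg$decoder_mode == "per_variable")
  x <- matrix(decoded, 1)
  mu <- as.numeric(mlp_apply(model$params, paste0("mu", q), x, 2L))
  s2 <- softplus(as.numeric(mlp_apply(model$params, paste0("s2", q), x, 2L))) + 1e-6
  c(mu = mu, s2 = s2)
}
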