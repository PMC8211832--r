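# Baseline architectures sharing the encoder and decoder scaffolding:
#
# * "mlp" / "lstm": the attention core is removed entirely; the (widened)
#   decoder sees only the agent's own value, so predictions are invariant to
#   other agents.
# * "gat": a single scaled inner-product attention per (i, j) pair computed
#   from 128-dim linear projections of key and query, shared by all output
#   variables (softmax over sources by default, sigmoid optional).
# * "gat3": three inner-product heads with per-head key/query/value
#   projections; head contexts are concatenated and fed to the per-variable
#   decoders.

# Row-wise dot product of two equal-shape matrices -> column vector.
ad_rowdot <- function(x, y) {
  xv <- ad_val(x); yv <- ad_val(y)
  ad_op(matrix(rowSums(xv * yv), ncol = 1), list(x, y), function(g) {
    gv <- as.vector(g)
    list(yv * gv, xv * gv)
  })
}

# Softmax over groups of rows (a: [P, 1]); numerically stabilized with the
# (constant) per-group maximum.
ad_group_softmax <- function(a, group, ngroups) {
  av <- ad_val(a)
  mx <- as.numeric(tapply(as.vector(av), group, max)[as.character(seq_len(ngroups))])
  mx[is.na(mx)] <- 0
  mx <- matrix(mx[group], ncol = 1)
  e <- ad_exp(ad_shift(a, -mx))
  denom <- ad_rowsum(e, group, ngroups)
  ad_mul(e, ad_recip(ad_rows(denom, group)))
}

#' Create a baseline model
#'
#' @param type `"mlp"`, `"lstm"`, `"gat"` or `"gat3"`.
#' @param config A [model_config()]; the system preset to compare against.
#' @param seed Optional RNG seed.
#' @return An `agentnet_model` whose attention core is replaced by the
#'   baseline mechanism (`"lstm"` forces the recurrent encoder, `"mlp"` the
#'   static one).
#' @export
#' @examples
#' b <- an_baseline("gat", model_config("vicsek"), seed = 1)
an_baseline <- function(type = c("mlp", "lstm", "gat", "gat3"), config,
                        seed = NULL) {
  type <- match.arg(type)
  stopifnot(inherits(config, "model_config"))
  config$baseline <- type
  if (type == "lstm") config$recurrent <- TRUE
  if (type == "mlp") config$recurrent <- FALSE
  an_model(config, seed = seed)
}

# Parameter initialization for the baseline-specific pieces; called from
# an_model().  K = attention dims, hd = per-head dims.
init_baseline_params <- function(cfg) {
  K <- cfg$attention_dims
  params <- list()
  if (cfg$baseline %in% c("mlp", "lstm")) {
    params <- c(params, init_mlp(c(2L * K, 256L, 256L, cfg$n_out), "dec1"))
    if (cfg$stochastic) {
      params <- c(params, init_mlp(c(cfg$n_out, cfg$head_hidden, cfg$n_out),
                                   "mu1"))
      params <- c(params, init_mlp(c(cfg$n_out, cfg$head_hidden, cfg$n_out),
                                   "s21"))
    }
  } else if (cfg$baseline == "gat") {
    pd <- cfg$gat_proj_dims
    params$gat_Pk <- matrix(rnorm(K * pd, sd = sqrt(1 / K)), K, pd)
    params$gat_Pq <- matrix(rnorm(K * pd, sd = sqrt(1 / K)), K, pd)
    for (q in seq_len(cfg$n_out)) {
      params <- c(params, init_mlp(c(2L * K, cfg$decoder_hidden, 1L),
                                   paste0("dec", q)))
      if (cfg$stochastic) {
        params <- c(params, init_mlp(c(1L, cfg$head_hidden, 1L),
                                     paste0("mu", q)))
        params <- c(params, init_mlp(c(1L, cfg$head_hidden, 1L),
                                     paste0("s2", q)))
      }
    }
  } else if (cfg$baseline == "gat3") {
    hd <- cfg$gat_head_dims
    for (hh in 1:3) {
      params[[paste0("gat_Pk", hh)]] <- matrix(rnorm(K * hd, sd = sqrt(1 / K)),
                                               K, hd)
      params[[paste0("gat_Pq", hh)]] <- matrix(rnorm(K * hd, sd = sqrt(1 / K)),
                                               K, hd)
      params[[paste0("gat_Pv", hh)]] <- matrix(rnorm(K * hd, sd = sqrt(1 / K)),
                                               K, hd)
    }
    for (q in seq_len(cfg$n_out)) {
      params <- c(params, init_mlp(c(K + 3L * hd, cfg$decoder_hidden, 1L),
                                   paste0("dec", q)))
      if (cfg$stochastic) {
        params <- c(params, init_mlp(c(1L, cfg$head_hidden, 1L),
                                     paste0("mu", q)))
        params <- c(params, init_mlp(c(1L, cfg$head_hidden, 1L),
                                     paste0("s2", q)))
      }
    }
  }
  params
}

# Baseline replacement for attend_decode(); same contract.
baseline_decode <- function(params, cfg, Kmat, Qmat, Vmat,
                            tgt_slot, src_slot, self_slot, group, T_total,
                            n_src, u_pair = NULL, collect_attention = FALSE) {
  V_self <- ad_rows(Vmat, self_slot)
  out <- list()
  heads_of <- function(dec) {
    if (cfg$stochastic && cfg$baseline %in% c("mlp", "lstm")) {
      mu <- mlp_apply(params, "mu1", dec, 2L)
      s2 <- ad_shift(ad_softplus(mlp_apply(params, "s21", dec, 2L)), 1e-6)
      list(mu = lapply(seq_len(cfg$n_out), function(q) ad_cols(mu, q)),
           s2 = lapply(seq_len(cfg$n_out), function(q) ad_cols(s2, q)))
    } else NULL
  }
  if (cfg$baseline %in% c("mlp", "lstm")) {
    zeros <- matrix(0, nrow(ad_val(V_self)), cfg$attention_dims)
    dec <- mlp_apply(params, "dec1", ad_cbind(V_self, zeros), 3L)
    if (cfg$stochastic) {
      out <- c(out, heads_of(dec))
    } else {
      out$logits <- lapply(seq_len(cfg$n_out), function(q) ad_cols(dec, q))
    }
    if (collect_attention) {
      out$alpha <- matrix(0, length(tgt_slot), 1)
    }
    return(out)
  }

  per_variable_outputs <- function(ctx_by_q, alpha_plain) {
    dec <- vector("list", cfg$n_out)
    for (q in seq_len(cfg$n_out)) {
      dec[[q]] <- mlp_apply(params, paste0("dec", q),
                            ad_cbind(V_self, ctx_by_q[[q]]), 2L)
    }
    if (cfg$stochastic) {
      out$mu <<- lapply(seq_len(cfg$n_out), function(q)
        mlp_apply(params, paste0("mu", q), dec[[q]], 2L))
      out$s2 <<- lapply(seq_len(cfg$n_out), function(q)
        ad_shift(ad_softplus(mlp_apply(params, paste0("s2", q), dec[[q]], 2L)),
                 1e-6))
    } else {
      out$logits <<- dec
    }
    if (collect_attention) out$alpha <<- alpha_plain
  }

  if (cfg$baseline == "gat") {
    pd <- cfg$gat_proj_dims
    kp <- ad_matmul(ad_rows(Kmat, tgt_slot), params$gat_Pk)
    qp <- ad_matmul(ad_rows(Qmat, src_slot), params$gat_Pq)
    a <- ad_scale(ad_rowdot(kp, qp), 1 / sqrt(pd))
    if (cfg$gat_norm == "softmax") {
      alpha <- ad_group_softmax(a, group, T_total)
      ctx <- ad_rowsum(ad_colscale(ad_rows(Vmat, src_slot), alpha),
                       group, T_total)
    } else {
      alpha <- ad_sigmoid(a)
      ctx <- ad_colscale(
        ad_rowsum(ad_colscale(ad_rows(Vmat, src_slot), alpha), group, T_total),
        1 / pmax(n_src, 1L))
    }
    per_variable_outputs(rep(list(ctx), cfg$n_out),
                         if (collect_attention) ad_val(alpha) else NULL)
    return(out)
  }

  # gat3: three heads, concatenated contexts shared by all variables
  ctxs <- vector("list", 3L)
  alphas <- vector("list", 3L)
  for (hh in 1:3) {
    hd <- cfg$gat_head_dims
    kp <- ad_matmul(ad_rows(Kmat, tgt_slot), params[[paste0("gat_Pk", hh)]])
    qp <- ad_matmul(ad_rows(Qmat, src_slot), params[[paste0("gat_Pq", hh)]])
    vp <- ad_matmul(ad_rows(Vmat, src_slot), params[[paste0("gat_Pv", hh)]])
    a <- ad_scale(ad_rowdot(kp, qp), 1 / sqrt(hd))
    alpha <- ad_group_softmax(a, group, T_total)
    ctxs[[hh]] <- ad_rowsum(ad_colscale(vp, alpha), group, T_total)
    if (collect_attention) alphas[[hh]] <- ad_val(alpha)
  }
  ctx_all <- do.call(ad_cbind, ctxs)
  per_variable_outputs(rep(list(ctx_all), cfg$n_out),
                       if (collect_attention) do.call(cbind, alphas) else NULL)
  out
}

# Dispatch between the variable-wise attention stage and baseline stages.
decode_stage <- function(params, cfg, Kmat, Qmat, Vmat,
                         tgt_slot, src_slot, self_slot, group, T_total,
                         n_src, u_pair = NULL, puid = NULL,
                         att_tgt = NULL, att_src = NULL, dense = NULL,
                         collect_attention = FALSE) {
  if (is.null(cfg$baseline) || cfg$baseline == "none") {
    attend_decode(params, cfg, Kmat, Qmat, Vmat, tgt_slot, src_slot,
                  self_slot, group, T_total, n_src, u_pair, puid,
                  att_tgt, att_src, dense, collect_attention)
  } else {
    baseline_decode(params, cfg, Kmat, Qmat, Vmat, tgt_slot, src_slot,
                    self_slot, group, T_total, n_src, u_pair,
                    collect_attention)
  }
}
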