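# Minimal reverse-mode automatic differentiation on dense matrices.
#
# A "tape" records every differentiable operation of one forward pass; the
# backward sweep walks the tape in reverse and accumulates gradients into the
# leaf nodes (the model parameters).  Values are plain base-R matrices; an
# operation whose inputs are all untracked constants is folded away and returns
# a plain matrix, so the same model code serves both training and inference
# (inference simply runs without an active tape).

.ad <- new.env(parent = emptyenv())
.ad$tape <- NULL

ad_begin <- function() {
  tape <- new.env(parent = emptyenv())
  tape$nodes <- vector("list", 256L)
  tape$k <- 0L
  .ad$tape <- tape
  invisible(tape)
}

ad_end <- function() {
  .ad$tape <- NULL
  invisible(NULL)
}

is_ad <- function(x) inherits(x, "ad_node")

ad_val <- function(x) if (is_ad(x)) x$value else x

# Register a leaf (gradient root).  Requires an active tape.
ad_leaf <- function(value) {
  tape <- .ad$tape
  stopifnot(!is.null(tape))
  id <- tape$k + 1L
  tape$k <- id
  if (id > length(tape$nodes)) length(tape$nodes) <- 2L * length(tape$nodes)
  tape$nodes[[id]] <- list(pids = integer(0), back = NULL)
  structure(list(value = value, id = id), class = "ad_node")
}

# Record an op with the given parents and backward closure.  `back` receives
# the upstream gradient and returns a list of gradients, one per parent
# (entries for untracked parents are ignored and may be NULL).
ad_op <- function(value, parents, back) {
  tape <- .ad$tape
  pids <- vapply(parents, function(p) if (is_ad(p)) p$id else 0L, integer(1))
  if (is.null(tape) || all(pids == 0L)) return(value)
  id <- tape$k + 1L
  tape$k <- id
  if (id > length(tape$nodes)) length(tape$nodes) <- 2L * length(tape$nodes)
  tape$nodes[[id]] <- list(pids = pids, back = back)
  structure(list(value = value, id = id), class = "ad_node")
}

# Backward sweep from scalar node `loss`; returns gradients for `leaves`
# (a list of ad_node), zero-filled where the loss does not depend on a leaf.
ad_grad <- function(loss, leaves) {
  tape <- .ad$tape
  stopifnot(!is.null(tape), is_ad(loss))
  grads <- vector("list", tape$k)
  grads[[loss$id]] <- 1
  for (id in seq.int(tape$k, 1L)) {
    g <- grads[[id]]
    if (is.null(g)) next
    node <- tape$nodes[[id]]
    if (is.null(node$back)) next
    pg <- node$back(g)
    for (j in seq_along(node$pids)) {
      pid <- node$pids[[j]]
      if (pid == 0L || is.null(pg[[j]])) next
      grads[[pid]] <- if (is.null(grads[[pid]])) pg[[j]] else grads[[pid]] + pg[[j]]
    }
  }
  lapply(leaves, function(l) {
    g <- grads[[l$id]]
    if (is.null(g)) array(0, dim = dim(as.matrix(l$value))) else g
  })
}

## ---- primitive operations ----------------------------------------------

# x %*% W + b for row-major batches; b is a length-ncol(W) vector.
ad_linear <- function(x, W, b) {
  xv <- ad_val(x); Wv <- ad_val(W); bv <- ad_val(b)
  out <- xv %*% Wv
  out <- out + rep(bv, each = nrow(out))
  ad_op(out, list(x, W, b), function(g) {
    list(g %*% t(Wv), crossprod(xv, g), colSums(g))
  })
}

ad_matmul <- function(x, y) {
  xv <- ad_val(x); yv <- ad_val(y)
  ad_op(xv %*% yv, list(x, y), function(g) {
    list(tcrossprod(g, yv), crossprod(xv, g))
  })
}

ad_add <- function(x, y) {
  xv <- ad_val(x); yv <- ad_val(y)
  ad_op(xv + yv, list(x, y), function(g) list(g, g))
}

ad_sub <- function(x, y) {
  xv <- ad_val(x); yv <- ad_val(y)
  ad_op(xv - yv, list(x, y), function(g) list(g, -g))
}

ad_mul <- function(x, y) {
  xv <- ad_val(x); yv <- ad_val(y)
  ad_op(xv * yv, list(x, y), function(g) list(g * yv, g * xv))
}

# Multiply a (n x k) matrix by a length-n column vector, recycling across cols.
ad_colscale <- function(x, s) {
  xv <- ad_val(x); sv <- ad_val(s)
  sv <- as.vector(sv)
  ad_op(xv * sv, list(x, s), function(g) {
    gs <- rowSums(g * xv)
    list(g * sv, gs)
  })
}

ad_scale <- function(x, a) {   # a: plain scalar constant
  xv <- ad_val(x)
  ad_op(xv * a, list(x), function(g) list(g * a))
}

ad_square <- function(x) {
  xv <- ad_val(x)
  ad_op(xv * xv, list(x), function(g) list(2 * g * xv))
}

ad_exp <- function(x) {
  v <- exp(ad_val(x))
  ad_op(v, list(x), function(g) list(g * v))
}

ad_log <- function(x) {
  xv <- ad_val(x)
  ad_op(log(xv), list(x), function(g) list(g / xv))
}

# Stable sigmoid; C kernel for matrices, base R for small/abstract input.
fast_sigmoid <- function(x) {
  if (is.matrix(x)) return(.sigmoid_fused(x))
  e <- exp(-abs(x))
  ((x >= 0) + (x < 0) * e) / (1 + e)
}

ad_sigmoid <- function(x) {
  v <- fast_sigmoid(as.matrix(ad_val(x)))
  ad_op(v, list(x), function(g) list(g * v * (1 - v)))
}

ad_tanh <- function(x) {
  v <- tanh(ad_val(x))
  ad_op(v, list(x), function(g) list(g * (1 - v * v)))
}

softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

ad_softplus <- function(x) {
  xv <- ad_val(x)
  sig <- fast_sigmoid(xv)
  ad_op(softplus(xv), list(x), function(g) list(g * sig))
}

#' Mish activation
#'
#' The smooth self-gated activation `x * tanh(softplus(x))` used throughout
#' the network's hidden layers.
#'
#' @param x Numeric vector, matrix or array.
#' @return Object of the same shape as `x`.
#' @export
#' @examples
#' mish(0)          # exactly 0
#' mish(c(-5, 5))
mish <- function(x) x * tanh(softplus(x))

ad_mish <- function(x) {
  xv <- ad_val(x)
  f <- .mish_fused(as.matrix(xv))    # value and derivative in one C pass
  ad_op(f$y, list(x), function(g) list(g * f$d))
}

# Row gather: out <- x[idx, ].  Backward scatter-adds into the source rows.
ad_rows <- function(x, idx) {
  xv <- ad_val(x)
  n <- nrow(xv)
  ad_op(xv[idx, , drop = FALSE], list(x), function(g) {
    acc <- rowsum(g, group = idx)
    out <- matrix(0, n, ncol(xv))
    out[as.integer(rownames(acc)), ] <- acc
    list(out)
  })
}

# Grouped row sums: out[k, ] <- sum over rows with group == k, k = 1..ngroups.
ad_rowsum <- function(x, group, ngroups) {
  xv <- ad_val(x)
  val <- matrix(0, ngroups, ncol(xv))
  acc <- rowsum(xv, group = group)
  val[as.integer(rownames(acc)), ] <- acc
  ad_op(val, list(x), function(g) list(g[group, , drop = FALSE]))
}

ad_cbind <- function(...) {
  args <- list(...)
  vals <- lapply(args, ad_val)
  widths <- vapply(vals, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ad_op(do.call(cbind, vals), args, function(g) {
    lapply(seq_along(args), function(j) g[, starts[j]:ends[j], drop = FALSE])
  })
}

ad_cols <- function(x, cols) {
  xv <- ad_val(x)
  ad_op(xv[, cols, drop = FALSE], list(x), function(g) {
    out <- matrix(0, nrow(xv), ncol(xv))
    out[, cols] <- g
    list(out)
  })
}

ad_mean <- function(x) {
  xv <- ad_val(x)
  n <- length(xv)
  ad_op(matrix(mean(xv), 1, 1), list(x), function(g) {
    list(array(as.numeric(g) / n, dim = dim(xv)))
  })
}

ad_sum <- function(x) {
  xv <- ad_val(x)
  ad_op(matrix(sum(xv), 1, 1), list(x), function(g) {
    list(array(as.numeric(g), dim = dim(xv)))
  })
}

# Mean of x weighted elementwise by constant weights w (same shape).
ad_wmean <- function(x, w) {
  xv <- ad_val(x)
  n <- length(xv)
  ad_op(matrix(sum(xv * w) / n, 1, 1), list(x), function(g) {
    list(array(as.numeric(g) * w / n, dim = dim(xv)))
  })
}

# Numerically stable binary cross-entropy from logits, averaged elementwise.
ad_bce_logits <- function(z, y) {
  zv <- ad_val(z)
  n <- length(zv)
  val <- mean(softplus(zv) - y * zv)
  ad_op(matrix(val, 1, 1), list(z), function(g) {
    list(as.numeric(g) * (plogis(zv) - y) / n)
  })
}

## ---- parameter utilities ------------------------------------------------

# Kaiming-style initialization for an MLP given layer widths.
init_mlp <- function(widths, prefix) {
  params <- list()
  for (l in seq_len(length(widths) - 1L)) {
    fan_in <- widths[l]
    params[[paste0(prefix, "_W", l)]] <-
      matrix(rnorm(fan_in * widths[l + 1L], sd = sqrt(2 / fan_in)),
             fan_in, widths[l + 1L])
    params[[paste0(prefix, "_b", l)]] <- numeric(widths[l + 1L])
  }
  params
}

# Apply an MLP (parameters named as in init_mlp) with Mish on hidden layers.
# The whole stack runs as a single fused tape node (C++ forward/backward).
mlp_apply <- function(params, prefix, x, n_layers) {
  Ws <- lapply(seq_len(n_layers), function(l) params[[paste0(prefix, "_W", l)]])
  bs <- lapply(seq_len(n_layers), function(l) params[[paste0(prefix, "_b", l)]])
  Wv <- lapply(Ws, ad_val)
  bv <- lapply(bs, ad_val)
  xv <- as.matrix(ad_val(x))
  if (!is.double(xv)) storage.mode(xv) <- "double"
  f <- .mlp_fwd(xv, Wv, bv)
  ad_op(f$out, c(list(x), Ws, bs), function(g) {
    bk <- .mlp_bwd(g, Wv, f$acts, f$derivs)
    c(list(bk$dX), bk$dWs, bk$dbs)
  })
}

# Reference implementation built from the layer-wise primitives; used to
# cross-check the fused path.
mlp_apply_ref <- function(params, prefix, x, n_layers) {
  h <- x
  for (l in seq_len(n_layers)) {
    h <- ad_linear(h, params[[paste0(prefix, "_W", l)]],
                   params[[paste0(prefix, "_b", l)]])
    if (l < n_layers) h <- ad_mish(h)
  }
  h
}

n_mlp_layers <- function(widths) length(widths) - 1L

## ---- Adam optimizer ------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim = dim(as.matrix(p)))),
       v = lapply(params, function(p) array(0, dim = dim(as.matrix(p)))),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, lr_factors = NULL,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    lr_p <- if (is.null(lr_factors)) lr else lr * (lr_factors[[nm]] %||% 1)
    g <- grads[[nm]]
    dim_p <- dim(as.matrix(params[[nm]]))
    g <- array(g, dim = dim_p)
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    upd <- lr_p * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    if (is.matrix(params[[nm]])) {
      params[[nm]] <- params[[nm]] - upd
    } else {
      params[[nm]] <- params[[nm]] - as.vector(upd)
    }
  }
  list(params = params, state = state)
}

ad_sqrt <- function(x) {
  v <- sqrt(ad_val(x))
  ad_op(v, list(x), function(g) list(g / (2 * v)))
}

# Add a plain constant (scalar or conforming array).
ad_shift <- function(x, c) {
  ad_op(ad_val(x) + c, list(x), function(g) list(g))
}

# Per-column affine transform with constant vectors: x * scale + shift.
ad_coltransform <- function(x, scale, shift) {
  xv <- ad_val(x)
  n <- nrow(xv)
  val <- xv * rep(scale, each = n) + rep(shift, each = n)
  ad_op(val, list(x), function(g) list(g * rep(scale, each = nrow(g))))
}

# Replace rows `idx` of `base` by `new` (same width); both may be tracked.
ad_scatter_rows <- function(base, idx, new) {
  bv <- ad_val(base); nv <- ad_val(new)
  out <- bv
  out[idx, ] <- nv
  ad_op(out, list(base, new), function(g) {
    gb <- g
    gb[idx, ] <- 0
    list(gb, g[idx, , drop = FALSE])
  })
}

# Fused gather-and-concatenate of per-pair attention inputs
# [K[it, ], Q[is, ], u]; the backward pass scatter-adds into K and Q rows.
ad_gather_pair <- function(K, Q, it, is, u = NULL) {
  Kv <- ad_val(K); Qv <- ad_val(Q)
  uv <- if (is.null(u)) matrix(0, length(it), 0) else as.matrix(u)
  it <- as.integer(it); is <- as.integer(is)
  val <- .gather_pair_input(Kv, Qv, it, is, uv)
  dk <- ncol(Kv); dq <- ncol(Qv)
  ad_op(val, list(K, Q), function(g) {
    s <- .scatter_pair_grad(g, it, is, nrow(Kv), dk, dq)
    list(s$dK, s$dQ)
  })
}

ad_recip <- function(x) {
  xv <- ad_val(x)
  v <- 1 / xv
  ad_op(v, list(x), function(g) list(-g * v * v))
}
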