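# Dynamic-node machinery: a per-agent recurrent hidden-state registry that
# survives agents appearing and disappearing mid-sequence, plus a synthetic
# occlusion generator that imposes presence intervals on full trajectories.
#
# The same mechanism drives the masked sequence forward
# (an_forward_sequence() with a presence mask); the registry API below
# exposes it step by step for inspection and testing.

#' Create an empty hidden-state registry
#'
#' @return Object of class `hidden_registry`: an environment mapping agent
#'   ids to their 128-dim hidden/cell vectors and last-seen step.
#' @export
hidden_registry <- function() {
  reg <- new.env(parent = emptyenv())
  reg$hidden <- list()
  reg$cell <- list()
  reg$last_seen <- list()
  structure(reg, class = "hidden_registry")
}

#' Initialize the recurrent state of a newly entering agent
#'
#' Hidden and cell vectors are produced by the model's trainable init MLPs
#' from the agent's first observed (standardized) state.
#'
#' @param model A recurrent [an_model()].
#' @param registry A [hidden_registry()].
#' @param agent_id Identifier of the entering agent.
#' @param state Raw state vector at entry.
#' @param step Time step of entry.
#' @param newly Indicator value appended to the input when the model uses an
#'   entry indicator variable.
#' @return The registry, invisibly (modified in place).
#' @export
init_hidden <- function(model, registry, agent_id, state, step = 1L,
                        newly = 1) {
  stopifnot(inherits(registry, "hidden_registry"), model$config$recurrent)
  id <- as.character(agent_id)
  if (!is.null(registry$hidden[[id]])) {
    stop("agent ", agent_id, " already has a hidden chain; ",
         "re-initialization of a present agent is not allowed")
  }
  xs <- an_std(matrix(state, 1), model$norm)
  if (model$config$indicator) xs <- cbind(xs, newly)
  registry$hidden[[id]] <- as.vector(mlp_apply(model$params, "inith", xs, 2L))
  registry$cell[[id]] <- as.vector(mlp_apply(model$params, "initc", xs, 2L))
  registry$last_seen[[id]] <- step
  invisible(registry)
}

#' Advance the registry by one observed frame
#'
#' Present agents already in the registry advance their LSTM state; present
#' agents not yet seen get a fresh chain from the init MLPs; absent agents
#' keep their stored state untouched (and would resume it on reappearance).
#'
#' @param model A recurrent [an_model()].
#' @param registry A [hidden_registry()].
#' @param frame Matrix of raw states, one row per agent listed in `ids`.
#' @param ids Agent identifiers aligned with the rows of `frame`.
#' @param present Logical vector: which of `ids` are present this step.
#'   Rows marked absent may not carry state in `frame` (an all-`NA` row is
#'   accepted); supplying a present-looking state for an absent agent is an
#'   error guard left to the mask consistency check.
#' @param step Time-step counter stored as `last_seen`.
#' @return List with the updated `registry` and `hidden`, the matrix of
#'   hidden states of the present agents (rows aligned with
#'   `ids[present]`).
#' @export
step_registry <- function(model, registry, frame, ids, present, step = 1L) {
  stopifnot(inherits(registry, "hidden_registry"))
  frame <- as.matrix(frame)
  if (length(ids) != nrow(frame) || length(present) != nrow(frame)) {
    stop("`frame`, `ids` and `present` must align")
  }
  if (anyDuplicated(ids)) stop("duplicated agent ids in frame")
  H <- model$config$lstm_dims
  for (r in which(present)) {
    id <- as.character(ids[r])
    if (any(!is.finite(frame[r, ]))) {
      stop("present agent ", id, " carries a non-finite state")
    }
    if (is.null(registry$hidden[[id]])) {
      init_hidden(model, registry, ids[r], frame[r, ], step = step)
    }
  }
  idx <- which(present)
  if (length(idx)) {
    xs <- an_std(frame[idx, , drop = FALSE], model$norm)
    if (model$config$indicator) {
      newly <- vapply(as.character(ids[idx]), function(id)
        as.numeric(identical(registry$last_seen[[id]], step)), numeric(1))
      xs <- cbind(xs, newly)
    }
    h <- do.call(rbind, registry$hidden[as.character(ids[idx])])
    cc <- do.call(rbind, registry$cell[as.character(ids[idx])])
    upd <- lstm_cell(model$params, xs, h, cc, H)
    hv <- ad_val(upd$h); cv <- ad_val(upd$c)
    for (k in seq_along(idx)) {
      id <- as.character(ids[idx[k]])
      registry$hidden[[id]] <- hv[k, ]
      registry$cell[[id]] <- cv[k, ]
      registry$last_seen[[id]] <- step
    }
    hidden <- hv
  } else {
    hidden <- matrix(0, 0L, H)
  }
  list(registry = registry, hidden = hidden)
}

#' Impose synthetic presence intervals on full trajectories
#'
#' Mimics camera occlusion: each agent is visible for one contiguous interval
#' whose length is drawn from a geometric-like distribution calibrated so the
#' median visible length is `median_length` steps, placed uniformly at random
#' within the sequence.
#'
#' @param n_samples,n_agents,n_steps Dimensions of the mask.
#' @param occlusion_rate Fraction of agents subject to occlusion; 0 returns
#'   an all-present mask.
#' @param median_length Target median of the visible-interval length.
#' @param contiguous If `FALSE`, additionally drops random single steps
#'   inside the interval (stress-testing non-contiguous presence).
#' @param seed Optional RNG seed.
#' @return Logical array `[n_samples, n_agents, n_steps]`.
#' @export
#' @examples
#' m <- synth_occlusion(2, 10, 30, median_length = 10, seed = 1)
#' mean(m)
synth_occlusion <- function(n_samples, n_agents, n_steps,
                            occlusion_rate = 1, median_length = 10,
                            contiguous = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mask <- array(TRUE, c(n_samples, n_agents, n_steps))
  if (occlusion_rate <= 0) return(mask)
  p <- 1 - 2^(-1 / median_length)     # geometric with the requested median
  for (s in seq_len(n_samples)) {
    occluded <- runif(n_agents) < occlusion_rate
    for (a in which(occluded)) {
      len <- min(n_steps, stats::rgeom(1, p) + 1L)
      start <- sample.int(n_steps - len + 1L, 1L)
      v <- rep(FALSE, n_steps)
      v[start:(start + len - 1L)] <- TRUE
      if (!contiguous && len > 2L) {
        drop <- which(v)[stats::runif(len) < 0.1]
        v[drop] <- FALSE
      }
      mask[s, a, ] <- v
    }
  }
  mask
}
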