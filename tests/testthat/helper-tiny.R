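# Small shared fixtures: reduced-width model configs so unit tests stay fast.
# Study-scale trained models for the quantitative checks are built (once) in
# helper-trained.R.

tiny_vicsek_cfg <- function(...) {
  model_config("vicsek", attention_dims = 4L, encoder_hidden = 8L,
               decoder_hidden = 6L, head_hidden = 5L,
               att_layers = c(8L, 6L, 1L), ...)
}

tiny_ca_cfg <- function(...) {
  model_config("ca", attention_dims = 4L, encoder_hidden = 8L,
               decoder_hidden = 6L, att_layers = c(8L, 6L, 1L), ...)
}

tiny_aoup_cfg <- function(...) {
  model_config("aoup", attention_dims = 3L, encoder_hidden = 6L,
               decoder_hidden = 5L, head_hidden = 4L, lstm_dims = 8L,
               att_layers = c(7L, 5L, 1L), ...)
}

# Finite-difference gradient check helper: loss_fn maps a named parameter
# list to an AD scalar; returns the worst relative error over `probes`
# random parameter entries.
fd_grad_check <- function(params, loss_fn, probes = 2L, eps = 1e-5,
                          seed = 42) {
  set.seed(seed)
  agentnet:::ad_begin()
  leaves <- lapply(params, agentnet:::ad_leaf)
  loss <- loss_fn(leaves)
  grads <- agentnet:::ad_grad(loss, leaves)
  agentnet:::ad_end()
  names(grads) <- names(params)
  worst <- 0
  for (nm in names(params)) {
    for (r in seq_len(probes)) {
      i <- sample(length(params[[nm]]), 1)
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
      l1 <- as.numeric(agentnet:::ad_val(loss_fn(pp)))
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
      l2 <- as.numeric(agentnet:::ad_val(loss_fn(pm)))
      fd <- (l1 - l2) / (2 * eps)
      an <- as.vector(grads[[nm]])[i]
      worst <- max(worst, abs(fd - an) / max(abs(fd), abs(an), 1e-8))
    }
  }
  worst
}
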