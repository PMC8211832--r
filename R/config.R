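# Configuration objects: simulator, model and training parameterizations.
#
# Every config is a validated named list with a class tag; unknown keys are
# rejected so that typos in config files fail loudly.

an_check_keys <- function(user, defaults, what) {
  bad <- setdiff(names(user), names(defaults))
  if (length(bad)) {
    stop(sprintf("unknown %s key(s): %s", what, paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  utils::modifyList(defaults, user)
}

#' Simulator configuration
#'
#' Builds the full parameterization of a simulator run for one of the three
#' model systems, starting from the package defaults.
#'
#' @param system One of `"ca"`, `"vicsek"`, `"aoup"`.
#' @param ... Overrides for the system's parameters.  `ca`: `width`, `height`,
#'   `p_alive`.  `vicsek`: `n`, `r_c`, `theta_c`, `sigma`, `region_radius`,
#'   `speed_range`, `angle_convention`.  `aoup`: `n`, `R_range` (interaction
#'   length drawn uniformly per run), `gamma`, `Temp`, `tau`, `D_a`, `k`,
#'   `dt`, `init_radius`, `obs_steps`, `target_steps`, `burn_steps`,
#'   `windows_per_run`.
#' @return Object of class `sim_config`.
#' @export
#' @examples
#' sim_config("vicsek", n = 40)
sim_config <- function(system = c("ca", "vicsek", "aoup"), ...) {
  system <- match.arg(system)
  user <- list(...)
  defaults <- switch(system,
    ca = list(width = 14L, height = 14L, p_alive = 0.5),
    vicsek = list(n = 50L, r_c = 1, theta_c = 120, sigma = 0.1,
                  region_radius = sqrt(5), speed_range = c(0.2, 1),
                  angle_convention = "full"),
    aoup = list(n = 50L, R_range = c(2, 4), gamma = 1, Temp = 1, tau = 1,
                D_a = 1, k = 0.1, dt = 0.05, init_radius = 5,
                obs_steps = 8L, target_steps = 12L, burn_steps = 200L,
                windows_per_run = 5L)
  )
  cfg <- an_check_keys(user, defaults, paste0(system, " simulator"))
  if (system == "aoup") {
    if (is.null(cfg$R_range) || length(cfg$R_range) != 2) {
      stop("aoup config requires `R_range`, the range of the global ",
           "interaction length (e.g. c(2, 4))", call. = FALSE)
    }
    if (cfg$dt >= cfg$tau) stop("`dt` must be well below `tau`", call. = FALSE)
  }
  if (system == "vicsek" && cfg$sigma < 0) stop("`sigma` must be >= 0")
  structure(c(list(system = system), cfg), class = "sim_config")
}

#' Model configuration
#'
#' Network dimensions for each target system.  Defaults follow the reference
#' architecture: encoders `[input, 256, attention_dims]` emitting key, query
#' and value jointly; one attention MLP and one decoder per output variable;
#' decoders `[2 x attention_dims, 128, 1]`; Gaussian statistic heads
#' `[1, 64, 1]` per variable for stochastic systems; LSTM hidden/cell size
#' 128 for recurrent systems.
#'
#' @param system `"ca"`, `"vicsek"`, `"aoup"`, `"swift"` (the dynamic-node
#'   recurrent variant), or `"custom"`.
#' @param ... Overrides: `input_dims`, `n_out` (number of output variables),
#'   `attention_dims`, `att_layers` (widths of the attention MLP including
#'   its input width), `encoder_hidden`, `decoder_hidden`, `head_hidden`,
#'   `stochastic`, `recurrent`, `n_globals`, `indicator`, `decoder_mode`
#'   (`"per_variable"` or `"shared"`), `lstm_dims`.
#' @return Object of class `model_config`.
#' @export
#' @examples
#' model_config("vicsek")
model_config <- function(system = c("ca", "vicsek", "aoup", "swift", "custom"),
                         ...) {
  system <- match.arg(system)
  user <- list(...)
  base <- list(input_dims = 3L, n_out = 1L, attention_dims = 16L,
               att_layers = NULL, encoder_hidden = 256L,
               decoder_hidden = 128L, head_hidden = 64L,
               stochastic = FALSE, recurrent = FALSE, n_globals = 0L,
               indicator = FALSE, decoder_mode = "per_variable",
               lstm_dims = 128L, baseline = "none", gat_proj_dims = 128L,
               gat_head_dims = 12L, gat_norm = "softmax", att_bias_init = -2)
  preset <- switch(system,
    ca = list(input_dims = 3L, n_out = 1L, attention_dims = 16L,
              att_layers = c(32L, 32L, 16L, 1L)),
    vicsek = list(input_dims = 4L, n_out = 2L, attention_dims = 16L,
                  att_layers = c(32L, 64L, 32L, 1L), stochastic = TRUE),
    aoup = list(input_dims = 4L, n_out = 4L, attention_dims = 16L,
                att_layers = c(33L, 16L, 8L, 1L), stochastic = TRUE,
                recurrent = TRUE, n_globals = 1L),
    swift = list(input_dims = 7L, n_out = 6L, attention_dims = 96L,
                 att_layers = c(192L, 16L, 8L, 1L), stochastic = TRUE,
                 recurrent = TRUE, indicator = TRUE),
    custom = list()
  )
  cfg <- an_check_keys(user, utils::modifyList(base, preset), "model config")
  if (is.null(cfg$att_layers)) {
    cfg$att_layers <- c(2L * cfg$attention_dims + cfg$n_globals, 32L, 16L, 1L)
  }
  expected_in <- 2L * cfg$attention_dims + cfg$n_globals
  if (cfg$att_layers[1] != expected_in) {
    stop(sprintf(paste0("attention MLP input width (%d) must equal ",
                        "2 * attention_dims + n_globals = %d"),
                 cfg$att_layers[1], expected_in), call. = FALSE)
  }
  if (utils::tail(cfg$att_layers, 1) != 1L) {
    stop("attention MLP must end in a single unit per output variable",
         call. = FALSE)
  }
  if (!cfg$decoder_mode %in% c("per_variable", "shared")) {
    stop("`decoder_mode` must be \"per_variable\" or \"shared\"", call. = FALSE)
  }
  structure(c(list(system = system), cfg), class = "model_config")
}

#' Training configuration
#'
#' @param ... Overrides: `lr` (initial learning rate), `decay` (multiplier
#'   applied when the validation loss plateaus), `patience` (epochs of no
#'   improvement that define a plateau), `improve_tol` (minimum decrease that
#'   counts as improvement), `batch_size`, `epochs`, `val_fraction`,
#'   `seed`, `loss` (`"bce"`, `"nll"` or `"weighted_nll"`),
#'   `feedback` (`"sample"` or `"teacher"`, recurrent multi-step training),
#'   `targets_per_frame` (subsample of loss/attention target agents per frame,
#'   `NULL` = all), `early_stop_loss` (stop once the validation loss reaches
#'   this value; `NULL` = never), `verbose`.
#' @return Object of class `train_config`.
#' @export
train_config <- function(...) {
  defaults <- list(lr = 5e-4, decay = 0.7, patience = 30L, improve_tol = 1e-4,
                   batch_size = 32L, epochs = 100L, val_fraction = 0.1,
                   seed = NULL, loss = "auto", feedback = "sample",
                   targets_per_frame = NULL, early_stop_loss = NULL,
                   att_lr_factor = 1, max_seconds = Inf, verbose = FALSE)
  cfg <- an_check_keys(list(...), defaults, "train config")
  if (cfg$lr <= 0) stop("learning rate must be positive", call. = FALSE)
  if (cfg$decay <= 0 || cfg$decay >= 1) {
    stop("`decay` must lie in (0, 1)", call. = FALSE)
  }
  if (cfg$patience < 1) stop("`patience` must be >= 1", call. = FALSE)
  if (!cfg$loss %in% c("auto", "bce", "nll", "weighted_nll")) {
    stop("unknown loss type: ", cfg$loss, call. = FALSE)
  }
  if (!cfg$feedback %in% c("sample", "teacher")) {
    stop("`feedback` must be \"sample\" or \"teacher\"", call. = FALSE)
  }
  structure(cfg, class = "train_config")
}

#' Load a configuration file
#'
#' Reads a YAML file holding one or more of the sections `sim`, `model`,
#' `train`, each validated against the package defaults (unknown keys are
#' rejected with the offending key named).  An empty file yields all defaults
#' for the requested `system`.
#'
#' @param path Path to a YAML file.
#' @param system Default system used for sections that do not name one.
#' @return List with elements `sim`, `model`, `train`.
#' @export
load_config <- function(path, system = NULL) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("sim", "model", "train", "system")
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop("unknown config section(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  system <- raw$system %||% system
  if (is.null(system)) stop("config must name a `system`", call. = FALSE)
  sim <- do.call(sim_config, c(list(system = system), raw$sim))
  msys <- if (system %in% c("ca", "vicsek", "aoup", "swift")) system else "custom"
  model <- do.call(model_config, c(list(system = msys), raw$model))
  train <- do.call(train_config, raw$train %||% list())
  list(sim = sim, model = model, train = train)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
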