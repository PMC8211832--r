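# Trajectory tables, model checkpoints and run manifests.

#' Write trajectories to disk
#'
#' Writes the tidy trajectory table as CSV together with a YAML sidecar
#' capturing the simulator configuration, so a dataset round-trips
#' losslessly.
#'
#' @param dataset An `an_dataset` (or a data frame already in table form).
#' @param path Output CSV path; the sidecar is written to `<path>.yml`.
#' @param mask Optional presence mask forwarded to [an_trajectory_table()].
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(dataset, path, mask = NULL) {
  tab <- if (is.data.frame(dataset)) dataset else
    an_trajectory_table(dataset, mask = mask)
  utils::write.csv(tab, path, row.names = FALSE)
  if (!is.data.frame(dataset)) {
    cfg <- dataset$config
    yaml::write_yaml(c(list(system = dataset$system),
                       cfg[setdiff(names(cfg), "system")]),
                     paste0(path, ".yml"))
  }
  invisible(path)
}

#' Read trajectories from disk
#'
#' @param path CSV path written by [write_trajectories()].
#' @return List with the `table` (rows sorted by sample, time, agent), and
#'   `config` (the sidecar list when present).  Missing mandatory columns or
#'   non-monotone time within a trajectory raise an error.
#' @export
read_trajectories <- function(path) {
  tab <- utils::read.csv(path)
  needed <- c("sample_id", "t", "agent_id", "present")
  missing <- setdiff(needed, names(tab))
  if (length(missing)) {
    stop("trajectory file lacks column(s): ", paste(missing, collapse = ", "))
  }
  tab <- tab[order(tab$sample_id, tab$t, tab$agent_id), ]
  rownames(tab) <- NULL
  cfgfile <- paste0(path, ".yml")
  cfg <- if (file.exists(cfgfile)) yaml::read_yaml(cfgfile) else NULL
  list(table = tab, config = cfg)
}

#' Save a model checkpoint
#'
#' Stores weights, configuration, normalization statistics and the training
#' log with a format version tag.
#'
#' @param model An `agentnet_model`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
an_save <- function(model, path) {
  stopifnot(inherits(model, "agentnet_model"))
  obj <- list(format = "agentnet-checkpoint-1", model = unclass(model))
  saveRDS(obj, path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path File written by [an_save()].
#' @return The restored `agentnet_model`.
#' @export
an_load <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "agentnet-checkpoint-1")) {
    stop("not an agentnet checkpoint: ", path)
  }
  structure(obj$model, class = "agentnet_model")
}

#' Write a run manifest
#'
#' Records the command, configuration snapshot, seed, package version, input
#' and output file digests and timing of a run as JSON next to its outputs.
#'
#' @param path Manifest destination.
#' @param command Name of the command that ran.
#' @param config Configuration list included verbatim.
#' @param seed Seed used.
#' @param files Character vector of associated files to digest.
#' @param started `POSIXct` start time.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, config = list(), seed = NULL,
                           files = character(0), started = Sys.time()) {
  digest <- function(f) {
    if (!file.exists(f)) return(NA_character_)
    sprintf("size:%d", file.size(f))
  }
  manifest <- list(
    command = command,
    package_version = as.character(utils::packageVersion("agentnet")),
    seed = seed,
    config = config,
    files = if (length(files))
      stats::setNames(lapply(files, digest), files) else NULL,
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Derive a component sub-seed from a global seed
#'
#' A single run seed fans out to per-component seeds through a fixed
#' counter scheme, so partial re-runs of a pipeline stay reproducible.
#'
#' @param seed Global integer seed.
#' @param component Component counter (0, 1, 2, ...).
#' @return Integer sub-seed (always below 2^31).
#' @export
an_subseed <- function(seed, component) {
  as.integer((as.numeric(seed) * 1000003 + 7919 * component) %% 2147483647)
}
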