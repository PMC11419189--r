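#' Read / write a run configuration file
#'
#' Plain-text YAML mirroring [train_config()] plus the model description
#' (scheme, sizes, synapses per dendrite, classes). Unknown keys are
#' preserved and returned alongside.
#'
#' @param path YAML file path.
#' @return `read_run_config` returns a list with `train` (a
#'   [train_config()]) and `model` (a plain list of model fields);
#'   `write_run_config` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config not found: '%s'", path),
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  tr <- raw$train %||% list()
  cfg <- train_config(
    epochs = tr$epochs %||% 15L,
    batch_size = tr$batch_size %||% 128L,
    learning_rate = tr$learning_rate %||% 0.001,
    beta1 = tr$beta1 %||% 0.9,
    beta2 = tr$beta2 %||% 0.999,
    epsilon = tr$epsilon %||% 1e-8,
    val_fraction = tr$val_fraction %||% 0.1,
    seed = tr$seed %||% 1L,
    shuffle = tr$shuffle %||% TRUE
  )
  list(train = cfg, model = raw$model %||% list(), extra = raw$extra)
}

#' @rdname read_run_config
#' @param config List with `train` (a [train_config()] or plain list) and
#'   `model` fields.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(list(train = unclass(config$train),
                        model = config$model, extra = config$extra), path)
  invisible(path)
}

#' Write a run manifest
#'
#' Records, next to a run's outputs, everything needed to reproduce it: the
#' configuration, all seeds, and the package version.
#'
#' @param dir Output directory.
#' @param config Configuration list (as in [write_run_config()]).
#' @param seeds Integer vector of seeds used.
#' @param extra Optional named list of additional fields.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(dir, config, seeds, extra = NULL) {
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(c(list(
    package = "dendrann",
    version = as.character(utils::packageVersion("dendrann")),
    seeds = as.integer(seeds),
    config = list(train = unclass(config$train), model = config$model)
  ), extra), path)
  invisible(path)
}
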