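# Run configuration: one serializable tree of defaults covering the phantom,
# sampler, training and evaluation stages, with file + override merging
# (overrides > file > defaults) and unknown-key rejection.

#' Default run configuration
#'
#' @return A nested list of class `"run_config"` with sections `phantom`
#'   (see [phantom_params()]), `sampler` (see [sampler_config()]), `dataset`
#'   (`field_of_view`, `resolution`, `volume_id`; `field_of_view = NULL`
#'   means "smallest volume extent"), `train` (see [train_config()]) and
#'   `eval` (`records_csv` flag).
#' @export
default_run_config <- function() {
  structure(list(
    phantom = list(shape = 64L, spacing = 1, skull_radii = NULL,
                   structure_count = 4L, speckle_strength = 0.3,
                   seed = 20220430L),
    sampler = list(n_random = 1000L, n_near_sp = 100L, trans_range = 0.5,
                   rot_range = 45, sp_trans_interval_max = 0.1,
                   sp_trans_interval_min = 0.001, sp_rot_interval_max = 7.9,
                   sp_rot_interval_min = 1.9, min_overlap = 0.75, seed = 1L),
    dataset = list(field_of_view = NULL, resolution = 128L,
                   volume_id = "phantom"),
    train = list(epochs = 50L, batch_size = 100L, learning_rate = 1e-4,
                 beta1 = 0.9, beta2 = 0.999, lambda_weight = 0.01,
                 val_fraction = 0.2, image_size = 128L,
                 backbone = "resnet18", pretrained = FALSE, squared = FALSE,
                 seed = 1L),
    eval = list(records_csv = TRUE)
  ), class = "run_config")
}

# recursive merge of `over` into `base`, rejecting keys absent from `base`
.merge_config <- function(base, over, path = "") {
  for (k in names(over)) {
    full <- if (nzchar(path)) paste0(path, ".", k) else k
    if (!k %in% names(base)) stopf("unknown configuration key '%s'", full)
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      if (!is.list(over[[k]]))
        stopf("configuration key '%s' must be a section", full)
      base[[k]] <- .merge_config(base[[k]], over[[k]], full)
    } else {
      base[k] <- over[k]   # [ ] keeps explicit NULLs
    }
  }
  base
}

#' Load a run configuration
#'
#' Starts from [default_run_config()], merges an optional YAML/JSON file on
#' top, then merges explicit overrides (a nested list) on top of that.
#' Unknown keys at any level are rejected.
#'
#' @param path optional YAML or JSON config file.
#' @param overrides optional nested list of overrides (highest precedence).
#' @return A `"run_config"` list.
#' @export
load_run_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stopf("config file not found: %s", path)
    file_cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    cfg <- .merge_config(cfg, file_cfg)
  }
  if (!is.null(overrides)) cfg <- .merge_config(cfg, overrides)
  structure(cfg, class = "run_config")
}

run_phantom_params <- function(cfg) {
  p <- cfg$phantom
  phantom_params(shape = p$shape, spacing = p$spacing,
                 skull_radii = p$skull_radii,
                 structure_count = p$structure_count,
                 speckle_strength = p$speckle_strength, seed = p$seed)
}

run_sampler_config <- function(cfg) do.call(sampler_config, cfg$sampler)

run_train_config <- function(cfg) do.call(train_config, cfg$train)
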