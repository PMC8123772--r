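#' Default run configuration
#'
#' Every pipeline stage reads its parameters from a nested configuration
#' list; each field carries the protocol default. Unknown keys in a user
#' file are rejected by name.
#'
#' @return A nested list of defaults.
#' @export
default_run_config <- function() {
  list(
    out_dir = "topospectra_out",
    seed = 1L,
    synthetic = list(n_calm = 137L, n_distress = 122L, fs = 512,
                     duration = 60, noise_floor = 0.05,
                     calm_gamma = 0.15, distress_gamma = 0.45),
    preprocess = list(fs_out = 128, low = 3, high = 45,
                      keep_seconds = 30, epoch_seconds = 5),
    spectral = list(window_seconds = 2, overlap = 0.5, n_points = 256L),
    map = list(scheme = "dmd", band = "pt", strict_cells = FALSE),
    net = list(dimensionality = "2D", width = 1.0, dropout = 0.5,
               init = "random"),
    train = list(epochs = 40L, iterations = NULL, batch_size = 12L,
                 learning_rate = 0.001, momentum = 0.9, l2_decay = 0.001,
                 validate_every = 50L),
    experiment = list(n_cycles = 10L, train_fraction = 0.8))
}

merge_config <- function(defaults, user, path = character()) {
  for (key in names(user)) {
    here <- c(path, key)
    if (!key %in% names(defaults)) {
      abort(paste0("unknown configuration key: ",
                   paste(here, collapse = ".")))
    }
    if (is.list(defaults[[key]]) && is.list(user[[key]])) {
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], here)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load and validate a run configuration
#'
#' Reads a YAML file, overlays it on [default_run_config()], and rejects
#' unknown keys by their dotted path.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param overrides Named list applied on top of the file (dotted keys not
#'   supported; pass nested lists).
#' @return The resolved configuration list.
#' @export
load_run_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- merge_config(cfg, user)
  }
  if (!is.null(overrides)) cfg <- merge_config(cfg, overrides)
  cfg
}

config_synthetic_spec <- function(cfg) {
  s <- cfg$synthetic
  calm <- c(theta = 0.30, alpha = 0.35, beta = 0.20, gamma = s$calm_gamma)
  calm[c("theta", "alpha", "beta")] <-
    calm[c("theta", "alpha", "beta")] *
    (1 - s$calm_gamma) / sum(calm[c("theta", "alpha", "beta")])
  dis <- c(theta = 0.15, alpha = 0.20, beta = 0.20,
           gamma = s$distress_gamma)
  dis[c("theta", "alpha", "beta")] <-
    dis[c("theta", "alpha", "beta")] *
    (1 - s$distress_gamma) / sum(dis[c("theta", "alpha", "beta")])
  synthetic_spec(n_calm = s$n_calm, n_distress = s$n_distress, fs = s$fs,
                 duration = s$duration, calm_profile = calm,
                 distress_profile = dis, noise_floor = s$noise_floor,
                 seed = cfg$seed)
}

run_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(fmt, ...)))
}

write_provenance <- function(cfg, out_dir, stage) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- list(stage = stage, seed = cfg$seed,
               package_version = as.character(
                 utils::packageVersion("topospectra")),
               config = cfg,
               config_hash = rlang::hash(cfg))
  jsonlite::write_json(prov, file.path(out_dir,
                                       paste0(stage, "_provenance.json")),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
}
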