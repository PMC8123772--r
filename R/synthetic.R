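BAND_EDGES <- list(theta = c(4, 8), alpha = c(8, 13),
                   beta = c(13, 30), gamma = c(30, 45))
BAND_NAMES <- names(BAND_EDGES)

#' Specification for the synthetic EEG generator
#'
#' Describes a two-class synthetic dataset: trial counts, sampling rate and
#' duration, per-class relative band-power profiles (theta, alpha, beta,
#' gamma fractions summing to 1), an optional per-channel gamma gain map
#' giving each class spatial structure, and a broadband noise floor.
#' Defaults emulate one-minute 32-channel trials at 512 Hz with a calm
#' class at gamma fraction 0.15 and a distress class at 0.45, the latter
#' frontally accentuated (negative stimuli elevate gamma, most visibly over
#' frontal sites).
#'
#' @param n_calm,n_distress Trials per class.
#' @param fs Sampling rate in Hz (>= 128).
#' @param duration Trial length in seconds (>= 30).
#' @param calm_profile,distress_profile Named numeric vectors
#'   (theta, alpha, beta, gamma) of relative band powers, each summing to 1.
#' @param distress_gamma_gain Named per-channel multipliers applied to the
#'   distress gamma fraction before per-channel renormalization; channels
#'   absent from the map keep gain 1.
#' @param noise_floor Fraction of total variance given to broadband white
#'   noise.
#' @param labels Channel labels (default: the packaged 32-channel montage).
#' @param seed Default RNG seed used by [generate_dataset()].
#' @return A `synthetic_spec` list, validated.
#' @export
synthetic_spec <- function(n_calm = 137, n_distress = 122,
                           fs = 512, duration = 60,
                           calm_profile = c(theta = 0.30, alpha = 0.35,
                                            beta = 0.20, gamma = 0.15),
                           distress_profile = c(theta = 0.15, alpha = 0.20,
                                                beta = 0.20, gamma = 0.45),
                           distress_gamma_gain = default_frontal_gain(),
                           noise_floor = 0.05,
                           labels = montage_channels(),
                           seed = 1L) {
  spec <- structure(list(
    n_calm = as.integer(n_calm), n_distress = as.integer(n_distress),
    fs = fs, duration = duration,
    profiles = list(calm = calm_profile, distress = distress_profile),
    gamma_gain = list(calm = NULL, distress = distress_gamma_gain),
    noise_floor = noise_floor, labels = labels, seed = as.integer(seed)),
    class = "synthetic_spec")
  validate_synthetic_spec(spec)
  spec
}

default_frontal_gain <- function(gain = 2.5) {
  frontal <- c("Fp1", "Fp2", "AF3", "AF4", "F3", "F4", "F7", "F8", "Fz",
               "FC1", "FC2", "FC5", "FC6")
  setNames(rep(gain, length(frontal)), frontal)
}

validate_synthetic_spec <- function(spec) {
  for (cl in c("calm", "distress")) {
    p <- spec$profiles[[cl]]
    if (!all(BAND_NAMES %in% names(p))) {
      abort(paste0(cl, " profile must name bands ",
                   paste(BAND_NAMES, collapse = ", ")))
    }
    if (any(p < 0)) abort(paste0(cl, " profile has negative fractions"))
    if (abs(sum(p[BAND_NAMES]) - 1) > 1e-9) {
      abort(paste0(cl, " profile fractions must sum to 1"))
    }
  }
  if (spec$fs < 128) abort("fs must be at least 128 Hz")
  if (spec$duration < 30) abort("duration must be at least 30 s")
  if (spec$noise_floor < 0 || spec$noise_floor >= 1) {
    abort("noise_floor must lie in [0, 1)")
  }
  if (spec$n_calm < 0 || spec$n_distress < 0) {
    abort("trial counts must be non-negative")
  }
  invisible(spec)
}

#' Effective per-channel band-power targets of a synthetic class
#'
#' Applies the class gamma gain map to the class profile and renormalizes
#' per channel, yielding the relative band powers each channel is generated
#' with.
#'
#' @param spec A `synthetic_spec`.
#' @param class `"calm"` or `"distress"`.
#' @return A tibble: `label`, `theta`, `alpha`, `beta`, `gamma`.
#' @export
band_targets <- function(spec, class) {
  profile <- spec$profiles[[class]]
  gain_map <- spec$gamma_gain[[class]]
  rows <- lapply(spec$labels, function(lab) {
    p <- profile[BAND_NAMES]
    g <- 1
    if (!is.null(gain_map) && lab %in% names(gain_map)) g <- gain_map[[lab]]
    p["gamma"] <- p["gamma"] * g
    p / sum(p)
  })
  out <- as_tibble(do.call(rbind, rows))
  dplyr::bind_cols(tibble(label = spec$labels), out)
}

band_mask <- function(n, fs, lo, hi, closed_upper) {
  k <- 0:(n - 1)
  fr <- pmin(k, n - k) * fs / n
  if (closed_upper) fr >= lo & fr <= hi else fr >= lo & fr < hi
}

# One channel: white noise split into exact in-band components by
# zero-phase spectral masking, each scaled to its target variance fraction.
synth_channel <- function(n, fs, fractions, noise_floor, total_var = 100) {
  x <- rnorm(n)
  X <- fft(x)
  sig <- numeric(n)
  for (b in BAND_NAMES) {
    e <- BAND_EDGES[[b]]
    m <- band_mask(n, fs, e[1], e[2], closed_upper = identical(b, "gamma"))
    comp <- Re(fft(X * m, inverse = TRUE)) / n
    v <- var(comp)
    if (v > 0) {
      target <- fractions[[b]] * (1 - noise_floor) * total_var
      sig <- sig + comp * sqrt(target / v)
    }
  }
  sig + rnorm(n, sd = sqrt(noise_floor * total_var))
}

sample_ratings <- function(class) {
  if (class == "calm") {
    c(valence = runif(1, 4, 6), arousal = runif(1, 1, 4 - 1e-6))
  } else {
    c(valence = runif(1, 1, 3 - 1e-6), arousal = runif(1, 5 + 1e-6, 9))
  }
}

#' Generate one synthetic EEG trial
#'
#' Each channel is a sum of band-limited Gaussian noise components, one per
#' band, scaled so the variance fractions match the class's per-channel
#' band targets, plus a broadband white-noise floor. Valence and arousal
#' ratings are drawn from the class's region of the rating plane, so
#' [label_trial()] reproduces the class by construction.
#'
#' @param spec A `synthetic_spec`.
#' @param class `"calm"` or `"distress"`.
#' @param participant_id,trial_id Identifiers recorded in the metadata.
#' @param seed Optional seed; when given, the trial is reproducible in
#'   isolation.
#' @return A list with `recording` (an [eeg_recording()]) and `meta` (a
#'   one-row tibble: participant_id, trial_id, valence, arousal, label).
#' @export
generate_trial <- function(spec, class, participant_id = 1L, trial_id = 1L,
                           seed = NULL) {
  validate_synthetic_spec(spec)
  if (!class %in% c("calm", "distress")) {
    abort("class must be 'calm' or 'distress'")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- round(spec$duration * spec$fs)
  targets <- band_targets(spec, class)
  samples <- matrix(0, nrow = length(spec$labels), ncol = n)
  for (i in seq_along(spec$labels)) {
    fr <- as.list(targets[i, BAND_NAMES])
    samples[i, ] <- synth_channel(n, spec$fs, fr, spec$noise_floor)
  }
  ratings <- sample_ratings(class)
  rec <- eeg_recording(samples, fs = spec$fs, labels = spec$labels,
                       history = sprintf("synthetic(%s)", class))
  meta <- tibble(participant_id = as.integer(participant_id),
                 trial_id = as.integer(trial_id),
                 valence = unname(ratings["valence"]),
                 arousal = unname(ratings["arousal"]),
                 label = class)
  list(recording = rec, meta = meta)
}

#' Generate a labeled synthetic dataset
#'
#' @param spec A `synthetic_spec`.
#' @param seed Master seed; defaults to `spec$seed`.
#' @return A list with `trials` (list of `eeg_recording`) and `metadata`
#'   (tibble, one row per trial in generation order).
#' @export
generate_dataset <- function(spec, seed = spec$seed) {
  validate_synthetic_spec(spec)
  set.seed(seed)
  classes <- c(rep("calm", spec$n_calm), rep("distress", spec$n_distress))
  trials <- vector("list", length(classes))
  metas <- vector("list", length(classes))
  for (i in seq_along(classes)) {
    tr <- generate_trial(spec, classes[i], participant_id = 1L,
                         trial_id = i)
    trials[[i]] <- tr$recording
    metas[[i]] <- tr$meta
  }
  metadata <- if (length(metas) > 0) dplyr::bind_rows(metas) else
    tibble(participant_id = integer(), trial_id = integer(),
           valence = numeric(), arousal = numeric(), label = character())
  list(trials = trials, metadata = metadata)
}

#' Write a synthetic dataset to disk
#'
#' One delimited matrix file (plus JSON sidecar) per trial and a CSV
#' metadata manifest.
#'
#' @param dataset Result of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return The manifest tibble (with a `file` column), invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(dataset$trials))
  for (i in seq_along(dataset$trials)) {
    files[i] <- file.path(dir, sprintf("trial_%04d.tsv", i))
    write_eeg_matrix(dataset$trials[[i]], files[i])
  }
  manifest <- dplyr::mutate(dataset$metadata, file = files)
  readr::write_csv(manifest, file.path(dir, "metadata.csv"))
  invisible(manifest)
}
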