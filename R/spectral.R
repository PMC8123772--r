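#' Welch power spectral density of an epoch
#'
#' Averaged modified periodogram: Hamming windows of `window_seconds`
#' (2 s, i.e. 256 samples at 128 Hz), 50% overlap between adjacent
#' windows and an `n_points`-point transform, giving a 0.5 Hz grid at the
#' canonical analysis rate. Density scaling (power per Hz) with window
#' power compensation; one-sided spectrum.
#'
#' @param epoch An `eeg_epoch` (or `eeg_recording`).
#' @param window_seconds Segment length in seconds.
#' @param overlap Fractional overlap between adjacent segments.
#' @param n_points Transform length (segment length must not exceed it).
#' @return A `psd_estimate`: list with `freqs` (Hz, ascending), `values`
#'   (channels x frequencies, non-negative), `labels`, `params`.
#' @export
welch_psd <- function(epoch, window_seconds = 2, overlap = 0.5,
                      n_points = 256) {
  fs <- epoch$fs
  x <- epoch$samples
  seg <- round(window_seconds * fs)
  if (ncol(x) < seg) {
    abort(sprintf("epoch (%d samples) shorter than one %d-sample window",
                  ncol(x), seg))
  }
  if (seg > n_points) abort("window longer than the transform length")
  step <- max(1L, round(seg * (1 - overlap)))
  starts <- seq(1L, ncol(x) - seg + 1L, by = step)
  w <- signal::hamming(seg)
  u <- sum(w^2)
  nf <- n_points %/% 2 + 1
  freqs <- (0:(nf - 1)) * fs / n_points
  one_sided <- rep(2, nf)
  one_sided[1] <- 1
  if (n_points %% 2 == 0) one_sided[nf] <- 1
  values <- matrix(0, nrow = nrow(x), ncol = nf)
  for (i in seq_len(nrow(x))) {
    acc <- numeric(nf)
    for (s in starts) {
      segd <- c(x[i, s:(s + seg - 1L)] * w, numeric(n_points - seg))
      X <- fft(segd)[seq_len(nf)]
      acc <- acc + (Mod(X)^2) / (fs * u)
    }
    values[i, ] <- one_sided * acc / length(starts)
  }
  structure(list(freqs = freqs, values = values, labels = epoch$labels,
                 params = list(window_seconds = window_seconds,
                               overlap = overlap, n_points = n_points,
                               n_segments = length(starts), fs = fs)),
            class = "psd_estimate")
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf("<psd_estimate> %d channels, %d bins (%.2g-%g Hz, step %g Hz), %d segments\n",
              nrow(x$values), length(x$freqs), min(x$freqs), max(x$freqs),
              x$freqs[2] - x$freqs[1], x$params$n_segments))
  invisible(x)
}

band_bins <- function(freqs) {
  list(total = which(freqs >= 4 & freqs <= 45),
       theta = which(freqs >= 4 & freqs < 8),
       alpha = which(freqs >= 8 & freqs < 13),
       beta  = which(freqs >= 13 & freqs < 30),
       gamma = which(freqs >= 30 & freqs <= 45))
}

#' Absolute and normalized band powers from a PSD
#'
#' Sums the PSD bins over the whole 4-45 Hz band (`pt`, absolute) and the
#' theta, alpha, beta and gamma sub-bands, each sub-band normalized by
#' `pt`. The sub-bands partition 4-45 Hz half-open ([4,8), [8,13),
#' [13,30), [30,45]), so the four normalized powers sum to exactly 1.
#'
#' @param psd A `psd_estimate` whose grid covers 4-45 Hz.
#' @return A tibble, one row per channel: `label`, `pt`, `theta`, `alpha`,
#'   `beta`, `gamma`.
#' @export
band_powers <- function(psd) {
  if (min(psd$freqs) > 4 || max(psd$freqs) < 45) {
    abort("PSD grid must cover 4-45 Hz")
  }
  bins <- band_bins(psd$freqs)
  pt <- rowSums(psd$values[, bins$total, drop = FALSE])
  zero <- which(pt <= 0)
  if (length(zero) > 0) {
    abort(paste0("total band power is zero for channel(s): ",
                 paste(psd$labels[zero], collapse = ", ")))
  }
  tibble(
    label = psd$labels,
    pt = pt,
    theta = rowSums(psd$values[, bins$theta, drop = FALSE]) / pt,
    alpha = rowSums(psd$values[, bins$alpha, drop = FALSE]) / pt,
    beta  = rowSums(psd$values[, bins$beta, drop = FALSE]) / pt,
    gamma = rowSums(psd$values[, bins$gamma, drop = FALSE]) / pt)
}

#' Band powers for a batch of epochs
#'
#' Maps [welch_psd()] then [band_powers()] over epochs, preserving order.
#' Failures are re-raised naming the offending trial and epoch.
#'
#' @param epochs A list of `eeg_epoch` objects.
#' @param ... Passed to [welch_psd()].
#' @return A tibble with one row per (epoch, channel): `trial_id`,
#'   `epoch_idx`, `class`, then the [band_powers()] columns.
#' @export
batch_band_powers <- function(epochs, ...) {
  if (length(epochs) == 0) {
    return(tibble(trial_id = integer(), epoch_idx = integer(),
                  class = character(), label = character(), pt = numeric(),
                  theta = numeric(), alpha = numeric(), beta = numeric(),
                  gamma = numeric()))
  }
  purrr::map_dfr(epochs, function(ep) {
    bp <- tryCatch(band_powers(welch_psd(ep, ...)), error = function(e) {
      abort(sprintf("band-power failure at trial %s, epoch %s: %s",
                    as.character(ep$trial_id), as.character(ep$epoch_idx),
                    conditionMessage(e)))
    })
    dplyr::bind_cols(
      tibble(trial_id = rep(as.integer(ep$trial_id), nrow(bp)),
             epoch_idx = rep(as.integer(ep$epoch_idx), nrow(bp)),
             class = rep(as.character(ep$label), nrow(bp))),
      bp)
  })
}

#' Write a band-power table as delimited text
#'
#' @param bp Tibble from [batch_band_powers()].
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_band_powers <- function(bp, path) {
  readr::write_tsv(bp, path)
  invisible(path)
}
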