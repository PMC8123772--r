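#' Downsample an EEG recording
#'
#' Anti-aliased rational rate conversion of every channel: zero-stuffing
#' upsampling where the ratio requires it, a zero-phase (forward/backward)
#' FIR anti-aliasing low-pass with exactly unit DC gain, then decimation.
#' Upsampling above the input rate is not supported; converting 512 Hz
#' trials to the 128 Hz analysis rate is an exact 1/4 decimation.
#'
#' @param rec An `eeg_recording`.
#' @param fs_out Target sampling rate in Hz (must divide into `fs` as a
#'   rational ratio and not exceed it).
#' @return The resampled `eeg_recording`.
#' @export
eeg_resample <- function(rec, fs_out = 128) {
  if (fs_out > rec$fs) abort("upsampling is not supported")
  if (fs_out == rec$fs) {
    return(append_history(rec, sprintf("resample(%g Hz, identity)", fs_out)))
  }
  ratio <- fs_out / rec$fs
  frac <- best_rational(ratio)
  p <- frac[1]; q <- frac[2]
  ntaps <- 16L * max(p, q)
  if (ntaps %% 2L == 1L) ntaps <- ntaps + 1L
  h <- signal::fir1(ntaps, 0.95 / max(p, q))
  h <- h / sum(h)
  n_out <- round(ncol(rec$samples) * ratio)
  out <- matrix(0, nrow = nrow(rec$samples), ncol = n_out)
  for (i in seq_len(nrow(rec$samples))) {
    x <- rec$samples[i, ]
    if (p > 1) {
      up <- numeric(length(x) * p)
      up[seq(1L, length(up), by = p)] <- x
      x <- up * p
    }
    y <- signal::filtfilt(h, x)
    y <- y[seq(1L, length(y), by = q)]
    out[i, ] <- y[seq_len(n_out)]
  }
  rec$samples <- out
  rec$fs <- fs_out
  append_history(rec, sprintf("resample(%g Hz)", fs_out))
}

best_rational <- function(x, max_den = 4096) {
  for (q in seq_len(max_den)) {
    p <- x * q
    if (abs(p - round(p)) < 1e-9) return(c(round(p), q))
  }
  abort("sampling-rate ratio is not rational within tolerance")
}

#' Re-reference to the channel average
#'
#' Subtracts the instantaneous mean over channels from every channel, so
#' the cross-channel mean of the output is zero at every sample.
#'
#' @param rec An `eeg_recording` with at least two channels.
#' @return The re-referenced `eeg_recording`.
#' @export
eeg_average_reference <- function(rec) {
  if (nrow(rec$samples) < 2) {
    abort("average reference requires at least two channels")
  }
  rec$samples <- sweep(rec$samples, 2, colMeans(rec$samples))
  append_history(rec, "average_reference")
}

#' Zero-phase band-pass filter
#'
#' Butterworth high-pass and low-pass filters applied forward/backward
#' (zero phase), the standard EEG practice behind "forward/backward
#' filters". Each pass is 4th order by default; the two-pass magnitude is
#' -6 dB at the cut-offs.
#'
#' @param rec An `eeg_recording`.
#' @param low,high Cut-off frequencies in Hz (0 < low < high < fs/2).
#' @param order Butterworth order per pass.
#' @return The filtered `eeg_recording`.
#' @export
eeg_bandpass <- function(rec, low = 3, high = 45, order = 4) {
  nyq <- rec$fs / 2
  if (!(low > 0 && low < high && high < nyq)) {
    abort("cut-offs must satisfy 0 < low < high < fs/2")
  }
  hp <- signal::butter(order, low / nyq, type = "high")
  lp <- signal::butter(order, high / nyq, type = "low")
  for (i in seq_len(nrow(rec$samples))) {
    y <- signal::filtfilt(hp, rec$samples[i, ])
    rec$samples[i, ] <- signal::filtfilt(lp, y)
  }
  append_history(rec, sprintf("bandpass(%g-%g Hz, order %d, zero-phase)",
                              low, high, order))
}

#' Keep the trailing segment of a recording
#'
#' @param rec An `eeg_recording` at least `seconds` long.
#' @param seconds Window length to keep, from the end.
#' @return The trailing `seconds` of the recording.
#' @export
eeg_last_segment <- function(rec, seconds = 30) {
  n <- round(seconds * rec$fs)
  if (ncol(rec$samples) < n) {
    abort(sprintf("recording is %.2f s, shorter than the requested %g s",
                  eeg_duration(rec), seconds))
  }
  rec$samples <- rec$samples[, (ncol(rec$samples) - n + 1):ncol(rec$samples),
                             drop = FALSE]
  append_history(rec, sprintf("last_segment(%g s)", seconds))
}

#' Split a 30 s recording into six 5 s epochs
#'
#' @param rec An `eeg_recording` whose length is an exact multiple of
#'   `epoch_seconds` (the canonical use is 30 s into six epochs).
#' @param epoch_seconds Epoch length in seconds.
#' @param trial_id,label Carried into each epoch for bookkeeping.
#' @return A list of `eeg_epoch` objects (channels x (epoch_seconds * fs)
#'   matrices with `trial_id`, `epoch_idx`, `label` fields).
#' @export
eeg_epochs <- function(rec, epoch_seconds = 5, trial_id = NA_integer_,
                       label = NA_character_) {
  len <- round(epoch_seconds * rec$fs)
  n <- ncol(rec$samples)
  if (n %% len != 0) {
    abort(sprintf("recording length (%d samples) is not a multiple of the %g s epoch",
                  n, epoch_seconds))
  }
  k <- n %/% len
  lapply(seq_len(k), function(i) {
    structure(list(
      samples = rec$samples[, ((i - 1) * len + 1):(i * len), drop = FALSE],
      fs = rec$fs, labels = rec$labels,
      trial_id = trial_id, epoch_idx = i, label = label),
      class = "eeg_epoch")
  })
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf("<eeg_epoch> trial %s, epoch %d: %d ch x %d samples @ %g Hz\n",
              as.character(x$trial_id), x$epoch_idx, nrow(x$samples),
              ncol(x$samples), x$fs))
  invisible(x)
}

#' Run the full preprocessing chain on one trial
#'
#' Applies, in order: downsampling to `fs_out`, average re-referencing,
#' zero-phase band-pass filtering, an artifact-rejection hook (identity by
#' default; slot for an ICA-style cleaner), trailing-window selection, and
#' epoch splitting.
#'
#' @param rec An `eeg_recording`.
#' @param fs_out Analysis sampling rate (Hz).
#' @param low,high Band-pass cut-offs (Hz).
#' @param keep_seconds Trailing window retained for analysis (s).
#' @param epoch_seconds Epoch length (s).
#' @param artifact_hook Function `eeg_recording -> eeg_recording` applied
#'   after filtering; default passes the recording through unchanged.
#' @param trial_id,label Bookkeeping carried into the epochs.
#' @return A list of `eeg_epoch` objects.
#' @export
preprocess_trial <- function(rec, fs_out = 128, low = 3, high = 45,
                             keep_seconds = 30, epoch_seconds = 5,
                             artifact_hook = identity,
                             trial_id = NA_integer_, label = NA_character_) {
  rec <- eeg_resample(rec, fs_out)
  rec <- eeg_average_reference(rec)
  rec <- eeg_bandpass(rec, low, high)
  rec <- artifact_hook(rec)
  rec <- eeg_last_segment(rec, keep_seconds)
  eeg_epochs(rec, epoch_seconds, trial_id = trial_id, label = label)
}
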