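# Shared fixtures, built in code. Values are kept small so the whole suite
# stays fast; heavier end-to-end runs live in test-acceptance.R.

fixture_montage <- standard_1020_montage()

named_values <- function(seed = 1, labels = fixture_montage$label) {
  set.seed(seed)
  setNames(runif(length(labels)), labels)
}

# Sinusoid recording helper.
sine_recording <- function(freq, fs, seconds, channels = 1, amp = 1) {
  t <- seq(0, seconds - 1 / fs, by = 1 / fs)
  eeg_recording(matrix(rep(amp * sin(2 * pi * freq * t), channels),
                       nrow = channels, byrow = TRUE),
                fs = fs, labels = paste0("ch", seq_len(channels)))
}

# A flat PSD object on the canonical 0.5 Hz grid.
flat_psd <- function(value = 1, fs = 128, n_points = 256) {
  freqs <- (0:(n_points / 2)) * fs / n_points
  structure(list(freqs = freqs,
                 values = matrix(value, 1, length(freqs)),
                 labels = "X1",
                 params = list(window_seconds = 2, overlap = 0.5,
                               n_points = n_points, fs = fs)),
            class = "psd_estimate")
}

random_psd <- function(n_channels = 4, fs = 128, n_points = 256) {
  freqs <- (0:(n_points / 2)) * fs / n_points
  structure(list(freqs = freqs,
                 values = matrix(runif(n_channels * length(freqs), 0.01, 2),
                                 n_channels, length(freqs)),
                 labels = paste0("X", seq_len(n_channels)),
                 params = list()),
            class = "psd_estimate")
}

# Mann-Whitney AUC of scores (positive class higher).
auc_score <- function(pos, neg) {
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}
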