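#' Construct an EEG recording
#'
#' A light container for a multichannel signal: a channels-by-samples
#' numeric matrix (microvolts), its sampling rate, ordered channel labels
#' and an append-only processing history.
#'
#' @param samples Numeric matrix, channels x samples.
#' @param fs Sampling rate in Hz (> 0).
#' @param labels Character vector of channel names, one per row.
#' @param history Character vector of already-applied processing steps.
#' @return An `eeg_recording` object.
#' @export
eeg_recording <- function(samples, fs, labels, history = character()) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples)) abort("samples must be numeric")
  if (length(labels) != nrow(samples)) {
    abort("label count must equal the number of channel rows")
  }
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    abort("fs must be a single positive number")
  }
  structure(list(samples = samples, fs = fs,
                 labels = as.character(labels),
                 history = as.character(history)),
            class = "eeg_recording")
}

append_history <- function(rec, step) {
  rec$history <- c(rec$history, step)
  rec
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs))
  if (length(x$history) > 0) {
    cat("  history:", paste(x$history, collapse = " -> "), "\n")
  }
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec An `eeg_recording`.
#' @return Length in seconds.
#' @export
eeg_duration <- function(rec) ncol(rec$samples) / rec$fs

#' Write an EEG recording as delimited text plus a JSON sidecar
#'
#' The matrix (channels x samples) goes to `path` as tab-separated values
#' without headers; sampling rate, channel labels and processing history go
#' to `<path>.json`.
#'
#' @param rec An `eeg_recording`.
#' @param path Output path for the signal matrix.
#' @return `path`, invisibly.
#' @export
write_eeg_matrix <- function(rec, path) {
  utils::write.table(rec$samples, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  sidecar <- list(fs = rec$fs, labels = rec$labels, history = rec$history)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an EEG recording written by [write_eeg_matrix()]
#'
#' @param path Path to the delimited signal matrix; `<path>.json` must hold
#'   the sampling rate and labels.
#' @return An `eeg_recording`.
#' @export
read_eeg_matrix <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path)) {
    abort(paste0("sidecar not found: ", sidecar_path))
  }
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  mat <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(mat) <- NULL
  eeg_recording(mat, fs = meta$fs, labels = meta$labels,
                history = meta$history %||% character())
}
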