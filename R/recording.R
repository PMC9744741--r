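#' EEG recording container
#'
#' One subject-by-condition multichannel time series. `data` is channels x
#' samples in microvolts; channel order follows `labels`.
#'
#' @param data Numeric matrix, channels x samples.
#' @param fs Sampling rate (Hz).
#' @param labels Unique channel labels.
#' @param condition `"eyes_open"` or `"eyes_closed"`.
#' @param impedances Per-channel end-of-session impedance (kOhm).
#' @return Object of class `eeg_recording`.
#' @export
new_recording <- function(data, fs, labels = rownames(data),
                          condition = c("eyes_open", "eyes_closed"),
                          impedances = NULL) {
  condition <- match.arg(condition)
  data <- as.matrix(data)
  if (is.null(labels)) labels <- sprintf("E%03d", seq_len(nrow(data)))
  if (anyDuplicated(labels)) stopf("new_recording: channel labels must be unique")
  if (length(labels) != nrow(data)) stopf("new_recording: labels/data mismatch")
  if (!is.numeric(fs) || fs <= 0) stopf("new_recording: fs must be > 0")
  if (is.null(impedances)) impedances <- rep(10, nrow(data))
  if (any(impedances < 0)) stopf("new_recording: impedances must be >= 0")
  rownames(data) <- labels
  structure(list(data = data, fs = fs, labels = labels,
                 condition = condition, impedances = impedances),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d ch x %d samples @ %g Hz [%s], %.1f s\n",
              nrow(x$data), ncol(x$data), x$fs, x$condition, ncol(x$data) / x$fs))
  invisible(x)
}

#' Write/read a recording as flat binary with a JSON sidecar
#'
#' Samples are stored as little-endian float64, channel-major (all samples
#' of channel 1, then channel 2, ...). The `.json` sidecar documents labels,
#' sampling rate, condition, impedances and the matrix shape.
#'
#' @param rec An `eeg_recording`.
#' @param path Path of the binary file; the sidecar is `<path>.json`.
#' @rdname recording_io
#' @export
write_recording <- function(rec, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(t(rec$data)), con, size = 8, endian = "little")
  meta <- list(labels = rec$labels, fs = rec$fs, condition = rec$condition,
               impedances = rec$impedances, n_channels = nrow(rec$data),
               n_samples = ncol(rec$data), dtype = "float64le",
               order = "channel_major", units = "uV")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname recording_io
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = meta$n_channels * meta$n_samples,
               size = 8, endian = "little")
  data <- t(matrix(v, nrow = meta$n_samples, ncol = meta$n_channels))
  new_recording(data, meta$fs, meta$labels, meta$condition, meta$impedances)
}
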