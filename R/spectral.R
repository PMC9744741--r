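#' Welch power spectral density
#'
#' Welch's overlapped segment averaging estimator with a Hamming taper and
#' 50% overlap. The segment length is `fs / resolution` samples, so the
#' frequency grid spacing equals `resolution` exactly. Power is returned in
#' density units (uV^2/Hz): each segment periodogram is scaled by
#' `1 / (fs * sum(w^2))` and one-sided bins (excluding DC and Nyquist) are
#' doubled.
#'
#' @param rec An `eeg_recording`.
#' @param resolution Frequency resolution (Hz).
#' @param overlap Fractional segment overlap (default 0.5).
#' @return Object of class `eeg_spectrum`: list with `freqs` (Hz), `power`
#'   (channels x freqs, uV^2/Hz), `fs`, `condition`.
#' @export
welch_psd <- function(rec, resolution = 0.5, overlap = 0.5) {
  stopifnot(inherits(rec, "eeg_recording"))
  seg <- rec$fs / resolution
  if (abs(seg - round(seg)) > 1e-9) {
    stopf("welch_psd: fs / resolution must be an integer segment length")
  }
  seg <- as.integer(round(seg))
  n <- ncol(rec$data)
  if (n < 2L * seg) stopf("welch_psd: recording shorter than two segments (need %d samples)", 2L * seg)
  step <- max(1L, as.integer(round(seg * (1 - overlap))))
  starts <- seq(1L, n - seg + 1L, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(seg - 1L)) / (seg - 1L))
  u <- sum(w^2)
  C <- nrow(rec$data)
  X <- t(rec$data)
  # all segments of all channels as columns of one matrix (channel-major)
  idx <- as.vector(outer(0:(seg - 1L), starts, `+`))
  nsegs <- length(starts)
  acc <- matrix(0, seg %/% 2L + 1L, C)
  Y <- matrix(X[idx, ], seg, nsegs * C) * w
  Fm <- mvfft_real(Y)
  P <- abs(Fm[seq_len(seg %/% 2L + 1L), , drop = FALSE])^2 / (rec$fs * u)
  for (ch in seq_len(C)) {
    acc[, ch] <- rowMeans(P[, ((ch - 1L) * nsegs + 1L):(ch * nsegs), drop = FALSE])
  }
  acc[2:(seg %/% 2L), ] <- 2 * acc[2:(seg %/% 2L), ]
  freqs <- seq(0, rec$fs / 2, by = resolution)
  power <- t(acc)
  rownames(power) <- rec$labels
  structure(list(freqs = freqs, power = power, fs = rec$fs,
                 condition = rec$condition, labels = rec$labels),
            class = "eeg_spectrum")
}

#' @export
print.eeg_spectrum <- function(x, ...) {
  cat(sprintf("<eeg_spectrum> %d ch x %d bins, %g-%g Hz (step %g) [%s]\n",
              nrow(x$power), length(x$freqs), min(x$freqs), max(x$freqs),
              x$freqs[2] - x$freqs[1], x$condition))
  invisible(x)
}

#' Canonical frequency bands
#'
#' delta 1-3, theta 3.5-7, alpha 7.5-12, beta 12.5-32, gamma 32.5-45 Hz.
#'
#' @return Data frame with columns `name`, `lo`, `hi`.
#' @export
default_bands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta", "gamma"),
             lo = c(1, 3.5, 7.5, 12.5, 32.5),
             hi = c(3, 7, 12, 32, 45),
             stringsAsFactors = FALSE)
}

#' Relative band power
#'
#' Per channel, the trapezoidal integral of the PSD over each band divided
#' by the trapezoidal integral over the normalization range, giving
#' dimensionless fractions in [0, 1].
#'
#' @param spectrum An `eeg_spectrum`.
#' @param bands Data frame with `name`, `lo`, `hi` (default [default_bands()]).
#' @param norm_range Normalization interval (Hz), default 1-45.
#' @return Object of class `band_power_map`: channels x bands matrix of
#'   fractions, with the condition tag as attribute.
#' @export
relative_power <- function(spectrum, bands = default_bands(),
                           norm_range = c(1, 45)) {
  stopifnot(inherits(spectrum, "eeg_spectrum"))
  f <- spectrum$freqs
  if (norm_range[1] < min(f) || norm_range[2] > max(f)) {
    stopf("relative_power: normalization range outside the spectrum grid")
  }
  in_rng <- function(lo, hi) {
    if (lo < min(f) || hi > max(f)) stopf("relative_power: band %g-%g outside the spectrum grid", lo, hi)
    which(f >= lo - 1e-9 & f <= hi + 1e-9)
  }
  ni <- in_rng(norm_range[1], norm_range[2])
  denom <- trapz_rows(f[ni], spectrum$power[, ni, drop = FALSE])
  out <- sapply(seq_len(nrow(bands)), function(b) {
    bi <- in_rng(bands$lo[b], bands$hi[b])
    trapz_rows(f[bi], spectrum$power[, bi, drop = FALSE]) / denom
  })
  out <- matrix(out, nrow = nrow(spectrum$power),
                dimnames = list(rownames(spectrum$power), bands$name))
  structure(out, condition = spectrum$condition, class = c("band_power_map", "matrix"))
}

#' Individual alpha frequency detection
#'
#' Averages the PSD over the montage's occipital channels and takes the
#' frequency of the maximum in `[search_lo, search_hi]`. The detection is
#' accepted as a true peak (`is_true_peak`) only when the maximum is a
#' strict local maximum of the occipital-average spectrum (greater than
#' both adjacent bins) and not a boundary bin of the search range; flagged
#' detections are meant for exclusion rather than guessing.
#'
#' @param spectrum Eyes-closed `eeg_spectrum`.
#' @param montage An `eeg_montage` with occipital channels.
#' @param search_lo,search_hi Search range (Hz).
#' @return Object of class `iaf_result`: list with `iaf` (Hz),
#'   `is_true_peak`, and the occipital-average spectrum used.
#' @export
detect_iaf <- function(spectrum, montage, search_lo = 7, search_hi = 13) {
  stopifnot(inherits(spectrum, "eeg_spectrum"), inherits(montage, "eeg_montage"))
  occ <- montage$labels[montage$regions == "occipital"]
  occ <- intersect(occ, rownames(spectrum$power))
  if (!length(occ)) stopf("detect_iaf: montage has no occipital channels")
  avg <- colMeans(spectrum$power[occ, , drop = FALSE])
  f <- spectrum$freqs
  rng <- which(f >= search_lo - 1e-9 & f <= search_hi + 1e-9)
  k <- rng[which.max(avg[rng])]
  at_boundary <- k == rng[1] || k == rng[length(rng)]
  strict_local <- k > 1L && k < length(f) && avg[k] > avg[k - 1L] && avg[k] > avg[k + 1L]
  structure(list(iaf = f[k], is_true_peak = !at_boundary && strict_local,
                 occipital_mean = stats::setNames(avg, f),
                 search = c(search_lo, search_hi)),
            class = "iaf_result")
}

#' @export
print.iaf_result <- function(x, ...) {
  cat(sprintf("<iaf_result> IAF = %g Hz (%s)\n", x$iaf,
              if (x$is_true_peak) "true peak" else "boundary/non-peak, flag for exclusion"))
  invisible(x)
}

#' Alpha reactivity index
#'
#' Ratio of global (channel-mean) alpha relative power between the eyes
#' open and eyes closed conditions (eyes open / eyes closed by default; the
#' orientation is reported with the value).
#'
#' @param map_eo,map_ec `band_power_map`s for the two conditions.
#' @param orientation `"eo_over_ec"` (default) or `"ec_over_eo"`.
#' @return Named scalar ratio with attribute `"orientation"`.
#' @export
alpha_reactivity <- function(map_eo, map_ec, orientation = c("eo_over_ec", "ec_over_eo")) {
  orientation <- match.arg(orientation)
  a_eo <- mean(map_eo[, "alpha"])
  a_ec <- mean(map_ec[, "alpha"])
  if (a_ec <= 0 || a_eo <= 0) stopf("alpha_reactivity: nonpositive alpha power")
  v <- if (orientation == "eo_over_ec") a_eo / a_ec else a_ec / a_eo
  structure(v, orientation = orientation)
}
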