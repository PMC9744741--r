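#' Alpha-band amplitude envelope
#'
#' Zero-phase FIR band-pass of the stated order followed by the analytic
#' signal magnitude (FFT Hilbert method), per channel. The filter is
#' applied circularly in the frequency domain with its zero-phase
#' (symmetric-kernel) amplitude response, so edge effects are confined to
#' about half the filter order per side; the attribute `"trim"` records how
#' many samples to drop at each edge before scaling analyses.
#'
#' @param rec An `eeg_recording`.
#' @param band Numeric `c(lo, hi)` in Hz (default alpha, 7.5-12).
#' @param order FIR order (default 66).
#' @return Object of class `envelope_series`: nonnegative matrix (channels
#'   x samples) with attributes `fs`, `band`, `trim`.
#' @export
amplitude_envelope <- function(rec, band = c(7.5, 12), order = 66) {
  stopifnot(inherits(rec, "eeg_recording"))
  n <- ncol(rec$data)
  if (order >= n) stopf("amplitude_envelope: filter order >= recording length")
  if (band[1] <= 0 || band[2] >= rec$fs / 2) stopf("amplitude_envelope: band outside (0, fs/2)")
  order <- as.integer(order)
  if (order %% 2L != 0L) order <- order + 1L
  h <- as.numeric(signal::fir1(order, band / (rec$fs / 2), type = "pass"))
  d <- order %/% 2L
  hpad <- c(h[(d + 1L):(order + 1L)], rep(0, n - order - 1L), h[1:d])
  A <- Re(fft(hpad))                       # zero-phase amplitude response
  mask <- analytic_mask(n)
  Fm <- mvfft_real(t(rec$data)) * (A * mask)
  env <- matrix(0, n, nrow(rec$data))
  for (ch in seq_len(ncol(env))) {
    env[, ch] <- Mod(fft(Fm[, ch], inverse = TRUE)) / n
  }
  structure(t(env), fs = rec$fs, band = band, trim = d,
            labels = rec$labels, class = c("envelope_series", "matrix"))
}

# Hilbert one-sided spectrum mask of length n.
analytic_mask <- function(n) {
  m <- numeric(n)
  if (n %% 2 == 0) {
    m[1] <- 1; m[n / 2 + 1] <- 1
    m[2:(n / 2)] <- 2
  } else {
    m[1] <- 1
    m[2:((n + 1) / 2)] <- 2
  }
  m
}

#' Detrended fluctuation analysis
#'
#' Computes the cumulative-sum profile of the mean-subtracted series,
#' splits it into windows of each (log-spaced) scale with the given
#' overlap, removes a least-squares polynomial trend of order
#' `detrend_order` (order 1, linear) per window, and pools the squared
#' residuals into the fluctuation function `F(s)`. The scaling exponent is
#' the ordinary least-squares slope of `log F(s)` versus `log s`. An
#' exponent of 0.5 indicates an uncorrelated (white-noise) signal; values
#' in (0.5, 1) indicate long-range temporal correlations.
#'
#' @param series Numeric vector, or matrix with one series per column.
#' @param scale_lo,scale_hi Window lengths in samples. `scale_hi` may not
#'   exceed a quarter of the series length; the default is an eighth of the
#'   length, which keeps enough windows at the largest scale for a stable
#'   fluctuation estimate.
#' @param n_scales Number of log-spaced scales.
#' @param overlap Fractional window overlap in [0, 1).
#' @param detrend_order Only order 1 (linear) is supported.
#' @return For a vector input, an object of class `dfa_result` with
#'   `scales`, `fluctuations`, `exponent`, `fit_rmse`; for a matrix, a list
#'   of one result per column.
#' @export
dfa <- function(series, scale_lo = 16, scale_hi = NULL, n_scales = 15,
                overlap = 0.5, detrend_order = 1) {
  if (detrend_order != 1) stopf("dfa: only linear (order-1) detrending is supported")
  X <- if (is.matrix(series)) series else matrix(series, ncol = 1L)
  n <- nrow(X)
  if (is.null(scale_hi)) scale_hi <- floor(n / 8)
  if (scale_hi > n / 4) stopf("dfa: scale_hi must not exceed a quarter of the series length")
  if (scale_lo < 4) stopf("dfa: scale_lo must be at least 4 samples")
  if (scale_lo >= scale_hi) stopf("dfa: need scale_lo < scale_hi")
  rng <- apply(X, 2, function(v) diff(range(v)))
  if (any(rng == 0)) stopf("dfa: constant series has zero fluctuations")
  scales <- unique(round(exp(seq(log(scale_lo), log(scale_hi), length.out = n_scales))))
  P <- apply(X, 2, function(v) cumsum(v - mean(v)))
  C <- ncol(X)
  Fmat <- matrix(0, length(scales), C)
  for (si in seq_along(scales)) {
    s <- scales[si]
    step <- max(1L, round(s * (1 - overlap)))
    starts <- seq(1L, n - s + 1L, by = step)
    k <- length(starts)
    idx <- as.vector(outer(seq_len(s) - 1L, starts, `+`))
    t1 <- seq_len(s)
    St <- sum(t1); Stt <- sum(t1^2)
    vt <- Stt - St^2 / s
    # all windows of all channels as columns; residual SS of y ~ 1 + t per
    # window in closed form
    W <- matrix(P[idx, ], s, k * C)
    Sy <- colSums(W)
    Syy <- colSums(W^2)
    Sty <- as.vector(crossprod(W, t1))
    ss <- Syy - Sy^2 / s - (Sty - Sy * St / s)^2 / vt
    dim(ss) <- c(k, C)
    Fmat[si, ] <- sqrt(colMeans(ss) / s)
  }
  out <- lapply(seq_len(C), function(ch) {
    lf <- log(Fmat[, ch]); ls <- log(scales)
    fit <- stats::lm.fit(cbind(1, ls), lf)
    structure(list(scales = scales, fluctuations = Fmat[, ch],
                   exponent = unname(fit$coefficients[2]),
                   fit_rmse = sqrt(mean(fit$residuals^2))),
              class = "dfa_result")
  })
  if (!is.matrix(series)) out[[1]] else out
}

#' @export
print.dfa_result <- function(x, ...) {
  cat(sprintf("<dfa_result> exponent = %.3f (%d scales %d-%d, fit RMSE %.3f)\n",
              x$exponent, length(x$scales), min(x$scales), max(x$scales), x$fit_rmse))
  invisible(x)
}

#' Default DFA scale range
#'
#' 1 s to 20 s at the series' sampling rate, with the upper scale capped at
#' a quarter of the series length.
#'
#' @param n Series length (samples).
#' @param fs Sampling rate (Hz).
#' @return `c(scale_lo, scale_hi)` in samples.
#' @export
dfa_default_scales <- function(n, fs) {
  c(max(4, round(fs)), min(round(20 * fs), floor(n / 4)))
}

#' Velocity-threshold fixation extraction
#'
#' Samples whose velocity exceeds `velocity_threshold` are marked saccade
#' (1), the rest fixation (0); runs shorter than the minimum durations are
#' merged into the surrounding state (short saccades first, then short
#' fixations).
#'
#' @param gaze A `gaze_recording` (or any list with `velocity`, `fs_gaze`).
#' @param velocity_threshold Threshold in deg/s.
#' @param min_fix_ms,min_sacc_ms Minimum run durations (ms).
#' @return Object of class `fixation_series`: list with `states` (0/1),
#'   `fs`, `n_fixations`.
#' @export
extract_fixations <- function(gaze, velocity_threshold = 30,
                              min_fix_ms = 50, min_sacc_ms = 10) {
  v <- gaze$velocity
  if (!length(v)) stopf("extract_fixations: empty velocity trace")
  fs <- gaze$fs_gaze
  states <- as.integer(v > velocity_threshold)
  states <- merge_short_runs(states, 1L, round(min_sacc_ms / 1000 * fs))
  states <- merge_short_runs(states, 0L, round(min_fix_ms / 1000 * fs))
  r <- rle(states)
  structure(list(states = states, fs = fs, n_fixations = sum(r$values == 0L)),
            class = "fixation_series")
}

merge_short_runs <- function(states, value, min_len) {
  if (min_len <= 1L) return(states)
  r <- rle(states)
  short <- r$values == value & r$lengths < min_len
  # interior short runs flip to the surrounding state; edge runs flip to
  # their single neighbor
  if (any(short)) {
    r$values[short] <- 1L - value
    states <- inverse.rle(r)
  }
  states
}

#' DFA of a binary fixation series
#'
#' Applies [dfa()] to the 0/1 fixation-state sequence. The default scale
#' range is 2 s to 100 s at the gaze sampling rate (capped at a quarter of
#' the series length): fixation/saccade alternation makes the series
#' renewal-like at sub-second scales, and the long-memory structure of
#' fixation durations expresses at multi-second scales.
#'
#' @param fix A `fixation_series`.
#' @param scale_lo,scale_hi,n_scales,overlap Passed to [dfa()].
#' @return A `dfa_result`.
#' @export
behavioural_dfa <- function(fix, scale_lo = NULL, scale_hi = NULL,
                            n_scales = 15, overlap = 0.5) {
  stopifnot(inherits(fix, "fixation_series"))
  if (fix$n_fixations < 10L) warnf("behavioural_dfa: only %d fixations; exponent unstable", fix$n_fixations)
  n <- length(fix$states)
  if (is.null(scale_lo)) scale_lo <- max(4, round(2 * fix$fs))
  if (is.null(scale_hi)) scale_hi <- min(round(100 * fix$fs), floor(n / 4))
  dfa(as.numeric(fix$states), scale_lo, scale_hi, n_scales, overlap)
}
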