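#' FIR filter specification
#'
#' Kaiser-windowed sinc FIR design parameters. The Kaiser beta is derived
#' from the stated transition bandwidth and order via the standard Kaiser
#' design relations (attenuation `A = 2.285 * dw * order + 7.95` with `dw`
#' the transition width in rad/sample).
#'
#' @param kind `"highpass"`, `"lowpass"` or `"bandpass"`.
#' @param cutoffs Cutoff frequency (Hz); two values for bandpass.
#' @param transition_bw Transition bandwidth (Hz).
#' @param order Filter order (number of taps minus one); must be even so
#'   the zero-phase group delay is an integer number of samples.
#' @return Object of class `filter_spec`.
#' @export
filter_spec <- function(kind = c("highpass", "lowpass", "bandpass"),
                        cutoffs, transition_bw, order) {
  kind <- match.arg(kind)
  order <- as.integer(order)
  if (is.na(order) || order <= 0L || order %% 2L != 0L) {
    stopf("filter_spec: order must be a positive even integer")
  }
  nc <- if (kind == "bandpass") 2L else 1L
  if (length(cutoffs) != nc || any(cutoffs <= 0)) {
    stopf("filter_spec: %s needs %d positive cutoff(s)", kind, nc)
  }
  structure(list(kind = kind, cutoffs = cutoffs,
                 transition_bw = transition_bw, order = order),
            class = "filter_spec")
}

kaiser_beta_from <- function(order, transition_bw, fs) {
  dw <- 2 * pi * transition_bw / fs
  A <- 2.285 * dw * order + 7.95
  if (A > 50) 0.1102 * (A - 8.7)
  else if (A >= 21) 0.5842 * (A - 21)^0.4 + 0.07886 * (A - 21)
  else 0
}

# Symmetric linear-phase FIR taps for a filter_spec at sampling rate fs.
design_fir <- function(spec, fs) {
  if (any(spec$cutoffs >= fs / 2)) stopf("design_fir: cutoff at or above Nyquist (%g Hz)", fs / 2)
  beta <- kaiser_beta_from(spec$order, spec$transition_bw, fs)
  win <- signal::kaiser(spec$order + 1L, beta)
  w <- spec$cutoffs / (fs / 2)
  type <- switch(spec$kind, highpass = "high", lowpass = "low", bandpass = "pass")
  as.numeric(signal::fir1(spec$order, w, type = type, window = win))
}

# Zero-phase application of symmetric taps h to an n x C matrix (columns =
# channels) by FFT convolution with group-delay compensation.
apply_fir_matrix <- function(X, h) {
  n <- nrow(X)
  lh <- length(h)
  if (lh >= n) stopf("FIR length (%d) must be below the data length (%d)", lh, n)
  L <- stats::nextn(n + lh - 1L, c(2, 3, 5))
  H <- fft(c(h, rep(0, L - lh)))
  Xp <- rbind(X, matrix(0, L - n, ncol(X)))
  Y <- mvifft_real(mvfft_real(Xp) * H)
  delay <- (lh - 1L) %/% 2L
  Y[(delay + 1L):(delay + n), , drop = FALSE]
}

#' Zero-phase FIR filtering of a recording
#'
#' Applies a Kaiser-windowed sinc FIR filter with group-delay compensation,
#' so the net phase is zero and the output has the input's length.
#'
#' @param rec An `eeg_recording`.
#' @param spec A [filter_spec()].
#' @return Filtered `eeg_recording`.
#' @export
filter_zerophase <- function(rec, spec) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(spec, "filter_spec"))
  h <- design_fir(spec, rec$fs)
  Y <- apply_fir_matrix(t(rec$data), h)
  out <- rec
  out$data <- t(Y)
  rownames(out$data) <- rec$labels
  out
}

#' Anti-aliased resampling of a recording
#'
#' Rational-ratio resampling: zero-stuff upsampling where needed, zero-phase
#' FIR anti-alias filtering with passband up to ~80% of the output Nyquist,
#' then decimation. Duration is preserved to within one sample period.
#'
#' @param rec An `eeg_recording`.
#' @param target_fs Output sampling rate (Hz).
#' @return Resampled `eeg_recording`.
#' @export
resample_recording <- function(rec, target_fs) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!is.numeric(target_fs) || target_fs <= 0) stopf("resample_recording: target_fs must be > 0")
  if (abs(target_fs - rec$fs) < 1e-9) return(rec)
  frac <- rational_ratio(target_fs, rec$fs)
  p <- frac[1]; q <- frac[2]
  X <- t(rec$data)
  n <- nrow(X)
  if (p > 1L) {
    Xu <- matrix(0, n * p, ncol(X))
    Xu[seq(1L, n * p, by = p), ] <- X * p
    X <- Xu
  }
  fs_up <- rec$fs * p
  cutoff <- 0.45 * min(rec$fs, target_fs)
  tbw <- 0.2 * min(rec$fs, target_fs) / 2
  A <- 60
  order <- 2L * ceiling((A - 7.95) / (2.285 * 2 * pi * tbw / fs_up) / 2)
  h <- design_fir(filter_spec("lowpass", cutoff, tbw, order), fs_up)
  X <- apply_fir_matrix(X, h)
  idx <- seq(1L, nrow(X), by = q)
  out <- rec
  out$fs <- target_fs
  out$data <- t(X[idx, , drop = FALSE])
  rownames(out$data) <- rec$labels
  out
}

rational_ratio <- function(a, b, scale = 1e6) {
  pa <- round(a * scale); pb <- round(b * scale)
  g <- gcd2(pa, pb)
  c(pa / g, pb / g)
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

#' Automated bad-channel detection
#'
#' Flags channels by the union rule: (i) end-of-session impedance above
#' `impedance_kohm`, OR (ii) maximum Pearson correlation with channels
#' within `neighbor_deg` degrees below `neighbor_corr`, OR at least two of
#' (iii) spectral deviation z-score above `spectral_z`, (iv) amplitude
#' improbability z-score above `improb_z`, (v) kurtosis z-score above
#' `kurtosis_z`. The spectral metric is the RMS deviation of the channel's
#' log power spectrum from the channel-mean log spectrum; the improbability
#' metric is the channel's negative mean Gaussian log-likelihood under a
#' density fit to all channels' pooled amplitudes; both and the kurtosis
#' are z-scored across channels.
#'
#' @param rec An `eeg_recording`.
#' @param montage An `eeg_montage`.
#' @param thresholds Named list overriding any of `impedance_kohm` (100),
#'   `neighbor_corr` (0.75), `spectral_z` (4), `improb_z` (4),
#'   `kurtosis_z` (7), `neighbor_deg` (25).
#' @param decimate Integer subsampling factor for the statistical metrics
#'   (the z-scored metrics are estimated on every `decimate`-th sample;
#'   1 = use all samples).
#' @return Character vector of flagged channel labels, with per-criterion
#'   metrics in attribute `"metrics"`.
#' @export
detect_bad_channels <- function(rec, montage, thresholds = list(), decimate = 1L) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(montage, "eeg_montage"))
  C <- nrow(rec$data)
  if (C < 3L) stopf("detect_bad_channels: need at least 3 channels for cross-channel z-scores")
  th <- utils::modifyList(list(impedance_kohm = 100, neighbor_corr = 0.75,
                               spectral_z = 4, improb_z = 4, kurtosis_z = 7,
                               neighbor_deg = 25), thresholds)
  decimate <- max(1L, as.integer(decimate))
  if (decimate > 1L) {
    rec$data <- rec$data[, seq(1L, ncol(rec$data), by = decimate), drop = FALSE]
    rec$fs <- rec$fs / decimate
  }
  X <- t(rec$data)

  # (i) impedance
  bad_i <- rec$impedances > th$impedance_kohm

  # (ii) neighbor correlation
  ang <- angular_distance(montage$positions)
  nb <- ang < th$neighbor_deg * pi / 180
  diag(nb) <- FALSE
  cc <- suppressWarnings(stats::cor(X))
  cc[is.na(cc)] <- 0
  max_nb_corr <- vapply(seq_len(C), function(j) {
    jj <- which(nb[j, ])
    if (!length(jj)) return(1)
    max(cc[j, jj])
  }, 0)
  bad_ii <- max_nb_corr < th$neighbor_corr

  # (iii) spectral deviation (~1 Hz resolution, non-overlapping segments)
  res <- rec$fs / min(128L, 2^floor(log2(ncol(rec$data) / 2)))
  spec_ok <- ncol(rec$data) >= 2 * round(rec$fs / res)
  if (spec_ok) {
    ps <- welch_psd(rec, resolution = res, overlap = 0)
    lp <- log10(pmax(ps$power, 1e-20))
    dev <- sqrt(rowMeans((lp - rep(colMeans(lp), each = C))^2))
    z_spec <- as.vector(scale(dev))
  } else z_spec <- rep(0, C)

  # (iv) improbability under pooled Gaussian fit
  mu <- mean(X); sg <- stats::sd(as.vector(X))
  nll <- colMeans((X - mu)^2) / (2 * sg^2) + log(sg) + 0.5 * log(2 * pi)
  z_improb <- as.vector(scale(nll))

  # (v) kurtosis
  cm <- colMeans(X)
  Xc <- X - rep(cm, each = nrow(X))
  s2 <- colMeans(Xc^2)
  kur <- ifelse(s2 == 0, 0, colMeans(Xc^4) / s2^2)
  z_kur <- as.vector(scale(kur))

  votes <- (z_spec > th$spectral_z) + (z_improb > th$improb_z) + (z_kur > th$kurtosis_z)
  bad <- bad_i | bad_ii | votes >= 2L
  out <- rec$labels[bad]
  attr(out, "metrics") <- data.frame(
    label = rec$labels, impedance = rec$impedances, max_neighbor_corr = max_nb_corr,
    z_spectral = z_spec, z_improbability = z_improb, z_kurtosis = z_kur,
    flagged = bad)
  out
}

# Perrin-style spherical spline basis: g(x) for cos(angle) matrix x,
# stiffness m, L Legendre terms.
spline_g <- function(x, m = 4, L = 50) {
  # iterative Legendre recurrence over matrix argument
  P_prev <- matrix(1, nrow(x), ncol(x))   # P_0
  P_cur <- x                              # P_1
  acc <- (2 * 1 + 1) / (1 * 2)^m * P_cur
  for (l in 2:L) {
    P_new <- ((2 * l - 1) * x * P_cur - (l - 1) * P_prev) / l
    acc <- acc + (2 * l + 1) / (l * (l + 1))^m * P_new
    P_prev <- P_cur; P_cur <- P_new
  }
  acc / (4 * pi)
}

#' Spherical-spline interpolation of bad channels
#'
#' Replaces flagged channels with spherical-spline estimates (stiffness
#' `m = 4`, truncated Legendre series) computed from the good channels.
#' Good channels are untouched.
#'
#' @param rec An `eeg_recording`.
#' @param bad Labels of channels to interpolate.
#' @param montage An `eeg_montage`.
#' @param m Spline stiffness.
#' @param n_legendre Number of Legendre terms.
#' @param lambda Ridge regularization added to the spline system.
#' @return An `eeg_recording` with interpolated channels.
#' @export
interpolate_bad <- function(rec, bad, montage, m = 4, n_legendre = 50,
                            lambda = 1e-5) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(montage, "eeg_montage"))
  bad <- intersect(bad, rec$labels)
  if (!length(bad)) return(rec)
  good <- setdiff(rec$labels, bad)
  if (!length(good)) stopf("interpolate_bad: all channels flagged bad")
  if (length(bad) > 0.25 * length(rec$labels)) {
    warnf("interpolate_bad: %d of %d channels flagged (> 25%%)", length(bad), length(rec$labels))
  }
  pos <- montage$positions[rec$labels, , drop = FALSE]
  gi <- match(good, rec$labels); bi <- match(bad, rec$labels)
  cosang <- tcrossprod(pos)
  cosang[cosang > 1] <- 1; cosang[cosang < -1] <- -1
  Ggg <- spline_g(cosang[gi, gi, drop = FALSE], m, n_legendre)
  Gbg <- spline_g(cosang[bi, gi, drop = FALSE], m, n_legendre)
  k <- length(gi)
  A <- rbind(cbind(Ggg + lambda * diag(k), rep(1, k)), c(rep(1, k), 0))
  rhs <- rbind(rec$data[gi, , drop = FALSE], 0)
  sol <- solve(A, rhs)
  est <- Gbg %*% sol[seq_len(k), , drop = FALSE] +
    matrix(sol[k + 1L, ], length(bi), ncol(rec$data), byrow = TRUE)
  out <- rec
  out$data[bi, ] <- est
  out
}

#' Average re-referencing
#'
#' Subtracts the across-channel mean from every sample; the per-sample
#' channel mean of the output is zero.
#'
#' @param rec An `eeg_recording`.
#' @return Re-referenced `eeg_recording`.
#' @export
rereference_average <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  out <- rec
  out$data <- sweep(rec$data, 2, colMeans(rec$data))
  out
}

#' Default band-pass filter chain specs
#'
#' High-pass at 0.5 Hz (transition 1 Hz) and low-pass at 47 Hz (transition
#' 2 Hz); the stated orders (1812 / 908 at 500 Hz) are scaled with the
#' sampling rate so the transition sharpness in Hz is preserved.
#'
#' @param fs Sampling rate (Hz).
#' @return List of two [filter_spec()]s (`highpass`, `lowpass`).
#' @export
default_filter_specs <- function(fs) {
  sc <- fs / 500
  list(highpass = filter_spec("highpass", 0.5, 1, 2L * round(1812 * sc / 2)),
       lowpass = filter_spec("lowpass", 47, 2, 2L * round(908 * sc / 2)))
}

#' Full deterministic preprocessing chain
#'
#' Band-pass FIR filtering (the high- and low-pass kernels are convolved
#' into one zero-phase kernel), resampling to `target_fs`, bad-channel
#' detection by the five-criterion union rule, spherical-spline
#' interpolation of flagged channels, and average re-referencing. An
#' optional `artifact_hook` (a function `recording -> recording`) runs
#' after interpolation, as an insertion point for artifact removal on real
#' data; the default is a no-op.
#'
#' @param rec An `eeg_recording`.
#' @param montage An `eeg_montage`.
#' @param target_fs Analysis sampling rate (Hz).
#' @param filter_specs List with `highpass` and `lowpass` [filter_spec()]s.
#' @param thresholds Bad-channel thresholds (see [detect_bad_channels()]).
#' @param artifact_hook Optional function applied before re-referencing.
#' @return List with `recording` (preprocessed) and `report` (channels
#'   flagged, per-criterion metrics).
#' @export
preprocess <- function(rec, montage, target_fs = 250,
                       filter_specs = default_filter_specs(rec$fs),
                       thresholds = list(), artifact_hook = NULL) {
  h <- stats::convolve(design_fir(filter_specs$highpass, rec$fs),
                       rev(design_fir(filter_specs$lowpass, rec$fs)),
                       type = "open")
  X <- apply_fir_matrix(t(rec$data), h)
  filt <- rec
  filt$data <- t(X)
  rownames(filt$data) <- rec$labels
  filt <- resample_recording(filt, target_fs)
  bad <- detect_bad_channels(filt, montage, thresholds, decimate = 3L)
  out <- interpolate_bad(filt, bad, montage)
  if (is.function(artifact_hook)) out <- artifact_hook(out)
  out <- rereference_average(out)
  list(recording = out,
       report = list(bad_channels = as.character(bad),
                     metrics = attr(bad, "metrics"),
                     target_fs = target_fs))
}
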