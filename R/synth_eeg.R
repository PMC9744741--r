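# Tunable constants of the EEG generator. Amplitude units are chosen so
# that the 1/f background integrates to a realistic resting power
# (~90 uV^2 over 0.5-47 Hz) and oscillatory components sit a few uV^2/Hz
# above it in their bands. Regional weights and gain exponents localize the
# group effects (alpha/gamma occipital, beta frontal) while keeping their
# global footprint small enough that arousal-style controls stay null.
.eeg_gen <- list(
  bg_level   = 20,      # background PSD at 1 Hz, uV^2/Hz
  bg_floor_hz = 0.5,    # background flat below this frequency
  bg_hi_hz   = 48,      # background synthesized up to here
  smooth_deg = 30,      # spatial smoothing kernel width (degrees)
  alpha_base = 3.5,     # alpha carrier amplitude scale, uV
  alpha_sd_hz = 0.45,    # Gaussian spectral width of the alpha peak, Hz
  alpha_w    = c(occipital = 1.8, frontal = 1.2, face = 0.5, other = 1.7),
  alpha_comp = 0.20,    # diffuse compensating exponent (reactivity balance)
  alpha_state_sd = 0.28, # per-recording lognormal state noise on alpha gain
  alpha_ch_jitter = 0.10, # per-channel lognormal jitter on alpha expression
  env_depth  = 0.7,     # envelope: e(t) = max(1 + env_depth * fGn, floor)
  env_floor  = 0.12,    # envelope positivity floor
  env_fs     = 4,       # sampling rate of the envelope fGn driver, Hz
  beta_level = 0.45,    # beta plateau PSD scale, uV^2/Hz
  beta_band  = c(12.5, 32),
  beta_w     = c(occipital = 0.7, frontal = 1.8, face = 0.7, other = 0.7),
  beta_exp   = c(occipital = 0.3, frontal = 1, face = 0.3, other = 0.3),
  gamma_level = 0.28,   # gamma plateau PSD scale, uV^2/Hz
  gamma_band = c(32.5, 45),
  gamma_w    = c(occipital = 1.8, frontal = 0.7, face = 0.7, other = 0.7),
  gamma_exp  = c(occipital = 1, frontal = 0.3, face = 0.3, other = 0.3),
  gamma_ec_suppress = 0.25, # gamma gain multiplier with eyes closed
  band_edge  = 1        # raised-cosine transition for band noise, Hz
)

# Raised-cosine band mask over frequencies f (Hz): 1 inside [lo, hi],
# cosine roll-off of width `edge` outside.
band_mask <- function(f, lo, hi, edge) {
  m <- numeric(length(f))
  inside <- f >= lo & f <= hi
  m[inside] <- 1
  up <- f > lo - edge & f < lo
  m[up] <- 0.5 * (1 + cos(pi * (lo - f[up]) / edge))
  dn <- f > hi & f < hi + edge
  m[dn] <- 0.5 * (1 + cos(pi * (f[dn] - hi) / edge))
  m
}

# Gaussian field with per-channel target one-sided PSD. `psd_half` gives
# uV^2/Hz on the half frequency grid (bins 1..floor(n/2)+1), as a vector or
# a (floor(n/2)+1) x C matrix. A Hermitian random spectrum is synthesized
# (E|X_k|^2 = n * fs * S_one / 2) and inverse-transformed, giving an exact
# stationary Gaussian field with the requested density.
noise_from_psd <- function(n, fs, psd_half, C = 1L) {
  if (is.matrix(psd_half)) C <- ncol(psd_half)
  m <- n %/% 2L
  P <- if (is.matrix(psd_half)) psd_half else matrix(psd_half, m + 1L, C)
  sig <- sqrt(P * n * fs / 2)
  nz <- which(rowSums(sig) > 0)
  nz <- nz[nz > 1L]                      # DC stays zero
  Fm <- matrix(0i, n, C)
  if (length(nz)) {
    k <- length(nz) * C
    Fm[nz, ] <- complex(real = rnorm(k), imaginary = rnorm(k)) * (sig[nz, , drop = FALSE] / sqrt(2))
    if (n %% 2L == 0L && (m + 1L) %in% nz) {
      Fm[m + 1L, ] <- complex(real = rnorm(C)) * sig[m + 1L, ]
    }
    mirror <- nz[nz <= (if (n %% 2L == 0L) m else m + 1L)]
    Fm[n + 2L - mirror, ] <- Conj(Fm[mirror, , drop = FALSE])
  }
  mvifft_real(Fm)
}

#' Synthesize one subject's multichannel EEG recording
#'
#' Each channel is the sum of a spatially correlated 1/f^chi background,
#' beta/gamma band-limited noise with region-weighted gains, and a
#' narrowband alpha oscillation centered at the subject's true IAF. The
#' alpha amplitude envelope is an affine, floor-clipped transform of
#' fractional Gaussian noise with exponent `hurst_alpha`, synthesized at a
#' slow rate and interpolated, so the envelope's long-memory structure
#' dominates the oscillation's own narrowband fluctuations at multi-second
#' scales. Group
#' effects are spatially localized: the subject's alpha gain concentrates
#' alpha occipitally while slightly reducing diffuse alpha (a topographic
#' redistribution, so global alpha stays comparable across groups), beta
#' acts on frontal and gamma on occipital channels. With eyes
#' closed the alpha gain is the subject's `alpha_gain_ec` (drawn from the
#' same distribution in both groups) and gamma is suppressed.
#'
#' This generator is a stand-in model: it reproduces the spectral, IAF and
#' LRTC structure the analysis targets, not artifact content or true volume
#' conduction (spatial correlation is imposed by a Gaussian smoothing
#' kernel over the montage; see the methods vignette).
#'
#' @param subject A `subject_record`.
#' @param montage An `eeg_montage` with occipital and frontal channels.
#' @param condition `"eyes_open"` or `"eyes_closed"`.
#' @param duration_s Length in seconds.
#' @param fs Sampling rate (Hz).
#' @param seed Integer seed (defaults to the subject's own stream).
#' @param chi Background spectral exponent (PSD proportional to 1/f^chi).
#' @param return_parts If `TRUE`, attach the ground-truth alpha envelope
#'   and carrier as attribute `"parts"` (for recovery tests).
#' @return An `eeg_recording` (channels x samples).
#' @export
synth_eeg <- function(subject, montage, condition = c("eyes_open", "eyes_closed"),
                      duration_s = 90, fs = 250, seed = subject$seed,
                      chi = 1, return_parts = FALSE) {
  condition <- match.arg(condition)
  stopifnot(inherits(montage, "eeg_montage"))
  if (!any(montage$regions == "occipital") || !any(montage$regions == "frontal")) {
    stopf("synth_eeg: montage must tag occipital and frontal regions")
  }
  g <- .eeg_gen
  n <- round(duration_s * fs)
  C <- length(montage$labels)
  f <- seq(0, by = fs / n, length.out = n %/% 2L + 1L)  # half grid
  reg <- as.character(montage$regions)

  cond_idx <- if (condition == "eyes_open") 1L else 2L
  with_seed(derive_seed(seed, 7L, cond_idx), {
    alpha_gain <- if (condition == "eyes_open") subject$alpha_gain_eo else subject$alpha_gain_ec
    alpha_gain <- alpha_gain * exp(g$alpha_state_sd * rnorm(1))
    gamma_gain <- subject$gamma_gain *
      (if (condition == "eyes_closed") g$gamma_ec_suppress else 1)

    # --- background + beta + gamma as one Gaussian field. Each component
    # is spatially smoothed (volume-conduction stand-in) in the frequency
    # domain and THEN given its per-channel regional weight, so smoothing
    # induces neighbor correlation without blurring the regional contrasts.
    # One inverse FFT synthesizes the sum.
    ang <- angular_distance(montage$positions)
    S <- exp(-(ang * 180 / pi)^2 / (2 * g$smooth_deg^2))
    S <- S / sqrt(rowSums(S^2))          # preserve per-channel variance
    bg_psd <- ifelse(f < g$bg_floor_hz, g$bg_level / g$bg_floor_hz^chi,
                     g$bg_level / pmax(f, g$bg_floor_hz)^chi)
    bg_psd[f == 0] <- 0
    bg_psd[f > g$bg_hi_hz] <- 0
    beta_psd <- g$beta_level * band_mask(f, g$beta_band[1], g$beta_band[2], g$band_edge)
    gamma_psd <- g$gamma_level * band_mask(f, g$gamma_band[1], g$gamma_band[2], g$band_edge)
    bw <- g$beta_w[reg] * subject$beta_gain^g$beta_exp[reg]
    gw <- g$gamma_w[reg] * (if (gamma_gain == 0) 0 else gamma_gain^g$gamma_exp[reg])
    m <- n %/% 2L
    Fh <- matrix(0i, m + 1L, C)
    add_component <- function(Fh, psd_vec, wch) {
      nz <- which(psd_vec > 0)
      nz <- nz[nz > 1L]
      if (!length(nz)) return(Fh)
      eps <- matrix(complex(real = rnorm(length(nz) * C),
                            imaginary = rnorm(length(nz) * C)) / sqrt(2),
                    length(nz), C)
      scale <- sqrt(psd_vec[nz] * n * fs / 2)
      Fh[nz, ] <- Fh[nz, ] + (eps %*% S) * (scale * rep(sqrt(wch), each = length(nz)))
      Fh
    }
    Fh <- add_component(Fh, bg_psd, rep(1, C))
    Fh <- add_component(Fh, beta_psd, bw)
    Fh <- add_component(Fh, gamma_psd, gw)
    Fm <- matrix(0i, n, C)
    Fm[seq_len(m + 1L), ] <- Fh
    if (n %% 2L == 0L) Fm[m + 1L, ] <- complex(real = sqrt(2) * Re(Fh[m + 1L, ]))
    mir <- 2L:(if (n %% 2L == 0L) m else m + 1L)
    Fm[n + 2L - mir, ] <- Conj(Fm[mir, , drop = FALSE])
    x <- mvifft_real(Fm)

    # --- alpha: Gaussian-peak narrowband carriers x fGn-driven envelope.
    # Per-channel carriers are spatially smoothed like the background, so
    # alpha coherence decays with electrode distance (as on a real scalp)
    # and average re-referencing removes only a weak common mode. Carriers
    # are synthesized in quadrature at a low rate (the Gaussian peak is a
    # baseband process of a few Hz bandwidth) and heterodyned to the IAF.
    fs_bb <- 12.5
    n_bb <- ceiling(n * fs_bb / fs) + 2L
    f_bb <- seq(0, by = fs_bb / n_bb, length.out = n_bb %/% 2L + 1L)
    bb_psd <- exp(-f_bb^2 / (2 * g$alpha_sd_hz^2))
    bb_psd[bb_psd < 1e-4] <- 0
    tt <- (seq_len(n) - 1L) / fs
    pos <- tt * fs_bb + 1
    i0 <- pmin(floor(pos), n_bb - 1L)
    wint <- pos - i0
    up <- function(M) {
      Ms <- M %*% S
      Ms[i0, , drop = FALSE] * (1 - wint) + Ms[i0 + 1L, , drop = FALSE] * wint
    }
    ac <- up(noise_from_psd(n_bb, fs_bb, bb_psd, C))
    as_ <- up(noise_from_psd(n_bb, fs_bb, bb_psd, C))
    carrier <- ac * cos(2 * pi * subject$iaf_true * tt) +
      as_ * sin(2 * pi * subject$iaf_true * tt)
    carrier <- carrier / stats::sd(carrier)   # unit variance overall
    n_slow <- max(8L, ceiling(duration_s * g$env_fs) + 1L)
    g_slow <- synth_fgn(n_slow, subject$hurst_alpha,
                        seed = derive_seed(seed, 11L, cond_idx))
    env <- stats::approx(x = seq(0, by = 1 / g$env_fs, length.out = n_slow),
                         y = pmax(1 + g$env_depth * g_slow, g$env_floor),
                         xout = (seq_len(n) - 1L) / fs, rule = 2)$y
    env <- env / sqrt(1 + g$env_depth^2)  # approximately unit-RMS envelope
    # gain of exactly zero silences the component everywhere (gain^0 == 1
    # would otherwise leave it on channels with exponent 0)
    # gain exponent: full effect over the occipital region, with a small
    # diffuse compensation elsewhere so the subject's total alpha stays
    # comparable across gains (reactivity control)
    a_exp <- ifelse(reg == "occipital", 1, -g$alpha_comp)
    aw <- if (alpha_gain == 0) rep(0, C) else
      g$alpha_base * g$alpha_w[reg] * alpha_gain^a_exp *
        exp(g$alpha_ch_jitter * rnorm(C))
    x <- x + (carrier * env) * rep(aw, each = n)

    imped <- runif(C, 5, 40)
    rec <- new_recording(t(x), fs, montage$labels, condition, imped)
    if (return_parts) {
      attr(rec, "parts") <- list(envelope = env, carrier = carrier[, 1L],
                                 alpha_weights = aw)
    }
    rec
  })
}
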