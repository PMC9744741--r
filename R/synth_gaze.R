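#' Synthesize a gaze velocity trace with ground-truth fixation states
#'
#' Builds an alternating fixation/saccade event sequence. Fixation
#' durations carry long memory: duration of event k is
#' `exp(fixation_log_mean + fixation_log_sd * g_k)` where `g` is fractional
#' Gaussian noise with the subject's `hurst_fix` exponent, so the binary
#' fixation series (0 = fixation, 1 = saccade) inherits long-range temporal
#' correlations. Saccade durations are short and near-constant. The
#' velocity trace is low-amplitude drift noise during fixations and a
#' ballistic half-sine profile during saccades.
#'
#' @param subject A `subject_record`.
#' @param duration_s Trace length in seconds.
#' @param fs_gaze Sampling rate (Hz).
#' @param seed Integer seed (defaults to the subject's stream).
#' @return Object of class `gaze_recording`: list with `velocity` (deg/s),
#'   `true_state` (integer 0/1), `fs_gaze`.
#' @export
synth_gaze <- function(subject, duration_s = 600, fs_gaze = 500,
                       seed = subject$seed) {
  n <- round(duration_s * fs_gaze)
  mu <- subject$fixation_log_mean
  sdl <- subject$fixation_log_sd
  mean_fix <- exp(mu + sdl^2 / 2)
  with_seed(derive_seed(seed, 23L), {
    # persistent low excursions of the duration driver can need far more
    # events than the expectation suggests; retry with a larger budget
    for (margin in c(1.8, 6, 20)) {
      n_events <- ceiling(duration_s / mean_fix * margin) + 16
      gk <- synth_fgn(n_events, subject$hurst_fix,
                      seed = derive_seed(seed, 29L, round(margin)))
      fix_dur <- exp(mu + sdl * gk)
      sac_dur <- pmax(0.012, subject$saccade_dur_ms / 1000 +
                        0.004 * rnorm(n_events))
      sac_peak <- runif(n_events, 120, 350)

      fix_len <- pmax(2L, round(fix_dur * fs_gaze))
      sac_len <- pmax(2L, round(sac_dur * fs_gaze))
      # interleave f1 s1 f2 s2 ...; keep events until the trace is covered
      total <- cumsum(as.vector(rbind(fix_len, sac_len)))
      k <- which(total >= n)[1]
      if (!is.na(k)) break
    }
    if (is.na(k)) stopf("synth_gaze: internal event budget exhausted")
    if (k < 3L) stopf("synth_gaze: duration too short for at least 2 fixations")
    lens <- as.vector(rbind(fix_len, sac_len))[seq_len(k)]
    states <- rep(rep(c(0L, 1L), length.out = k), lens)[seq_len(n)]
    # trailing saccade samples merge into the preceding fixation so the
    # trace starts and ends in a fixation
    last_run <- rev(which(states != states[n]))[1]
    if (states[n] == 1L) states[(if (is.na(last_run)) 1L else last_run + 1L):n] <- 0L

    velocity <- abs(2 + 1.2 * rnorm(n))      # fixational drift, deg/s
    r <- rle(states)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    si <- which(r$values == 1L)
    for (j in seq_along(si)) {
      a <- starts[si[j]]; b <- ends[si[j]]
      m <- b - a + 1L
      prof <- sin(pi * seq_len(m) / (m + 1))
      velocity[a:b] <- sac_peak[j] * prof + abs(2 + 1.2 * rnorm(m))
    }
    structure(list(velocity = velocity, true_state = states, fs_gaze = fs_gaze),
              class = "gaze_recording")
  })
}

#' @export
print.gaze_recording <- function(x, ...) {
  r <- rle(x$true_state)
  cat(sprintf("<gaze_recording> %.1f s @ %g Hz; %d fixations, %d saccades\n",
              length(x$velocity) / x$fs_gaze, x$fs_gaze,
              sum(r$values == 0L), sum(r$values == 1L)))
  invisible(x)
}

#' Write a gaze trace as CSV
#'
#' Columns: `time_s`, `velocity_deg_s`, `true_state`.
#'
#' @param gaze A `gaze_recording`.
#' @param path CSV path.
#' @export
write_gaze <- function(gaze, path) {
  df <- data.frame(time_s = (seq_along(gaze$velocity) - 1) / gaze$fs_gaze,
                   velocity_deg_s = gaze$velocity,
                   true_state = gaze$true_state)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
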