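# Independent reference DFA: explicit window loop with least-squares
# detrending via .lm.fit. Shares only the definition with dfa(), not code.
dfa_reference <- function(x, scale_lo, scale_hi, n_scales = 15, overlap = 0.5) {
  scales <- unique(round(exp(seq(log(scale_lo), log(scale_hi), length.out = n_scales))))
  prof <- cumsum(x - mean(x))
  n <- length(prof)
  Fs <- vapply(scales, function(s) {
    step <- max(1, round(s * (1 - overlap)))
    starts <- seq(1, n - s + 1, by = step)
    tmat <- cbind(1, seq_len(s))
    ss <- vapply(starts, function(a) {
      sum(.lm.fit(tmat, prof[a:(a + s - 1)])$residuals^2)
    }, 0)
    sqrt(mean(ss) / s)
  }, 0)
  fit <- stats::lm(log(Fs) ~ log(scales))
  unname(stats::coef(fit)[2])
}

# small montage + clean multichannel recording helpers used across files
tiny_montage <- function(n = 32) make_montage(n)

# recording whose channels share a common signal plus small independent
# noise (volume-conduction-like; keeps neighbor correlations high)
clean_recording <- function(montage, n = 2000, fs = 250, seed = 1,
                            impedances = NULL) {
  set.seed(seed)
  C <- length(montage$labels)
  common <- stats::rnorm(n)
  data <- matrix(common, C, n, byrow = TRUE) + 0.2 * matrix(stats::rnorm(C * n), C, n)
  new_recording(data, fs, montage$labels, "eyes_open",
                impedances = if (is.null(impedances)) rep(10, C) else impedances)
}

tone_recording <- function(freq, fs = 250, dur = 10, amp = 1, C = 2) {
  t <- (0:(dur * fs - 1)) / fs
  data <- matrix(rep(amp * sin(2 * pi * freq * t), each = C), C)
  new_recording(data, fs, sprintf("E%03d", 1:C), "eyes_open")
}
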