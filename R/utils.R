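#' @keywords internal
#' @import stats
#' @import utils
"_PACKAGE"

# Run an expression under a local RNG state. The caller's .Random.seed is
# restored on exit, so package functions taking a `seed` argument never
# perturb the user's random stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Counter-based seed fan-out: one global seed plus a stream index yields an
# independent-looking 31-bit sub-seed. Adding a subject (new index) never
# perturbs the draws of existing indices.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  h <- as.double(seed) %% 2147483647
  for (k in idx) {
    h <- (h * 48271 + as.double(k) + 1) %% 2147483647
  }
  as.integer(h)
}

# Trapezoidal integration on an arbitrary grid.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Matrix trapezoid: integrate each row of Y (channels x freqs) over x.
trapz_rows <- function(x, Y) {
  n <- length(x)
  dx <- x[-1] - x[-n]
  as.vector((Y[, -1, drop = FALSE] + Y[, -n, drop = FALSE]) %*% dx) / 2
}

# Real-input multi-channel FFT via complex packing: pairs of real columns
# share one complex FFT. Returns the full complex spectrum (n x C).
mvfft_real <- function(X) {
  n <- nrow(X); C <- ncol(X)
  if (C == 1L) return(matrix(fft(X[, 1L]), ncol = 1L))
  odd <- seq(1L, C - 1L, by = 2L); even <- odd + 1L
  Fz <- mvfft(X[, odd, drop = FALSE] + 1i * X[, even, drop = FALSE])
  Fr <- Conj(Fz[c(1L, n:2L), , drop = FALSE])
  out <- matrix(0i, n, C)
  out[, odd] <- (Fz + Fr) / 2
  out[, even] <- (Fz - Fr) / 2i
  if (C %% 2L == 1L) out[, C] <- fft(X[, C])
  out
}

# Inverse of mvfft_real for spectra of real signals: returns the real part
# of the inverse transform, packing two columns per complex FFT.
mvifft_real <- function(F) {
  n <- nrow(F); C <- ncol(F)
  if (C == 1L) return(matrix(Re(fft(F[, 1L], inverse = TRUE)) / n, ncol = 1L))
  odd <- seq(1L, C - 1L, by = 2L); even <- odd + 1L
  Z <- mvfft(F[, odd, drop = FALSE] + 1i * F[, even, drop = FALSE], inverse = TRUE) / n
  out <- matrix(0, n, C)
  out[, odd] <- Re(Z)
  out[, even] <- Im(Z)
  if (C %% 2L == 1L) out[, C] <- Re(fft(F[, C], inverse = TRUE)) / n
  out
}

# FFT frequencies (Hz) for length n at sampling rate fs, in FFT bin order.
fft_freqs <- function(n, fs) {
  k <- if (n %% 2 == 0) {
    c(0:(n / 2), seq.int(-(n / 2) + 1, -1))
  } else {
    c(0:((n - 1) / 2), seq.int(-((n - 1) / 2), -1))
  }
  k * fs / n
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
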