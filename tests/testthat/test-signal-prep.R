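test_that("zero-phase band-pass keeps passband tones and kills stopband tones", {
  bp <- filter_spec("bandpass", c(7.5, 12), transition_bw = 2, order = 250)
  rec10 <- tone_recording(10, fs = 250, dur = 10)
  out10 <- filter_zerophase(rec10, bp)
  mid <- 500:2000
  amp <- max(abs(out10$data[1, mid]))
  expect_lt(abs(amp - 1), 0.05)
  rec40 <- tone_recording(40, fs = 250, dur = 10)
  out40 <- filter_zerophase(rec40, bp)
  expect_lt(max(abs(out40$data[1, mid])), 0.01)
  expect_equal(ncol(out10$data), ncol(rec10$data))
})

test_that("zero-phase filtering is symmetric around an impulse", {
  n <- 1000
  imp <- matrix(0, 1, n); imp[1, 500] <- 1
  rec <- new_recording(imp, 250, "E001")
  out <- filter_zerophase(rec, filter_spec("bandpass", c(7.5, 12), 2, 66))
  y <- out$data[1, ]
  expect_equal(y[500 + 1:30], y[500 - 1:30], tolerance = 1e-10)
  expect_equal(which.max(abs(y)), 500)
})

test_that("filter specs validate orders and cutoffs", {
  expect_error(filter_spec("lowpass", 47, 2, 3), "even")
  expect_error(filter_spec("lowpass", -1, 2, 100), "cutoff")
  rec <- tone_recording(10, fs = 100, dur = 5)
  expect_error(filter_zerophase(rec, filter_spec("lowpass", 60, 2, 100)), "Nyquist")
})

test_that("resampling preserves duration, tones and the low spectrum", {
  rec <- tone_recording(5, fs = 500, dur = 10)
  out <- resample_recording(rec, 250)
  expect_equal(out$fs, 250)
  expect_equal(ncol(out$data), 2500)
  mid <- 300:2200
  expect_lt(abs(max(abs(out$data[1, mid])) - 1), 0.02)
  expect_error(resample_recording(rec, -5), "target_fs")

  # broadband: spectrum below 100 Hz unchanged within tolerance
  set.seed(4)
  m <- tiny_montage(6)
  rec2 <- clean_recording(m, n = 5000, fs = 500, seed = 4)
  ps1 <- welch_psd(rec2, resolution = 1)
  ps2 <- welch_psd(resample_recording(rec2, 250), resolution = 1)
  sel1 <- ps1$freqs >= 2 & ps1$freqs <= 90
  sel2 <- ps2$freqs >= 2 & ps2$freqs <= 90
  rel <- mean(abs(log(ps2$power[1, sel2] / ps1$power[1, sel1])))
  expect_lt(rel, 0.25)
})

test_that("bad-channel detection applies the five-criterion union rule", {
  m <- tiny_montage(16)
  imp <- rep(10, 16); imp[3] <- 120
  rec <- clean_recording(m, n = 4000, seed = 2, impedances = imp)
  bad <- detect_bad_channels(rec, m)
  expect_identical(as.character(bad), m$labels[3])

  # clean shared-signal recording: nothing flagged
  rec2 <- clean_recording(m, n = 4000, seed = 7)
  expect_length(detect_bad_channels(rec2, m), 0)

  # sparse high-amplitude spikes: flagged via two of the z-criteria.
  # The cross-channel z-score of a single outlier is bounded by
  # (C - 1)/sqrt(C), so this criterion needs a dense montage.
  m64 <- make_montage(64)
  rec3 <- clean_recording(m64, n = 4000, seed = 8)
  set.seed(88)
  spikes <- rep(0, 4000); spikes[sample.int(4000, 12)] <- 60
  rec3$data[5, ] <- 0.3 * rnorm(4000) + spikes
  bad3 <- detect_bad_channels(rec3, m64)
  expect_true(m64$labels[5] %in% bad3)
  mt <- attr(bad3, "metrics")
  expect_gt(mt$z_kurtosis[5], 7)
  expect_gt(mt$z_improbability[5], 4)

  rec4 <- new_recording(matrix(rnorm(200), 2, 100), 100, c("a", "b"))
  expect_error(detect_bad_channels(rec4, m), "3 channels")
})

test_that("bad-channel detection has no false positives on clean fixtures", {
  m <- tiny_montage(12)
  flags <- vapply(1:50, function(s) {
    length(detect_bad_channels(clean_recording(m, n = 1500, seed = 100 + s), m))
  }, 0L)
  expect_true(all(flags == 0L))
})

test_that("spherical-spline interpolation reproduces held-out structure", {
  m <- tiny_montage(64)
  rec <- clean_recording(m, n = 300, seed = 5)

  # no bad channels: identity
  expect_identical(interpolate_bad(rec, character(0), m), rec)

  # constant field: interpolation reproduces it
  recc <- rec
  sig <- sin(2 * pi * 10 * (1:300) / 250)
  recc$data <- matrix(rep(sig, each = 64), 64, dimnames = list(m$labels, NULL))
  recc$data[7, ] <- rnorm(300) * 10
  out <- interpolate_bad(recc, m$labels[7], m, lambda = 1e-7)
  expect_lt(max(abs(out$data[7, ] - sig)), 0.01 * max(abs(sig)))
  expect_identical(out$data[-7, ], recc$data[-7, ])

  # smooth dipolar topography: < 10% RMS reconstruction error
  d <- c(0.3, -0.5, 0.81)
  topo <- as.vector(m$positions %*% d)
  recd <- rec
  recd$data <- outer(topo, sig)
  rownames(recd$data) <- m$labels
  truth <- recd$data[11, ]
  recd$data[11, ] <- 0
  outd <- interpolate_bad(recd, m$labels[11], m)
  err <- sqrt(mean((outd$data[11, ] - truth)^2)) / sqrt(mean(truth^2))
  expect_lt(err, 0.10)

  expect_error(interpolate_bad(rec, m$labels, m), "all channels")
  expect_warning(interpolate_bad(rec, m$labels[1:20], m), "25%")
})

test_that("average reference zeroes the channel mean and is idempotent", {
  m <- tiny_montage(8)
  rec <- clean_recording(m, n = 1000, seed = 6)
  out <- rereference_average(rec)
  expect_lt(max(abs(colMeans(out$data))), 1e-12)
  out2 <- rereference_average(out)
  expect_equal(out2$data, out$data, tolerance = 1e-14)
  # bipolar differences unchanged
  expect_equal(out$data[1, ] - out$data[2, ], rec$data[1, ] - rec$data[2, ], tolerance = 1e-12)
})

test_that("the preprocessing chain is deterministic and reports its decisions", {
  m <- tiny_montage(16)
  rec <- clean_recording(m, n = 3000, seed = 9)
  a <- preprocess(rec, m, target_fs = 250)
  b <- preprocess(rec, m, target_fs = 250)
  expect_identical(a$recording$data, b$recording$data)
  expect_true(is.data.frame(a$report$metrics))
  expect_lt(max(abs(colMeans(a$recording$data))), 1e-10)
})
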