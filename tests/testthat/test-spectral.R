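test_that("Welch grid spacing equals the requested resolution exactly", {
  m <- tiny_montage(4)
  rec <- clean_recording(m, n = 2500, fs = 250, seed = 1)
  ps <- welch_psd(rec, resolution = 0.5)
  expect_equal(unique(round(diff(ps$freqs), 10)), 0.5)
  expect_equal(ps$freqs[1], 0)
  expect_equal(max(ps$freqs), 125)
  expect_error(welch_psd(rec, resolution = 0.3), "integer")
  short <- new_recording(matrix(rnorm(300), 1, 300), 250, "E001")
  expect_error(welch_psd(short, resolution = 0.5), "shorter")
})

test_that("Welch PSD integrates to the variance and localizes tones", {
  set.seed(2)
  rec <- new_recording(matrix(rnorm(250 * 60), 1, 250 * 60), 250, "E001")
  ps <- welch_psd(rec, resolution = 0.5)
  tot <- sum(ps$power[1, ]) * 0.5
  expect_lt(abs(tot - 1), 0.1)

  tone <- tone_recording(10, fs = 250, dur = 30)
  pt <- welch_psd(tone, resolution = 0.5)
  expect_equal(pt$freqs[which.max(pt$power[1, ])], 10)
})

test_that("relative power matches analytic ratios and is scale invariant", {
  freqs <- seq(0, 125, by = 0.5)
  flat <- structure(list(freqs = freqs,
                         power = matrix(1, 2, length(freqs),
                                        dimnames = list(c("a", "b"), NULL)),
                         fs = 250, condition = "eyes_open", labels = c("a", "b")),
                    class = "eeg_spectrum")
  bp <- relative_power(flat)
  expect_equal(unname(bp[1, "alpha"]), (12 - 7.5) / 44, tolerance = 1e-12)
  expect_true(all(rowSums(bp) < 1))

  one_band <- data.frame(name = "all", lo = 1, hi = 45)
  expect_equal(unname(relative_power(flat, bands = one_band)[, "all"]), c(1, 1))

  m <- tiny_montage(4)
  rec <- clean_recording(m, n = 5000, seed = 3)
  rec7 <- rec; rec7$data <- rec$data * 7
  expect_equal(relative_power(welch_psd(rec)), relative_power(welch_psd(rec7)),
               tolerance = 1e-12)
  expect_error(relative_power(flat, bands = data.frame(name = "x", lo = 1, hi = 200)),
               "outside")
})

test_that("IAF is recovered at the group-median alpha frequencies", {
  m <- make_montage(64)
  co <- make_cohort(cohort_spec(seed = 2))
  for (target in c(9.5, 10.5)) {
    sub <- co[[1]]
    sub$iaf_true <- target
    rec <- synth_eeg(sub, m, "eyes_closed", duration_s = 60, fs = 250, seed = 31)
    res <- detect_iaf(welch_psd(rec), m)
    expect_equal(res$iaf, target)
    expect_true(res$is_true_peak)
  }
})

test_that("a monotone spectrum is flagged as a boundary maximum, not a peak", {
  m <- make_montage(64)
  co <- make_cohort(cohort_spec(seed = 2))
  sub <- co[[2]]
  sub$alpha_gain_eo <- 0; sub$alpha_gain_ec <- 0
  sub$beta_gain <- 0; sub$gamma_gain <- 0
  rec <- synth_eeg(sub, m, "eyes_closed", duration_s = 60, fs = 250, seed = 5)
  res <- detect_iaf(welch_psd(rec), m)
  expect_false(res$is_true_peak)
  expect_equal(res$iaf, 7)
  expect_error(detect_iaf(welch_psd(rec), structure(list(labels = "x",
    regions = factor("other", levels = levels(m$regions)),
    positions = m$positions[1, , drop = FALSE]), class = "eeg_montage")),
    "occipital")
})

test_that("IAF detection is invariant to spectrum scaling", {
  m <- make_montage(64)
  sub <- make_cohort(cohort_spec(seed = 4))[[3]]
  rec <- synth_eeg(sub, m, "eyes_closed", duration_s = 45, fs = 250)
  ps <- welch_psd(rec)
  r1 <- detect_iaf(ps, m)
  ps$power <- ps$power * 123.4
  r2 <- detect_iaf(ps, m)
  expect_equal(r1$iaf, r2$iaf)
  expect_equal(r1$is_true_peak, r2$is_true_peak)
})

test_that("alpha reactivity is the EO/EC global alpha ratio", {
  map <- matrix(0.2, 4, 5, dimnames = list(NULL, default_bands()$name))
  expect_equal(as.numeric(alpha_reactivity(map, map)), 1)
  half <- map; half[, "alpha"] <- 0.1
  expect_equal(as.numeric(alpha_reactivity(half, map)), 0.5)
  expect_equal(as.numeric(alpha_reactivity(half, map, orientation = "ec_over_eo")), 2)
  zero <- map; zero[, "alpha"] <- 0
  expect_error(alpha_reactivity(map, zero), "alpha")
})
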