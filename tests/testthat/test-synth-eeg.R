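test_that("synthetic recordings have the requested shape and are deterministic", {
  m <- make_montage(64)
  sub <- make_cohort(cohort_spec(seed = 1))[[1]]
  rec <- synth_eeg(sub, m, "eyes_open", duration_s = 12, fs = 250, seed = 9)
  expect_equal(rec$fs, 250)
  expect_equal(ncol(rec$data), 12 * 250)
  expect_equal(nrow(rec$data), 64)
  rec2 <- synth_eeg(sub, m, "eyes_open", duration_s = 12, fs = 250, seed = 9)
  expect_identical(rec$data, rec2$data)
  m_bad <- m
  m_bad$regions <- factor(rep("other", 64), levels = levels(m$regions))
  expect_error(synth_eeg(sub, m_bad, "eyes_open", 12, 250), "occipital")
})

test_that("static subjects show more occipital relative alpha than dynamic (eyes open)", {
  m <- make_montage(64)
  co <- make_cohort(cohort_spec(seed = 5))
  st <- co[[1]]; dy <- co[[40]]
  stopifnot(st$group == "static", dy$group == "dynamic")
  occ <- region_channels(m, "occipital")
  diffs <- vapply(1:10, function(k) {
    a <- synth_eeg(st, m, "eyes_open", 30, 250, seed = 100 + k)
    b <- synth_eeg(dy, m, "eyes_open", 30, 250, seed = 100 + k)
    pa <- relative_power(welch_psd(a))
    pb <- relative_power(welch_psd(b))
    mean(pa[occ, "alpha"]) - mean(pb[occ, "alpha"])
  }, 0)
  expect_gt(mean(diffs), 0)
})

test_that("zero band gains give a monotone 1/f spectrum with no alpha peak", {
  m <- make_montage(64)
  sub <- make_cohort(cohort_spec(seed = 3))[[1]]
  sub$alpha_gain_eo <- 0; sub$beta_gain <- 0; sub$gamma_gain <- 0
  rec <- synth_eeg(sub, m, "eyes_open", 60, 250, seed = 2)
  ps <- welch_psd(rec)
  avg <- colMeans(ps$power)
  sel <- ps$freqs >= 2 & ps$freqs <= 40
  # smoothed log-spectrum decreases monotonically over the analysis range
  sm <- stats::filter(log(avg[sel]), rep(1 / 5, 5), sides = 2)
  sm <- sm[!is.na(sm)]
  expect_true(all(diff(sm) < 0.05))
  expect_false(detect_iaf(ps, m)$is_true_peak)
})

test_that("eyes-closed recordings suppress gamma and use the EC alpha gain", {
  m <- make_montage(64)
  sub <- make_cohort(cohort_spec(seed = 6))[[1]]
  eo <- synth_eeg(sub, m, "eyes_open", 40, 250, seed = 4)
  ec <- synth_eeg(sub, m, "eyes_closed", 40, 250, seed = 4)
  occ <- region_channels(m, "occipital")
  peo <- relative_power(welch_psd(eo)); pec <- relative_power(welch_psd(ec))
  expect_lt(mean(pec[occ, "gamma"]), mean(peo[occ, "gamma"]))
  expect_gt(mean(pec[occ, "alpha"]), mean(peo[occ, "alpha"]))
})

test_that("the measured alpha envelope recovers the generated fGn envelope", {
  m <- make_montage(64)
  sub <- make_cohort(cohort_spec(seed = 8))[[1]]
  rec <- synth_eeg(sub, m, "eyes_open", 120, 250, seed = 3, return_parts = TRUE)
  truth <- attr(rec, "parts")$envelope
  env <- amplitude_envelope(rec)
  tr <- attr(env, "trim")
  idx <- (tr + 1):(ncol(env) - tr)
  occ <- region_channels(m, "occipital")
  meas <- colMeans(unclass(env)[occ, idx, drop = FALSE])
  # pool to 1-s bins: the narrowband carrier's own envelope fluctuations
  # (sub-second correlation time) average out, leaving the fGn modulator
  pool <- function(v, d = 250) {
    nb <- length(v) %/% d
    colMeans(matrix(v[seq_len(nb * d)], d))
  }
  expect_gt(stats::cor(pool(meas), pool(truth[idx]), method = "spearman"), 0.8)
})
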