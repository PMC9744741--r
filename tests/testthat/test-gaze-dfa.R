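test_that("gaze traces alternate states and start/end in fixation", {
  sub <- make_cohort(cohort_spec(seed = 2))[[1]]
  gz <- synth_gaze(sub, duration_s = 60, fs_gaze = 500, seed = 3)
  expect_equal(length(gz$velocity), 60 * 500)
  r <- rle(gz$true_state)
  expect_true(all(r$lengths > 0))
  expect_true(all(abs(diff(r$values)) == 1))     # strict alternation
  expect_equal(r$values[1], 0L)
  expect_equal(r$values[length(r$values)], 0L)
  # velocity separates the states
  expect_gt(mean(gz$velocity[gz$true_state == 1]), mean(gz$velocity[gz$true_state == 0]))
  expect_identical(gz$velocity, synth_gaze(sub, 60, 500, seed = 3)$velocity)
  expect_error(synth_gaze(sub, duration_s = 0.2, fs_gaze = 500), "duration")
})

test_that("static subjects fixate longer than dynamic subjects", {
  co <- make_cohort(cohort_spec(seed = 4))
  groups <- vapply(co, `[[`, "", "group")
  mean_fix <- function(s) {
    gz <- synth_gaze(s, 60, 500)
    r <- rle(gz$true_state)
    mean(r$lengths[r$values == 0])
  }
  durs <- vapply(co, mean_fix, 0)
  expect_gt(mean(durs[groups == "static"]), mean(durs[groups == "dynamic"]))
})

test_that("velocity-threshold extraction matches constructed fixtures", {
  flat <- list(velocity = rep(5, 5000), fs_gaze = 500)
  fx <- extract_fixations(flat)
  expect_equal(fx$n_fixations, 1L)
  expect_true(all(fx$states == 0L))

  v <- rep(3, 6000)
  for (a in c(1000, 2500, 4200)) v[a:(a + 25)] <- 200
  fx3 <- extract_fixations(list(velocity = v, fs_gaze = 500))
  expect_equal(fx3$n_fixations, 4L)
  expect_error(extract_fixations(list(velocity = numeric(0), fs_gaze = 500)), "empty")
})

test_that("extraction agrees with the generator's ground-truth states", {
  co <- make_cohort(cohort_spec(seed = 9))
  agree <- vapply(co[c(1, 15, 40)], function(s) {
    gz <- synth_gaze(s, 120, 500)
    fx <- extract_fixations(gz)
    mean(fx$states == gz$true_state)
  }, 0)
  expect_true(all(agree >= 0.95))
})

test_that("binary-series DFA is calibrated on memoryless sequences", {
  set.seed(10)
  fx <- structure(list(states = as.integer(runif(3e5) < 0.1), fs = 500,
                       n_fixations = 100L), class = "fixation_series")
  expect_lt(abs(behavioural_dfa(fx)$exponent - 0.5), 0.05)
  few <- structure(list(states = rep(c(0L, 1L), each = 50, times = 4), fs = 100,
                        n_fixations = 4L), class = "fixation_series")
  expect_warning(behavioural_dfa(few, scale_lo = 8, scale_hi = 100), "fixations")
})

test_that("behavioural exponents increase with the generating Hurst exponent", {
  sub <- make_cohort(cohort_spec(seed = 1))[[1]]
  sub$fixation_log_mean <- log(0.28)
  means <- vapply(c(0.55, 0.70, 0.85), function(h) {
    ex <- vapply(1:10, function(k) {
      s <- sub; s$hurst_fix <- h; s$seed <- 4000 + 13 * k
      behavioural_dfa(extract_fixations(synth_gaze(s, 300, 500)))$exponent
    }, 0)
    mean(ex)
  }, 0)
  expect_true(all(diff(means) > 0))
})
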