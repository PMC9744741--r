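test_that("default cohort has the study composition and honors invariants", {
  co <- make_cohort(cohort_spec(seed = 7))
  expect_length(co, 40)
  groups <- vapply(co, `[[`, "", "group")
  expect_equal(sum(groups == "static"), 19)
  expect_equal(sum(groups == "dynamic"), 21)
  pc1 <- vapply(co, `[[`, 0, "pc1_score")
  expect_true(all(pc1[groups == "static"] > 1))
  expect_true(all(pc1[groups == "dynamic"] < -1))
  tab <- cohort_table(co)
  expect_true(all(tab$hurst_alpha >= 0.5 & tab$hurst_alpha < 1))
  expect_true(all(tab$hurst_fix >= 0.5 & tab$hurst_fix < 1))
  expect_true(all(tab$alpha_gain_eo > 0))
})

test_that("group means separate in the phenotype directions", {
  tab <- cohort_table(make_cohort(cohort_spec(n_static = 200, n_dynamic = 200, seed = 3)))
  st <- tab$group == "static"
  expect_gt(mean(tab$alpha_gain_eo[st]), mean(tab$alpha_gain_eo[!st]))
  expect_lt(mean(tab$iaf_true[st]), mean(tab$iaf_true[!st]))
  expect_lt(mean(tab$beta_gain[st]), mean(tab$beta_gain[!st]))
  expect_lt(mean(tab$gamma_gain[st]), mean(tab$gamma_gain[!st]))
  expect_gt(mean(tab$hurst_alpha[st]), mean(tab$hurst_alpha[!st]))
  expect_gt(mean(tab$hurst_fix[st]), mean(tab$hurst_fix[!st]))
  # eyes-closed alpha gain is the arousal control: identical distributions
  expect_lt(abs(mean(log(tab$alpha_gain_ec[st])) - mean(log(tab$alpha_gain_ec[!st]))), 0.15)
})

test_that("PC1 correlates with the generative parameters in the reported directions", {
  tab <- cohort_table(make_cohort(cohort_spec(seed = 1)))
  sp <- function(y) stats::cor(tab$pc1_score, y, method = "spearman")
  expect_lt(sp(tab$iaf_true), 0)
  expect_gt(sp(tab$alpha_gain_eo), 0)
  expect_lt(sp(tab$beta_gain), 0)
  expect_lt(sp(tab$gamma_gain), 0)
  expect_gt(sp(tab$hurst_alpha), 0)
  expect_gt(sp(tab$hurst_fix), 0)
})

test_that("cohort generation is deterministic and edge cases are handled", {
  s <- cohort_spec(seed = 9)
  expect_identical(cohort_table(make_cohort(s)), cohort_table(make_cohort(s)))
  expect_length(make_cohort(cohort_spec(n_static = 0, n_dynamic = 0)), 0)
  bad <- default_group_params()
  bad$static$hurst_alpha$mean <- 1.2
  expect_error(cohort_spec(group_params = bad), "hurst")
})

test_that("adding a subject does not perturb earlier subjects' draws", {
  a <- make_cohort(cohort_spec(n_static = 3, n_dynamic = 2, seed = 5))
  b <- make_cohort(cohort_spec(n_static = 3, n_dynamic = 3, seed = 5))
  expect_identical(cohort_table(a)[1:5, ], cohort_table(b)[1:5, ])
})
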