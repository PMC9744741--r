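groups40 <- factor(rep(c("static", "dynamic"), c(19, 21)), levels = c("static", "dynamic"))

test_that("permutation ANOVA is calibrated, floored and powered", {
  set.seed(1)
  p_null <- vapply(1:200, function(i) {
    perm_anova_global(rnorm(40), groups40, n_perm = 200, seed = i)$p_perm
  }, 0)
  expect_gt(mean(p_null > 0.05), 0.90)
  expect_true(all(p_null >= 1 / 201))

  shifted <- c(rnorm(19, 3), rnorm(21, 0))
  res <- perm_anova_global(shifted, groups40, n_perm = 1000, seed = 4)
  expect_equal(res$p_perm, 1 / 1001)
  expect_error(perm_anova_global(rnorm(3), factor(c("a", "a", "b"))), "n >= 2")
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(fdr_bh(0.03)$p_adjusted, 0.03)
  fam <- c(0.01, 0.02, 0.03, 0.04, 0.05)
  expect_equal(fdr_bh(fam)$p_adjusted, rep(0.05, 5))
  expect_true(all(fdr_bh(fam)$rejected))
  expect_equal(fdr_bh(rep(0.2, 4))$p_adjusted, rep(0.2, 4))
  expect_error(fdr_bh(numeric(0)), "empty")
})

test_that("permutation t-test is antisymmetric, deterministic and calibrated", {
  set.seed(2)
  v <- rnorm(40)
  a <- perm_ttest(v, groups40, seed = 5)
  b <- perm_ttest(v, factor(as.character(groups40), levels = c("dynamic", "static")),
                  seed = 5)
  expect_equal(a$statistic, -b$statistic)
  expect_identical(perm_ttest(v, groups40, seed = 7)$p_perm,
                   perm_ttest(v, groups40, seed = 7)$p_perm)
  rej <- mean(vapply(1:200, function(i) {
    perm_ttest(rnorm(40), groups40, n_perm = 200, seed = i)$p_perm < 0.05
  }, TRUE))
  expect_lt(rej, 0.10)
})

test_that("Spearman correlation matches hand-computed values", {
  expect_equal(spearman_cor(1:10, exp(1:10))$r, 1)
  expect_equal(spearman_cor(1:10, -(1:10)^3)$r, -1)
  res <- spearman_cor(1:5, c(1, 3, 2, 5, 4))
  expect_equal(res$r, 0.8)
  expect_lt(res$ci95[1], res$r)
  expect_gt(res$ci95[2], res$r)
  expect_error(spearman_cor(1:3, 1:3), "n >= 4")
})

test_that("cluster permutation t-test finds planted regional effects", {
  m <- make_montage(64)
  occ <- region_channels(m, "occipital")
  set.seed(3)
  maps <- matrix(rnorm(40 * 64), 40, 64, dimnames = list(NULL, m$labels))
  maps[groups40 == "static", occ] <- maps[groups40 == "static", occ] + 1.4
  res <- cluster_perm_ttest(maps, groups40, m, seed = 11)
  expect_true(any(res$significant))
  top <- res$clusters[[which(res$significant)[1]]]
  regs <- m$regions[match(top, m$labels)]
  expect_gt(mean(regs == "occipital"), 0.5)
  expect_equal(res$signs[which(res$significant)[1]], "+")

  # group means exactly equal on every channel -> nothing above threshold
  v <- c(rep(c(1, -1), 9), 0, rep(c(1, -1), 10), 0)
  balanced <- matrix(v, 40, 64, dimnames = list(NULL, m$labels))
  res0 <- cluster_perm_ttest(balanced, groups40, m, seed = 2)
  expect_length(res0$clusters, 0)

  expect_error(cluster_perm_ttest(matrix(0, 40, 3, dimnames = list(NULL, c("x", "y", "z"))),
                                  groups40, m), "montage")
})

test_that("face channels are excluded from cluster statistics", {
  m <- make_montage(64)
  maps <- matrix(rnorm(40 * 64), 40, 64, dimnames = list(NULL, m$labels))
  res <- cluster_perm_ttest(maps, groups40, m, seed = 1)
  expect_false(any(m$labels[m$regions == "face"] %in% names(res$stat_map)))
})

test_that("cluster correlation test localizes covariate-linked channels", {
  m <- make_montage(64)
  occ <- region_channels(m, "occipital")
  set.seed(4)
  cov <- rnorm(40)
  maps <- matrix(rnorm(40 * 64), 40, 64, dimnames = list(NULL, m$labels))
  maps[, occ] <- maps[, occ] + 1.1 * cov
  res <- cluster_perm_correlation(maps, cov, m, seed = 9)
  expect_true(any(res$significant))
  top <- res$clusters[[which(res$significant)[1]]]
  expect_gt(mean(m$regions[match(top, m$labels)] == "occipital"), 0.5)

  # sign reversal flips cluster signs, not sizes
  res2 <- cluster_perm_correlation(maps, -cov, m, seed = 9)
  expect_equal(res2$cluster_sizes, res$cluster_sizes)
  expect_equal(res2$signs, chartr("+-", "-+", res$signs))
  expect_error(cluster_perm_correlation(maps, rep(1, 40), m), "constant")
})

test_that("cluster correlation test is calibrated under the null", {
  m <- make_montage(64)
  hits <- vapply(1:40, function(i) {
    set.seed(100 + i)
    maps <- matrix(rnorm(40 * 64), 40, 64, dimnames = list(NULL, m$labels))
    any(cluster_perm_correlation(maps, rnorm(40), m, n_perm = 500,
                                 seed = 200 + i)$significant)
  }, TRUE)
  expect_lte(mean(hits), 0.125)
})
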