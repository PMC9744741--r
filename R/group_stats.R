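#' Permutation one-way ANOVA on per-subject scalars
#'
#' Observed one-way F statistic compared against a null distribution of F
#' recomputed under random group-label permutations. The permutation
#' p-value uses the add-one estimator
#' `p = (1 + #(F_perm >= F_obs)) / (n_perm + 1)`, so it is never below
#' `1/(n_perm + 1)`.
#'
#' @param values Numeric per-subject values.
#' @param groups Group labels (2+ groups, each n >= 2).
#' @param n_perm Number of permutations.
#' @param seed Integer seed; result is deterministic given the seed.
#' @return Object of class `perm_test_result`: `statistic`, `p_perm`,
#'   `n_perm`, `p_fdr` (NA until adjusted within a family).
#' @export
perm_anova_global <- function(values, groups, n_perm = 1000, seed = 1) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) stopf("perm_anova_global: need at least two groups")
  if (any(table(groups) < 2L)) stopf("perm_anova_global: every group needs n >= 2")
  f_obs <- anova_f(values, groups)
  f_null <- if (nlevels(groups) == 2L) {
    # vectorized two-group permutation null
    n <- length(values)
    n1 <- sum(groups == levels(groups)[1L])
    n2 <- n - n1
    I <- with_seed(seed, {
      matrix(vapply(seq_len(n_perm), function(i) sample.int(n) <= n1,
                    logical(n)), n, n_perm) + 0
    })
    s1 <- as.vector(crossprod(I, values))
    m <- mean(values)
    m1 <- s1 / n1; m2 <- (sum(values) - s1) / n2
    ssb <- n1 * (m1 - m)^2 + n2 * (m2 - m)^2
    sst <- sum((values - m)^2)
    (ssb / 1) / ((sst - ssb) / (n - 2))
  } else {
    with_seed(seed, replicate(n_perm, anova_f(values, sample(groups))))
  }
  p <- (1 + sum(f_null >= f_obs)) / (n_perm + 1)
  structure(list(statistic = f_obs, stat_name = "F", p_perm = p,
                 n_perm = n_perm, p_fdr = NA_real_),
            class = "perm_test_result")
}

anova_f <- function(values, groups) {
  n <- length(values)
  k <- nlevels(groups)
  gm <- tapply(values, groups, mean)
  gn <- tabulate(groups)
  ssb <- sum(gn * (gm - mean(values))^2)
  ssw <- sum((values - gm[as.integer(groups)])^2)
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' @export
print.perm_test_result <- function(x, ...) {
  cat(sprintf("<perm_test_result> %s = %.3f, p_perm = %.4g (%d permutations)%s\n",
              x$stat_name, x$statistic, x$p_perm, x$n_perm,
              if (is.na(x$p_fdr)) "" else sprintf(", p_fdr = %.4g", x$p_fdr)))
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (with monotonicity enforcement) and the
#' rejection set at level `q`. Thin wrapper over `stats::p.adjust`.
#'
#' @param pvals Family of p-values.
#' @param q FDR level.
#' @return List with `p_adjusted` and logical `rejected`.
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  if (!length(pvals)) stopf("fdr_bh: empty p-value family")
  adj <- stats::p.adjust(pvals, method = "BH")
  list(p_adjusted = adj, rejected = adj <= q)
}

#' Permutation two-sample t-test
#'
#' Pooled-variance independent-samples t, with a two-tailed permutation
#' p-value from `n_perm` label permutations (add-one estimator on |t|).
#'
#' @param values Numeric per-subject values.
#' @param groups Two group labels.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return A `perm_test_result`.
#' @export
perm_ttest <- function(values, groups, n_perm = 1000, seed = 1) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stopf("perm_ttest: exactly two groups required")
  if (any(table(groups) < 2L)) stopf("perm_ttest: every group needs n >= 2")
  t_obs <- pooled_t(values, groups)
  n <- length(values)
  n1 <- sum(groups == levels(groups)[1L]); n2 <- n - n1
  I <- with_seed(seed, {
    matrix(vapply(seq_len(n_perm), function(i) sample.int(n) <= n1,
                  logical(n)), n, n_perm) + 0
  })
  s1 <- as.vector(crossprod(I, values))
  q1 <- as.vector(crossprod(I, values^2))
  m1 <- s1 / n1; m2 <- (sum(values) - s1) / n2
  v1 <- (q1 - n1 * m1^2) / (n1 - 1)
  v2 <- (sum(values^2) - q1 - n2 * m2^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n - 2)
  t_null <- abs((m1 - m2) / sqrt(pmax(sp2, 1e-300) * (1 / n1 + 1 / n2)))
  p <- (1 + sum(t_null >= abs(t_obs))) / (n_perm + 1)
  structure(list(statistic = t_obs, stat_name = "t", p_perm = p,
                 n_perm = n_perm, p_fdr = NA_real_),
            class = "perm_test_result")
}

pooled_t <- function(values, groups) {
  i1 <- groups == levels(groups)[1L]
  x <- values[i1]; y <- values[!i1]
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

#' Spearman rank correlation with t-approximation inference
#'
#' Rank correlation with average ranks for ties, two-sided p-value via the
#' t approximation `t = r * sqrt((n-2)/(1-r^2))`, and a 95% confidence
#' interval from the Fisher z-transform.
#'
#' @param x,y Numeric vectors (n >= 4).
#' @return Object of class `correlation_result`: `r`, `p`, `ci95`, `n`.
#' @export
spearman_cor <- function(x, y) {
  n <- length(x)
  if (n < 4L || length(y) != n) stopf("spearman_cor: need paired vectors with n >= 4")
  r <- stats::cor(rank(x), rank(y))
  tt <- r * sqrt((n - 2) / max(1e-12, 1 - r^2))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  z <- atanh(min(max(r, -1 + 1e-12), 1 - 1e-12))
  ci <- tanh(z + c(-1, 1) * 1.959964 / sqrt(n - 3))
  structure(list(r = r, p = p, ci95 = ci, n = n), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> r = %.3f, p = %.4g, 95%% CI [%.3f, %.3f], n = %d\n",
              x$r, x$p, x$ci95[1], x$ci95[2], x$n))
  invisible(x)
}

# Connected components of the channel subset `idx` in adjacency `nb`
# (logical matrix). Returns a list of integer vectors.
components_in <- function(idx, nb) {
  if (!length(idx)) return(list())
  remaining <- idx
  comps <- list()
  while (length(remaining)) {
    queue <- remaining[1L]
    comp <- queue
    remaining <- remaining[-1L]
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nbrs <- remaining[nb[v, remaining]]
      if (length(nbrs)) {
        comp <- c(comp, nbrs)
        queue <- c(queue, nbrs)
        remaining <- setdiff(remaining, nbrs)
      }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

# max cluster size over both signs for a vector of channel statistics
max_cluster_size <- function(stat, crit, nb) {
  above <- which(stat > crit)
  below <- which(stat < -crit)
  m <- 0L
  if (length(above)) m <- max(m, max(lengths(components_in(above, nb))))
  if (length(below)) m <- max(m, max(lengths(components_in(below, nb))))
  m
}

#' Cluster-based permutation t-test on scalp maps
#'
#' Per-channel two-sample pooled-variance t-tests; channels exceeding the
#' two-tailed critical value at `cluster_alpha` form candidate clusters
#' through the montage neighbor graph, split by sign. Each observed
#' cluster's size (channel count) is compared against the permutation null
#' of the maximum cluster size over the map (group labels permuted), with
#' the add-one estimator; a cluster is significant when its p-value is
#' below `alpha`. Face channels are excluded before testing.
#'
#' @param maps Subjects x channels matrix (column names = channel labels).
#' @param groups Two group labels per subject.
#' @param montage An `eeg_montage`.
#' @param cluster_alpha Cluster-forming threshold (two-tailed).
#' @param alpha Cluster significance level.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return Object of class `cluster_result`: list of clusters (channel
#'   labels), `cluster_sizes`, `signs`, `cluster_p`, `significant`, plus
#'   the per-channel statistic map.
#' @export
cluster_perm_ttest <- function(maps, groups, montage, cluster_alpha = 0.01,
                               alpha = 0.05, n_perm = 1000, seed = 1) {
  cluster_perm_engine(maps, montage, cluster_alpha, alpha, n_perm, seed,
                      mode = "ttest", groups = as.factor(groups))
}

#' Cluster-based permutation test of map-covariate correlation
#'
#' Per-channel Spearman rank correlation between the map values and a
#' per-subject covariate; the cluster-forming threshold is the |r|
#' corresponding to the two-tailed `cluster_alpha` critical value of the t
#' approximation at the sample size. The null permutes the covariate
#' across subjects; correction is by maximum cluster size as in
#' [cluster_perm_ttest()].
#'
#' @param maps Subjects x channels matrix.
#' @param covariate Per-subject scalar (not constant).
#' @param montage An `eeg_montage`.
#' @param cluster_alpha,alpha,n_perm,seed As in [cluster_perm_ttest()].
#' @return A `cluster_result`.
#' @export
cluster_perm_correlation <- function(maps, covariate, montage, cluster_alpha = 0.01,
                                     alpha = 0.05, n_perm = 1000, seed = 1) {
  if (stats::sd(covariate) == 0) stopf("cluster_perm_correlation: covariate is constant")
  cluster_perm_engine(maps, montage, cluster_alpha, alpha, n_perm, seed,
                      mode = "correlation", covariate = covariate)
}

cluster_perm_engine <- function(maps, montage, cluster_alpha, alpha, n_perm, seed,
                                mode, groups = NULL, covariate = NULL) {
  stopifnot(inherits(montage, "eeg_montage"))
  maps <- as.matrix(maps)
  if (is.null(colnames(maps))) colnames(maps) <- montage$labels
  if (!all(colnames(maps) %in% montage$labels)) {
    stopf("cluster_perm: map channels not found in the montage")
  }
  keep <- colnames(maps)[montage$regions[match(colnames(maps), montage$labels)] != "face"]
  maps <- maps[, keep, drop = FALSE]
  nb <- montage$neighbors[match(keep, montage$labels), match(keep, montage$labels)]
  n <- nrow(maps)

  # observed statistics and a channels x n_perm matrix of permutation
  # statistics, computed by matrix algebra
  if (mode == "ttest") {
    if (nlevels(groups) != 2L) stopf("cluster_perm_ttest: exactly two groups required")
    n1 <- sum(groups == levels(groups)[1L]); n2 <- n - n1
    crit <- stats::qt(1 - cluster_alpha / 2, df = n - 2)
    obs <- channel_t(maps, as.integer(groups) == 1L)
    I <- with_seed(seed, {
      matrix(vapply(seq_len(n_perm), function(i) sample.int(n) <= n1,
                    logical(n)), n, n_perm) + 0
    })
    S1 <- crossprod(maps, I)                 # channels x n_perm group-1 sums
    Q1 <- crossprod(maps^2, I)
    m1 <- S1 / n1
    m2 <- (colSums(maps) - S1) / n2
    v1 <- (Q1 - n1 * m1^2) / (n1 - 1)
    v2 <- (colSums(maps^2) - Q1 - n2 * m2^2) / (n2 - 1)
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n - 2)
    Tn <- (m1 - m2) / sqrt(pmax(sp2, 1e-300) * (1 / n1 + 1 / n2))
  } else {
    crit_t <- stats::qt(1 - cluster_alpha / 2, df = n - 2)
    crit <- crit_t / sqrt(n - 2 + crit_t^2)   # critical |r|
    Rz <- scale(apply(maps, 2, rank))
    rcz <- as.vector(scale(rank(covariate)))
    obs <- as.vector(crossprod(Rz, rcz)) / (n - 1)
    P <- with_seed(seed, {
      matrix(vapply(seq_len(n_perm), function(i) rcz[sample.int(n)],
                    numeric(n)), n, n_perm)
    })
    Tn <- crossprod(Rz, P) / (n - 1)
  }
  obs[is.na(obs)] <- 0
  Tn[is.na(Tn)] <- 0

  pos <- components_in(which(obs > crit), nb)
  neg <- components_in(which(obs < -crit), nb)
  clusters <- c(pos, neg)
  signs <- c(rep("+", length(pos)), rep("-", length(neg)))
  sizes <- lengths(clusters)

  n_above <- colSums(Tn > crit) + colSums(Tn < -crit)
  null_max <- integer(n_perm)
  for (i in which(n_above > 0L)) {
    null_max[i] <- if (n_above[i] == 1L) 1L else max_cluster_size(Tn[, i], crit, nb)
  }
  cluster_p <- vapply(sizes, function(sz) (1 + sum(null_max >= sz)) / (n_perm + 1), 0)

  ord <- order(sizes, decreasing = TRUE)
  structure(list(
    clusters = lapply(clusters[ord], function(ix) keep[ix]),
    cluster_sizes = sizes[ord], signs = signs[ord], cluster_p = cluster_p[ord],
    significant = cluster_p[ord] < alpha,
    cluster_alpha = cluster_alpha, alpha = alpha, n_perm = n_perm,
    stat_map = stats::setNames(obs, keep), forming_threshold = crit,
    mode = mode), class = "cluster_result")
}

# vectorized per-channel pooled-variance two-sample t
channel_t <- function(maps, in1) {
  n1 <- sum(in1); n2 <- sum(!in1)
  m1 <- colMeans(maps[in1, , drop = FALSE])
  m2 <- colMeans(maps[!in1, , drop = FALSE])
  v1 <- (colSums(maps[in1, , drop = FALSE]^2) - n1 * m1^2) / (n1 - 1)
  v2 <- (colSums(maps[!in1, , drop = FALSE]^2) - n2 * m2^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  (m1 - m2) / sqrt(pmax(sp2, 1e-300) * (1 / n1 + 1 / n2))
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %s; %d cluster(s) above |stat| threshold %.3f\n",
              x$mode, length(x$clusters), x$forming_threshold))
  for (i in seq_along(x$clusters)) {
    cat(sprintf("  [%s] size %d, p = %.4g%s\n", x$signs[i], x$cluster_sizes[i],
                x$cluster_p[i], if (x$significant[i]) " *" else ""))
  }
  invisible(x)
}
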