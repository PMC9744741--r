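#' Cohort specification for the synthetic study
#'
#' Describes the simulated study conditions: group sizes, recording lengths,
#' sampling rates, and per-group distributions of the generative parameters.
#' Defaults emulate a two-group resting-state study with 19 "static" viewers
#' (long fixations, PC1 > 1) and 21 "dynamic" viewers (short fixations,
#' PC1 < -1): static viewers carry stronger eyes-open occipital alpha,
#' weaker beta/gamma, a lower individual alpha frequency (group medians
#' 9.5 vs 10.5 Hz), and stronger long-range temporal correlations in both
#' the alpha envelope and fixation behaviour. Eyes-closed alpha gain is
#' drawn from the same distribution in both groups (arousal control).
#'
#' Each group entry gives, per parameter, the sampling distribution used by
#' [make_cohort()]: normal (`mean`/`sd`, with clipping bounds where stated)
#' or log-normal (`meanlog`/`sdlog`).
#'
#' @param n_static,n_dynamic Group sizes.
#' @param seed Integer seed for cohort generation.
#' @param duration_s EEG duration per condition (seconds).
#' @param gaze_duration_s Gaze-trace duration (seconds).
#' @param fs_eeg,fs_gaze Sampling rates (Hz).
#' @param group_params Named list with entries `static` and `dynamic`; see
#'   `default_group_params()`. Each is validated for Hurst exponents in
#'   [0.5, 1) and positive rates.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_static = 19, n_dynamic = 21, seed = 1,
                        duration_s = 90, gaze_duration_s = 600,
                        fs_eeg = 250, fs_gaze = 500,
                        group_params = default_group_params()) {
  n_static <- as.integer(n_static); n_dynamic <- as.integer(n_dynamic)
  if (is.na(n_static) || n_static < 0L || is.na(n_dynamic) || n_dynamic < 0L) {
    stopf("cohort_spec: group counts must be >= 0")
  }
  if (fs_eeg <= 2 * 45) stopf("cohort_spec: fs_eeg must exceed twice the highest synthesized frequency (45 Hz)")
  if (duration_s <= 0 || gaze_duration_s <= 0) stopf("cohort_spec: durations must be positive")
  for (g in c("static", "dynamic")) {
    p <- group_params[[g]]
    if (is.null(p)) stopf("cohort_spec: group_params must contain '%s'", g)
    for (hn in c("hurst_alpha", "hurst_fix")) {
      h <- p[[hn]]
      if (h$mean < 0.5 || h$mean >= 1) stopf("cohort_spec: %s mean must lie in [0.5, 1)", hn)
      if (h$lo < 0.5 || h$hi >= 1) stopf("cohort_spec: %s clip bounds must lie in [0.5, 1)", hn)
    }
  }
  structure(list(n_static = n_static, n_dynamic = n_dynamic, seed = as.integer(seed),
                 duration_s = duration_s, gaze_duration_s = gaze_duration_s,
                 fs_eeg = fs_eeg, fs_gaze = fs_gaze, group_params = group_params),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_group_params <- function() {
  list(
    static = list(
      iaf_hz          = list(mean = 9.5,  sd = 0.6, lo = 8.9, hi = 10.9),
      alpha_gain_eo   = list(meanlog = log(1.30), sdlog = 0.22),
      alpha_gain_ec   = list(meanlog = log(1.60), sdlog = 0.50),
      beta_gain       = list(meanlog = log(0.55), sdlog = 0.30),
      gamma_gain      = list(meanlog = log(0.28), sdlog = 0.35),
      hurst_alpha     = list(mean = 0.82, sd = 0.065, lo = 0.55, hi = 0.95),
      hurst_fix       = list(mean = 0.85, sd = 0.045, lo = 0.55, hi = 0.95),
      fixation_log_mean = list(mean = log(0.35), sd = 0.15),
      fixation_log_sd = 0.85,
      saccade_dur_ms  = list(mean = 30, sd = 4)
    ),
    dynamic = list(
      iaf_hz          = list(mean = 10.5, sd = 0.6, lo = 8.9, hi = 10.9),
      alpha_gain_eo   = list(meanlog = log(0.78), sdlog = 0.22),
      alpha_gain_ec   = list(meanlog = log(1.60), sdlog = 0.50),
      beta_gain       = list(meanlog = log(0.80), sdlog = 0.30),
      gamma_gain      = list(meanlog = log(0.42), sdlog = 0.35),
      hurst_alpha     = list(mean = 0.62, sd = 0.065, lo = 0.55, hi = 0.95),
      hurst_fix       = list(mean = 0.65, sd = 0.045, lo = 0.55, hi = 0.95),
      fixation_log_mean = list(mean = log(0.22), sd = 0.15),
      fixation_log_sd = 0.85,
      saccade_dur_ms  = list(mean = 30, sd = 4)
    )
  )
}

# correlation between the within-group phenotype depth latent and each
# generative parameter's latent normal
.pc1_rho <- 0.9

#' Generate a phenotyped synthetic cohort
#'
#' Draws `n_static + n_dynamic` subject records with ground-truth generative
#' parameters. Per subject, a latent "phenotype depth" normal drives both
#' the PC1 score (static: > 1; dynamic: < -1) and, with correlation 0.9, the
#' subject's deviations from the group means, so that across the cohort PC1
#' correlates positively with eyes-open alpha gain and both Hurst exponents,
#' and negatively with IAF, beta gain and gamma gain.
#'
#' @param spec A [cohort_spec()].
#' @return List of `subject_record` objects (class `cohort`), each with
#'   fields `subject_id`, `group`, `pc1_score`, `iaf_true`, `alpha_gain_eo`,
#'   `alpha_gain_ec`, `beta_gain`, `gamma_gain`, `hurst_alpha`, `hurst_fix`,
#'   `fixation_log_mean`, `fixation_log_sd`, `saccade_dur_ms`, `seed`.
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- c(rep("static", spec$n_static), rep("dynamic", spec$n_dynamic))
  n <- length(groups)
  records <- vector("list", n)
  for (i in seq_len(n)) {
    records[[i]] <- make_subject(spec, i, groups[i])
  }
  structure(records, class = "cohort")
}

make_subject <- function(spec, i, group) {
  p <- spec$group_params[[group]]
  sgn <- if (group == "static") 1 else -1
  rho <- .pc1_rho
  with_seed(derive_seed(spec$seed, 101L, i), {
    u <- rnorm(1)                       # phenotype depth within group
    pc1 <- sgn * (1 + exp(0.2 + 0.6 * u))
    w <- u                               # pc1 is increasing in w within group
    lat <- function(s) s * rho * w + sqrt(1 - rho^2) * rnorm(1)
    draw_norm <- function(d, s) {
      v <- d$mean + d$sd * lat(s)
      if (!is.null(d$lo)) v <- min(max(v, d$lo), d$hi)
      v
    }
    draw_lnorm <- function(d, s) exp(d$meanlog + d$sdlog * lat(s))
    rec <- list(
      subject_id = sprintf("S%03d", i),
      group = group,
      pc1_score = pc1,
      iaf_true = draw_norm(p$iaf_hz, -1),
      alpha_gain_eo = draw_lnorm(p$alpha_gain_eo, +1),
      alpha_gain_ec = draw_lnorm(p$alpha_gain_ec, 0),
      beta_gain = draw_lnorm(p$beta_gain, -1),
      gamma_gain = draw_lnorm(p$gamma_gain, -1),
      hurst_alpha = draw_norm(p$hurst_alpha, +1),
      hurst_fix = draw_norm(p$hurst_fix, +1),
      fixation_log_mean = p$fixation_log_mean$mean + p$fixation_log_mean$sd * lat(+1),
      fixation_log_sd = p$fixation_log_sd,
      saccade_dur_ms = max(10, p$saccade_dur_ms$mean + p$saccade_dur_ms$sd * rnorm(1)),
      seed = derive_seed(spec$seed, 202L, i)
    )
    structure(rec, class = "subject_record")
  })
}

#' @export
print.cohort <- function(x, ...) {
  tab <- table(vapply(x, `[[`, "", "group"))
  cat(sprintf("<cohort> %d subjects (%s)\n", length(x),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("<subject_record> %s [%s] PC1=%.2f IAF=%.2f Hz H_alpha=%.2f H_fix=%.2f\n",
              x$subject_id, x$group, x$pc1_score, x$iaf_true, x$hurst_alpha, x$hurst_fix))
  invisible(x)
}

#' Cohort ground truth as a data frame / CSV
#'
#' @param cohort A `cohort`.
#' @return Data frame with one row per subject and all ground-truth fields.
#' @export
cohort_table <- function(cohort) {
  do.call(rbind, lapply(cohort, function(r) {
    data.frame(subject_id = r$subject_id, group = r$group, pc1_score = r$pc1_score,
               iaf_true = r$iaf_true, alpha_gain_eo = r$alpha_gain_eo,
               alpha_gain_ec = r$alpha_gain_ec, beta_gain = r$beta_gain,
               gamma_gain = r$gamma_gain, hurst_alpha = r$hurst_alpha,
               hurst_fix = r$hurst_fix, fixation_log_mean = r$fixation_log_mean,
               fixation_log_sd = r$fixation_log_sd, saccade_dur_ms = r$saccade_dur_ms,
               stringsAsFactors = FALSE)
  }))
}

#' @param cohort A `cohort`.
#' @param path CSV path.
#' @rdname cohort_table
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort_table(cohort), path, row.names = FALSE)
  invisible(path)
}
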