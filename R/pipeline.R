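#' Study configuration
#'
#' One serializable object holding every knob of a simulated study run:
#' cohort composition, preprocessing, spectral, DFA and statistics
#' parameters, plus the single global seed from which all per-subject and
#' per-test random streams are derived (counter-based fan-out, so adding a
#' subject does not perturb the others' data).
#'
#' @param seed Global integer seed.
#' @param n_static,n_dynamic Group sizes.
#' @param duration_s Eyes-open EEG duration (s).
#' @param duration_ec_s Eyes-closed EEG duration (s); the eyes-closed
#'   recording serves spectral endpoints (band power, IAF) and needs less
#'   data than the eyes-open scaling analyses.
#' @param gaze_duration_s Gaze-trace duration (s).
#' @param fs_eeg,fs_gaze Sampling rates (Hz).
#' @param n_channels Montage size.
#' @param run_preprocess Apply the preprocessing chain to each recording.
#' @param norm_range Relative-power normalization range (Hz).
#' @param iaf_range IAF search range (Hz).
#' @param envelope_band,envelope_order Alpha-envelope band (Hz) and FIR order.
#' @param env_decimate Envelope decimation factor before DFA (mean pooling;
#'   the envelope is band-limited far below the decimated Nyquist).
#' @param dfa_n_scales,dfa_overlap DFA scale count and window overlap.
#' @param n_perm,cluster_alpha,alpha Statistics parameters.
#' @param dfa_conditions Conditions for which alpha-envelope DFA is run.
#' @param group_params Generator distributions (see [default_group_params()]).
#' @param output_dir Optional directory for report files.
#' @return Object of class `study_config`.
#' @export
study_config <- function(seed = 1, n_static = 19, n_dynamic = 21,
                         duration_s = 90, duration_ec_s = 45,
                         gaze_duration_s = 600,
                         fs_eeg = 250, fs_gaze = 500, n_channels = 64,
                         run_preprocess = TRUE,
                         norm_range = c(1, 45), iaf_range = c(7, 13),
                         envelope_band = c(7.5, 12), envelope_order = 66,
                         env_decimate = 10, dfa_n_scales = 15, dfa_overlap = 0.5,
                         n_perm = 1000, cluster_alpha = 0.01, alpha = 0.05,
                         dfa_conditions = "eyes_open",
                         group_params = default_group_params(),
                         output_dir = NULL) {
  cfg <- as.list(environment())
  structure(cfg, class = "study_config")
}

#' Write / read a study configuration as YAML
#'
#' @param config A `study_config`.
#' @param path YAML file path.
#' @rdname config_io
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname config_io
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(study_config, raw[names(raw) %in% names(formals(study_config))])
}

#' Run the full simulated study
#'
#' Generates (or accepts) a phenotyped cohort, synthesizes eyes-open and
#' eyes-closed EEG plus gaze traces per subject, preprocesses, computes
#' spectra, relative band power, IAF, alpha-envelope DFA and behavioural
#' DFA, and runs the full inference layer: per-band permutation ANOVAs with
#' FDR, cluster-based permutation tests on the alpha/beta/gamma scalp maps,
#' PC1 correlations in the dominant significant clusters, the IAF group test and PC1
#' correlation, brain-behaviour DFA correlations (global and cluster
#' level), and the arousal control contrasts (eyes-closed alpha, alpha
#' reactivity). Subjects whose processing fails are excluded with a logged
#' reason.
#'
#' @param config A [study_config()].
#' @param cohort Optional pre-built `cohort` (defaults to generating one
#'   from the config).
#' @return Object of class `study_report`.
#' @export
run_study <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "study_config"))
  montage <- make_montage(config$n_channels)
  if (is.null(cohort)) {
    spec <- cohort_spec(config$n_static, config$n_dynamic, seed = config$seed,
                        duration_s = config$duration_s,
                        gaze_duration_s = config$gaze_duration_s,
                        fs_eeg = config$fs_eeg, fs_gaze = config$fs_gaze,
                        group_params = config$group_params)
    cohort <- make_cohort(spec)
  }
  n <- length(cohort)
  labels <- montage$labels
  conds <- c("eyes_open", "eyes_closed")

  per <- vector("list", n)
  excluded <- list()
  for (i in seq_len(n)) {
    sub <- cohort[[i]]
    res <- tryCatch(process_subject(sub, montage, config), error = function(e) e)
    if (inherits(res, "error")) {
      excluded[[sub$subject_id]] <- conditionMessage(res)
    } else {
      per[[i]] <- res
    }
  }
  keep <- which(!vapply(per, is.null, TRUE))
  per <- per[keep]
  cohort_kept <- cohort[keep]
  groups <- factor(vapply(cohort_kept, `[[`, "", "group"), levels = c("static", "dynamic"))
  pc1 <- vapply(cohort_kept, `[[`, 0, "pc1_score")
  bands <- default_bands()

  # --- band-level permutation ANOVAs, FDR within condition
  band_tests <- list()
  for (cond in conds) {
    tests <- lapply(seq_len(nrow(bands)), function(b) {
      vals <- vapply(per, function(s) mean(s$relpow[[cond]][, bands$name[b]]), 0)
      perm_anova_global(vals, groups, n_perm = config$n_perm,
                        seed = derive_seed(config$seed, 301L, match(cond, conds), b))
    })
    adj <- fdr_bh(vapply(tests, `[[`, 0, "p_perm"), q = config$alpha)
    for (b in seq_along(tests)) tests[[b]]$p_fdr <- adj$p_adjusted[b]
    names(tests) <- bands$name
    band_tests[[cond]] <- tests
  }

  # --- scalp-level cluster tests + PC1 correlations. The alpha, beta and
  # gamma bands are always tested at the scalp level (the bands carrying
  # the phenotype contrasts); the global band ANOVAs above are reported
  # alongside rather than used as a gate, since the cluster statistic
  # carries its own family-wise error control.
  cluster_tests <- list()
  for (cond in conds) {
    res <- list()
    for (bn in c("alpha", "beta", "gamma")) {
      maps <- t(vapply(per, function(s) s$relpow[[cond]][, bn], numeric(length(labels))))
      colnames(maps) <- labels
      cl <- cluster_perm_ttest(maps, groups, montage,
                               cluster_alpha = config$cluster_alpha,
                               alpha = config$alpha, n_perm = config$n_perm,
                               seed = derive_seed(config$seed, 401L, match(cond, conds),
                                                  match(bn, bands$name)))
      chans <- peak_cluster(cl)
      pc1_cor <- if (!is.null(chans)) {
        spearman_cor(pc1, rowMeans(maps[, chans, drop = FALSE]))
      } else NULL
      res[[bn]] <- list(cluster = cl, pc1_correlation = pc1_cor)
    }
    cluster_tests[[cond]] <- res
  }

  # --- IAF: group permutation t-test + PC1 correlation (true peaks only)
  iaf_all <- vapply(per, function(s) s$iaf$iaf, 0)
  true_peak <- vapply(per, function(s) s$iaf$is_true_peak, TRUE)
  iaf_res <- if (sum(true_peak) >= 4 && nlevels(droplevels(groups[true_peak])) == 2) {
    list(values = iaf_all, true_peak = true_peak,
         group_test = perm_ttest(iaf_all[true_peak], groups[true_peak],
                                 n_perm = config$n_perm,
                                 seed = derive_seed(config$seed, 501L)),
         pc1_correlation = spearman_cor(pc1[true_peak], iaf_all[true_peak]))
  } else list(values = iaf_all, true_peak = true_peak,
              group_test = NULL, pc1_correlation = NULL)

  # --- DFA: brain vs behaviour
  behav_exp <- vapply(per, function(s) s$behav_dfa$exponent, 0)
  dfa_res <- list(behavioural_exponents = behav_exp,
                  behavioural_range = range(behav_exp))
  for (cond in intersect(config$dfa_conditions, conds)) {
    maps <- t(vapply(per, function(s) s$env_exponents[[cond]], numeric(length(labels))))
    colnames(maps) <- labels
    scalp <- montage$regions != "face"
    mean_exp <- rowMeans(maps)
    glob <- spearman_cor(mean_exp, behav_exp)
    cl <- cluster_perm_correlation(maps, behav_exp, montage,
                                   cluster_alpha = config$cluster_alpha,
                                   alpha = config$alpha, n_perm = config$n_perm,
                                   seed = derive_seed(config$seed, 601L, match(cond, conds)))
    chans <- peak_cluster(cl)
    cl_cor <- if (!is.null(chans)) {
      spearman_cor(rowMeans(maps[, chans, drop = FALSE]), behav_exp)
    } else NULL
    grp <- perm_ttest(mean_exp, groups, n_perm = config$n_perm,
                      seed = derive_seed(config$seed, 602L, match(cond, conds)))
    dfa_res[[cond]] <- list(mean_exponents = mean_exp, global_correlation = glob,
                            cluster = cl, cluster_correlation = cl_cor,
                            group_test = grp)
  }

  # --- controls: eyes-closed alpha and alpha reactivity
  ec_alpha <- vapply(per, function(s) mean(s$relpow$eyes_closed[, "alpha"]), 0)
  react <- vapply(per, function(s) {
    as.numeric(alpha_reactivity(s$relpow$eyes_open, s$relpow$eyes_closed))
  }, 0)
  controls <- list(
    ec_alpha_test = perm_ttest(ec_alpha, groups, n_perm = config$n_perm,
                               seed = derive_seed(config$seed, 701L)),
    reactivity_test = perm_ttest(react, groups, n_perm = config$n_perm,
                                 seed = derive_seed(config$seed, 702L)),
    reactivity_orientation = "eo_over_ec")

  report <- structure(list(
    config = config, montage = montage,
    subjects = data.frame(subject_id = vapply(cohort_kept, `[[`, "", "subject_id"),
                          group = as.character(groups), pc1_score = pc1,
                          iaf = iaf_all, iaf_true_peak = true_peak,
                          behavioural_exponent = behav_exp,
                          stringsAsFactors = FALSE),
    excluded = excluded,
    band_tests = band_tests, cluster_tests = cluster_tests,
    iaf = iaf_res, dfa = dfa_res, controls = controls,
    seed = config$seed, n_perm = config$n_perm), class = "study_report")
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

process_subject <- function(sub, montage, config) {
  out <- list(relpow = list(), env_exponents = list())
  for (cond in c("eyes_open", "eyes_closed")) {
    dur <- if (cond == "eyes_open") config$duration_s else config$duration_ec_s
    rec <- synth_eeg(sub, montage, cond, duration_s = dur,
                     fs = config$fs_eeg)
    if (isTRUE(config$run_preprocess)) {
      rec <- preprocess(rec, montage, target_fs = config$fs_eeg)$recording
    }
    ps <- welch_psd(rec, resolution = 0.5)
    out$relpow[[cond]] <- relative_power(ps, norm_range = config$norm_range)
    if (cond == "eyes_closed") {
      out$iaf <- detect_iaf(ps, montage, config$iaf_range[1], config$iaf_range[2])
    }
    if (cond %in% config$dfa_conditions) {
      out$env_exponents[[cond]] <- envelope_exponents(rec, config)
    }
  }
  gaze <- synth_gaze(sub, duration_s = config$gaze_duration_s,
                     fs_gaze = config$fs_gaze)
  fix <- extract_fixations(gaze)
  # pool the binary series to ~50 Hz occupancy before DFA: identical
  # scaling over the 2-100 s analysis range at a tenth of the cost
  dec <- max(1L, as.integer(round(fix$fs / 50)))
  if (dec > 1L) {
    nb <- length(fix$states) %/% dec
    pooled <- colMeans(matrix(as.numeric(fix$states[seq_len(nb * dec)]), dec))
    fs_p <- fix$fs / dec
    out$behav_dfa <- dfa(pooled, scale_lo = round(2 * fs_p),
                         scale_hi = min(round(100 * fs_p), floor(nb / 4)),
                         n_scales = config$dfa_n_scales,
                         overlap = config$dfa_overlap)
  } else {
    out$behav_dfa <- behavioural_dfa(fix, n_scales = config$dfa_n_scales,
                                     overlap = config$dfa_overlap)
  }
  out
}

# Per-channel alpha-envelope DFA exponents. The analytic signal of the
# band-passed data is band-limited below fs / (2 * env_decimate), so its
# decimated samples are computed exactly by truncating the one-sided
# spectrum (frequency-domain decimation); the envelope magnitude is then
# taken at the reduced rate, edges are trimmed, and DFA runs on the
# decimated envelope. Identical multi-second scaling at a fraction of the
# cost of the full-rate envelope.
envelope_exponents <- function(rec, config) {
  n <- ncol(rec$data)
  dec <- max(1L, as.integer(config$env_decimate))
  order <- as.integer(config$envelope_order)
  if (order %% 2L != 0L) order <- order + 1L
  h <- as.numeric(signal::fir1(order, config$envelope_band / (rec$fs / 2), type = "pass"))
  d <- order %/% 2L
  hpad <- c(h[(d + 1L):(order + 1L)], rep(0, n - order - 1L), h[1:d])
  A <- Re(fft(hpad))                     # zero-phase amplitude response
  m8 <- n %/% dec
  stopifnot(config$envelope_band[2] < rec$fs / (2 * dec))
  Fm <- mvfft_real(t(rec$data)) * (A * analytic_mask(n))
  C <- nrow(rec$data)
  E <- matrix(0, m8, C)
  for (ch in seq_len(C)) {
    E[, ch] <- Mod(fft(Fm[seq_len(m8), ch], inverse = TRUE))
  }
  tr <- ceiling(d / dec) + 1L
  E <- E[(tr + 1L):(m8 - tr), , drop = FALSE]
  fs_env <- rec$fs / dec
  sc <- dfa_default_scales(nrow(E), fs_env)
  res <- dfa(E, scale_lo = sc[1], scale_hi = sc[2],
             n_scales = config$dfa_n_scales, overlap = config$dfa_overlap)
  stats::setNames(vapply(res, `[[`, 0, "exponent"), rec$labels)
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d subjects (%d excluded), seed %d, %d permutations\n",
              nrow(x$subjects), length(x$excluded), x$seed, x$n_perm))
  for (cond in names(x$band_tests)) {
    sig <- names(which(vapply(x$band_tests[[cond]], `[[`, 0, "p_fdr") <= x$config$alpha))
    cat(sprintf("  %s bands significant after FDR: %s\n", cond,
                if (length(sig)) paste(sig, collapse = ", ") else "none"))
  }
  invisible(x)
}

# The cluster whose member channels include the peak |statistic| channel:
# the dominant effect of the map, the cluster a study would report. NULL
# when that cluster is not significant (or no cluster formed).
peak_cluster <- function(cl) {
  if (!length(cl$clusters) || !any(cl$significant)) return(NULL)
  peak <- names(cl$stat_map)[which.max(abs(cl$stat_map))]
  hit <- which(vapply(cl$clusters, function(ch) peak %in% ch, TRUE))
  if (length(hit) && cl$significant[hit[1]]) cl$clusters[[hit[1]]] else NULL
}

#' Direction checks on a study report
#'
#' Evaluates the headline sign pattern: PC1 versus significant-cluster
#' alpha power positive; versus beta and gamma cluster power negative;
#' versus IAF negative; eyes-open brain-vs-behaviour DFA correlation
#' positive (with p < 0.05). Conclusiveness gates mirror the analysis
#' sequence: a band direction needs a significant dominant cluster; the
#' IAF direction needs a significant IAF group difference (the PC1
#' correlation then confirms the direction); the DFA direction needs the
#' brain-behaviour correlation itself significant. Each effect is `pass`
#' when its gate is met and the sign matches, `fail` when the gate is met
#' with the opposite sign, and `inconclusive` otherwise (as in a null
#' cohort).
#'
#' @param report A `study_report`.
#' @return Data frame with columns `effect`, `status`, `value`.
#' @export
check_directions <- function(report) {
  stopifnot(inherits(report, "study_report"))
  rows <- list()
  add <- function(effect, status, value) {
    rows[[length(rows) + 1L]] <<- data.frame(effect = effect, status = status,
                                             value = value, stringsAsFactors = FALSE)
  }
  cl_eo <- report$cluster_tests$eyes_open
  for (spec in list(c("alpha", "+"), c("beta", "-"), c("gamma", "-"))) {
    bn <- spec[1]; want <- spec[2]
    entry <- cl_eo[[bn]]
    if (is.null(entry) || is.null(entry$pc1_correlation)) {
      add(paste0("pc1_", bn, "_cluster"), "inconclusive", NA_real_)
    } else {
      r <- entry$pc1_correlation$r
      ok <- if (want == "+") r > 0 else r < 0
      add(paste0("pc1_", bn, "_cluster"), if (ok) "pass" else "fail", r)
    }
  }
  if (is.null(report$iaf$pc1_correlation) || is.null(report$iaf$group_test)) {
    add("pc1_iaf", "inconclusive", NA_real_)
  } else {
    r <- report$iaf$pc1_correlation$r
    p_group <- report$iaf$group_test$p_perm
    add("pc1_iaf", if (p_group >= 0.05) "inconclusive" else if (r < 0) "pass" else "fail", r)
  }
  deo <- report$dfa$eyes_open
  if (is.null(deo)) {
    add("brain_behaviour_dfa", "inconclusive", NA_real_)
  } else {
    r <- deo$global_correlation$r
    p <- deo$global_correlation$p
    add("brain_behaviour_dfa",
        if (p >= 0.05) "inconclusive" else if (r > 0) "pass" else "fail", r)
  }
  do.call(rbind, rows)
}

#' Write a study report to disk
#'
#' JSON report (tests, clusters, correlations, controls, exclusions, seeds)
#' plus CSV sidecars for the subject table.
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if missing).
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(report$subjects, file.path(dir, "subjects.csv"), row.names = FALSE)
  ser_perm <- function(t) if (is.null(t)) NULL else
    list(statistic = t$statistic, stat = t$stat_name, p_perm = t$p_perm,
         n_perm = t$n_perm, p_fdr = t$p_fdr)
  ser_cor <- function(c) if (is.null(c)) NULL else
    list(r = c$r, p = c$p, ci95 = c$ci95, n = c$n)
  ser_cluster <- function(cl) if (is.null(cl)) NULL else
    list(sizes = cl$cluster_sizes, signs = cl$signs, p = cl$cluster_p,
         significant = cl$significant, channels = cl$clusters,
         cluster_alpha = cl$cluster_alpha, n_perm = cl$n_perm)
  out <- list(
    seed = report$seed, n_perm = report$n_perm,
    excluded = report$excluded,
    band_tests = lapply(report$band_tests, function(ct) lapply(ct, ser_perm)),
    cluster_tests = lapply(report$cluster_tests, function(ct) lapply(ct, function(e)
      list(cluster = ser_cluster(e$cluster), pc1_correlation = ser_cor(e$pc1_correlation)))),
    iaf = list(group_test = ser_perm(report$iaf$group_test),
               pc1_correlation = ser_cor(report$iaf$pc1_correlation)),
    dfa = c(list(behavioural_range = report$dfa$behavioural_range),
            lapply(report$dfa[intersect(names(report$dfa), c("eyes_open", "eyes_closed"))],
                   function(d) list(global_correlation = ser_cor(d$global_correlation),
                                    cluster = ser_cluster(d$cluster),
                                    cluster_correlation = ser_cor(d$cluster_correlation),
                                    group_test = ser_perm(d$group_test)))),
    controls = list(ec_alpha_test = ser_perm(report$controls$ec_alpha_test),
                    reactivity_test = ser_perm(report$controls$reactivity_test),
                    reactivity_orientation = report$controls$reactivity_orientation),
    directions = check_directions(report))
  jsonlite::write_json(out, file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(file.path(dir, "report.json"))
}
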