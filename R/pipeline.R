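#' Analysis configuration
#'
#' Tunable parameters of the full analysis pipeline, with defaults matching
#' the standard settings of each stage: broadband 0.5-40 Hz session filter,
#' 0.8-20 Hz band and 100 Hz rate for TRF estimation with encoder lags
#' -150..450 ms and decoder lags -400..0 ms, ridge grid 1e-2..1e4, 12 Hz ERP
#' low-pass with -100..500 ms epochs baselined on -100..0 ms, alpha 8-12 Hz /
#' beta 15-25 Hz personal peaks over a 2-35 Hz aperiodic fit, 16 Hz skin
#' conductance, and the 0.01-radius / 80 ms dispersion criterion for 3D
#' fixations.
#'
#' @param ... overrides for any named default.
#' @return a `vr_analysisconfig` list.
#' @export
analysis_config <- function(...) {
  cfg <- list(
    bp_session = c(0.5, 40), bp_trf = c(0.8, 20), filter_order = 4,
    fs_trf = 100, enc_lags = c(-150, 450), dec_lags = c(-400, 0),
    lambda_grid = 10^seq(-2, 4),
    erp_lowpass = 12, epoch_window = c(-0.1, 0.5), baseline = c(-0.1, 0),
    erp_windows = list(N1 = c(75, 200), P2 = c(210, 260), P3 = c(300, 400)),
    trf_windows = list(N1 = c(75, 155), P2 = c(190, 260)),
    alpha_band = c(8, 12), beta_band = c(15, 25), psd_fit_range = c(2, 35),
    sc_fs = 16, scr_tau_rise = 0.75, scr_tau_decay = 2.0,
    gaze_radius = 0.01, gaze_min_dur = 0.08, roi_max_angle = 10,
    shift_window = 2
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad) > 0) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  class(cfg) <- "vr_analysisconfig"
  cfg
}

# Per-trial TRF segments for the Events condition: z-scored EEG at the TRF
# rate plus the z-scored stimulus matrix (teacher envelope + event regressor).
.trf_segments <- function(bundle, acfg) {
  eeg_bp <- filter_ts(bundle$eeg,
                      filter_spec("bandpass", acfg$bp_session,
                                  order = acfg$filter_order))
  eeg_trf <- resample_ts(filter_ts(eeg_bp,
                                   filter_spec("bandpass", acfg$bp_trf,
                                               order = acfg$filter_order)),
                         acfg$fs_trf)
  ev_trials <- bundle$trials[bundle$trials$condition == "EVENTS", , drop = FALSE]
  R_trials <- list(); S_trials <- list(); s_trials <- list()
  for (i in seq_len(nrow(ev_trials))) {
    t0 <- ev_trials$onset_s[i]
    t1 <- t0 + ev_trials$duration_s[i]
    R <- ts_zscore(ts_window(eeg_trf, t0, t1))
    tr_ev <- bundle$events[bundle$events$trial_index == ev_trials$trial_index[i], ]
    env_seg <- ts_window(bundle$stim, t0, t1)
    ev_reg <- event_regressor(tr_ev, ts_duration(env_seg), acfg$fs_trf, t0 = t0)
    S <- build_regressors(env_seg, ev_reg, acfg$fs_trf)
    n <- min(ts_length(R), nrow(S$S))
    R_trials[[i]] <- R$data[seq_len(n), , drop = FALSE]
    S_trials[[i]] <- S$S[seq_len(n), , drop = FALSE]
    s_trials[[i]] <- S$S[seq_len(n), 1]
  }
  list(R = R_trials, S = S_trials, s = s_trials, eeg_bp = eeg_bp,
       fs = acfg$fs_trf)
}

# ERP epochs over all sound-events, from the broadband signal at the TRF
# rate. The 12 Hz ERP low-pass is applied to the continuous signal before
# epoching (equivalent for a linear zero-phase filter, and free of epoch-edge
# transients).
.erp_for <- function(bundle, eeg_bp, acfg, event_type = NULL) {
  ev <- bundle$events
  if (!is.null(event_type)) ev <- ev[ev$event_type == event_type, , drop = FALSE]
  if (nrow(ev) == 0) return(NULL)
  eeg100 <- resample_ts(eeg_bp, acfg$fs_trf)
  if (!is.null(acfg$erp_lowpass)) {
    eeg100 <- filter_ts(eeg100, filter_spec("lowpass", acfg$erp_lowpass,
                                            order = acfg$filter_order))
  }
  ep <- epoch_ts(eeg100, ev$onset_s, acfg$epoch_window[1], acfg$epoch_window[2],
                 baseline_window = acfg$baseline)
  compute_erp(ep, lowpass = NULL, baseline_window = acfg$baseline)
}

# alpha/beta personal peaks averaged over conditions
.spectral_features <- function(bundle, eeg_bp, acfg) {
  cl <- electrode_clusters(bundle$montage)
  out <- list(alpha = c(), beta = c())
  for (cond in unique(bundle$trials$condition)) {
    tr <- bundle$trials[bundle$trials$condition == cond, , drop = FALSE]
    segs <- lapply(seq_len(nrow(tr)), function(i) {
      ts_window(eeg_bp, tr$onset_s[i], tr$onset_s[i] + tr$duration_s[i])
    })
    psd <- psd_trials(segs, fmax = acfg$psd_fit_range[2] + 5)
    a <- personal_peak(psd, acfg$alpha_band, cl$occipito_parietal,
                       acfg$psd_fit_range)
    b <- personal_peak(psd, acfg$beta_band, cl$fronto_central,
                       acfg$psd_fit_range)
    out$alpha <- c(out$alpha, a$power)
    out$beta <- c(out$beta, b$power)
  }
  list(alpha_power = mean(out$alpha), beta_power = mean(out$beta))
}

.sc_features <- function(bundle, acfg) {
  sc <- preprocess_sc(bundle$sc, acfg$sc_fs)
  kern <- bateman_kernel(acfg$scr_tau_rise, acfg$scr_tau_decay, sc$fs)
  # decompose trial-by-trial (the deconvolution is local; tonic is slow)
  tonic_means <- numeric(0)
  phasic_parts <- list()
  for (i in seq_len(nrow(bundle$trials))) {
    t0 <- bundle$trials$onset_s[i]
    t1 <- t0 + bundle$trials$duration_s[i]
    seg <- ts_window(sc, t0, min(t1 + 5, sc$t0 + ts_duration(sc)))
    dec <- sc_decompose(seg, kern, driver = FALSE)
    tonic_means <- c(tonic_means, mean(dec$tonic$data))
    phasic_parts[[i]] <- dec$phasic
  }
  # stitch phasic segments back onto the session clock for event epochs
  n <- ts_length(sc)
  ph <- numeric(n)
  for (seg in phasic_parts) {
    i0 <- round((seg$t0 - sc$t0) * sc$fs) + 1
    idx <- i0:(i0 + ts_length(seg) - 1)
    ok <- idx >= 1 & idx <= n
    ph[idx[ok]] <- seg$data[ok, 1]
  }
  phasic <- timeseries(ph, sc$fs, sc$t0, "phasic")
  scr <- if (nrow(bundle$events) > 0) {
    event_related_scr(phasic, bundle$events)
  } else NULL
  list(event_sc = if (is.null(scr)) NA_real_ else scr$mean,
       tonic_mean = mean(tonic_means),
       phasic_mean = mean(abs(ph)), scr = scr)
}

.gaze_features <- function(bundle, acfg) {
  g <- clean_gaze(bundle$gaze)
  fx <- detect_fixations(g, radius = acfg$gaze_radius,
                         min_dur = acfg$gaze_min_dur)
  fx <- assign_roi(fx, max_angle = acfg$roi_max_angle)
  met <- dwell_and_shift_metrics(fx, bundle$trials)
  quiet <- bundle$trials[bundle$trials$condition == "QUIET", , drop = FALSE]
  els <- if (nrow(bundle$events) > 0) {
    event_locked_shifts(fx, bundle$events, quiet, window = acfg$shift_window)
  } else NULL
  list(gaze_shifts = mean(met$n_shifts_away),
       pct_teacher = mean(met$pct_time_on_teacher),
       event_shift_norm = if (is.null(els)) NA_real_ else els$normalized,
       metrics = met, fixations = fx)
}

#' Compute the per-subject feature set
#'
#' Runs every analysis stage on one session bundle and returns the 10
#' measures that feed the multivariate analyses: comprehension accuracy,
#' speech-decoding reconstruction correlation, TRF N1 and P2 amplitudes,
#' mean gaze-shifts away from the teacher, ERP N1 and P2 amplitudes to
#' sound-events, event-related skin-conductance response, and personal alpha
#' and beta peak power (condition-averaged where applicable).
#'
#' @param bundle a `vr_session`.
#' @param acfg analysis configuration.
#' @param lambda_enc,lambda_dec ridge parameters for the encoder/decoder
#'   (normally the group-level choices; NULL = subject-best).
#' @param segments optional precomputed result of the internal TRF
#'   segmentation (used by [run_pipeline()] to avoid refiltering).
#' @return list with `features` (named numeric vector of the 10 measures),
#'   `meta`, and per-stage detail objects.
#' @export
compute_features <- function(bundle, acfg = analysis_config(),
                             lambda_enc = NULL, lambda_dec = NULL,
                             segments = NULL) {
  if (is.null(segments)) segments <- .trf_segments(bundle, acfg)
  cl <- electrode_clusters(bundle$montage)
  enc <- fit_encoder(segments$S, segments$R, segments$fs,
                     lags_ms = acfg$enc_lags, lambda_grid = acfg$lambda_grid,
                     lambda = lambda_enc,
                     channel_names = bundle$montage$channel_names)
  dec <- fit_decoder(segments$R, segments$s, segments$fs,
                     lags_ms = acfg$dec_lags, lambda_grid = acfg$lambda_grid,
                     lambda = lambda_dec)
  trf_comp <- extract_trf_components(enc$model, cl$trf,
                                     windows = acfg$trf_windows)
  erp_all <- .erp_for(bundle, segments$eeg_bp, acfg)
  erp_n1 <- component_amplitude(erp_all, "N1", cl$centro_parietal,
                                windows = acfg$erp_windows)
  erp_p2 <- component_amplitude(erp_all, "P2", cl$centro_parietal,
                                windows = acfg$erp_windows)
  spec <- .spectral_features(bundle, segments$eeg_bp, acfg)
  scf <- .sc_features(bundle, acfg)
  gzf <- .gaze_features(bundle, acfg)
  features <- c(
    behavior = mean(bundle$behavior$accuracy),
    decoding_r = dec$reconstruction_r,
    trf_n1 = unname(trf_comp["TRF_N1"]),
    trf_p2 = unname(trf_comp["TRF_P2"]),
    gaze_shifts = gzf$gaze_shifts,
    erp_n1 = erp_n1,
    erp_p2 = erp_p2,
    event_sc = scf$event_sc,
    alpha_power = spec$alpha_power,
    beta_power = spec$beta_power
  )
  list(features = features, meta = bundle$meta, encoding = enc, decoding = dec,
       erp = erp_all, spectral = spec, sc = scf, gaze = gzf)
}

#' Run the full cohort pipeline
#'
#' Orchestrates the complete analysis for a cohort: per-subject TRF grids,
#' group-level ridge selection (one lambda for all subjects, encoder and
#' decoder separately), per-subject feature extraction, and — when both
#' groups have at least two subjects — the group-statistics report (t-tests
#' with Cohen's d and BF10, Spearman/FDR correlation matrix, logistic and
#' linear dominance analyses).
#'
#' @param bundles list of `vr_session` objects, or character vector of bundle
#'   directories.
#' @param acfg analysis configuration.
#' @param out_dir optional output directory for `features.tsv` and the report
#'   TSVs.
#' @param seed seed for the pipeline's own randomness (control epochs).
#' @param verbose print stage progress (default FALSE).
#' @return A `vr_pipeline`: list with `features` (data frame, one row per
#'   subject), `lambda_enc`, `lambda_dec`, `report` (NULL when the cohort is
#'   too small), `subject_details`.
#' @export
run_pipeline <- function(bundles, acfg = analysis_config(), out_dir = NULL,
                         seed = 1, verbose = FALSE) {
  if (is.character(bundles)) bundles <- lapply(bundles, read_bundle)
  say <- function(...) if (verbose) message(sprintf(...))
  n <- length(bundles)
  segs <- vector("list", n)
  encs <- vector("list", n)
  decs <- vector("list", n)
  for (i in seq_len(n)) {
    say("stage trf-grid subject %d/%d", i, n)
    segs[[i]] <- .trf_segments(bundles[[i]], acfg)
    encs[[i]] <- fit_encoder(segs[[i]]$S, segs[[i]]$R, segs[[i]]$fs,
                             lags_ms = acfg$enc_lags,
                             lambda_grid = acfg$lambda_grid,
                             channel_names = bundles[[i]]$montage$channel_names)
    decs[[i]] <- fit_decoder(segs[[i]]$R, segs[[i]]$s, segs[[i]]$fs,
                             lags_ms = acfg$dec_lags,
                             lambda_grid = acfg$lambda_grid)
  }
  lambda_enc <- select_lambda_group(encs)
  lambda_dec <- select_lambda_group(decs)
  say("group lambda: encoder %g, decoder %g", lambda_enc, lambda_dec)
  rows <- vector("list", n)
  details <- vector("list", n)
  for (i in seq_len(n)) {
    say("stage features subject %d/%d", i, n)
    set.seed((seed * 2477L + i * 613L) %% .Machine$integer.max)
    res <- compute_features(bundles[[i]], acfg, lambda_enc = lambda_enc,
                            lambda_dec = lambda_dec, segments = segs[[i]])
    rows[[i]] <- data.frame(subject_id = res$meta$subject_id,
                            group = res$meta$group,
                            asrs = res$meta$asrs_score,
                            t(res$features))
    details[[i]] <- res
  }
  features <- do.call(rbind, rows)
  report <- NULL
  if (min(table(features$group)) >= 2 && length(unique(features$group)) == 2) {
    report <- group_report(features)
  } else {
    warning("cohort too small for group statistics; features only")
  }
  out <- structure(list(features = features, lambda_enc = lambda_enc,
                        lambda_dec = lambda_dec, report = report,
                        subject_details = details),
                   class = "vr_pipeline")
  if (!is.null(out_dir)) write_pipeline_output(out, out_dir)
  out
}

.measure_cols <- c("behavior", "decoding_r", "trf_n1", "trf_p2", "gaze_shifts",
                   "erp_n1", "erp_p2", "event_sc", "alpha_power", "beta_power")

#' Group-statistics report from a feature table
#'
#' Per-measure unpaired t-tests (AD(H)D vs control) with Cohen's d and JZS
#' BF10, the Spearman correlation matrix with BH-FDR correction, and
#' hold-one-out dominance analyses: logistic (predicting group membership,
#' indexed by AUC) and linear (predicting ASRS scores, indexed by
#' R-squared). Measures with missing values are dropped from the
#' multivariate models.
#'
#' @param features data frame with columns `group`, `asrs`, and the 10
#'   measures.
#' @return a `vr_report` list: `group_tests`, `correlations`,
#'   `dominance_logistic`, `dominance_linear`.
#' @export
group_report <- function(features) {
  meas <- intersect(.measure_cols, names(features))
  g <- features$group == "ADHD"
  tests <- lapply(meas, function(m) {
    x <- features[[m]][g]; y <- features[[m]][!g]
    if (any(is.na(c(x, y))) || stats::sd(c(x, y)) == 0) {
      return(data.frame(measure = m, t = NA, df = NA, p = NA, cohens_d = NA,
                        mean_diff = NA, bf10 = NA))
    }
    tt <- ttest_unpaired(x, y)
    tt$bf10 <- bayes_factor_t(tt$t, length(x), length(y))
    cbind(measure = m, tt)
  })
  group_tests <- do.call(rbind, tests)
  X <- features[, meas, drop = FALSE]
  ok <- colSums(is.na(X)) == 0
  X <- X[, ok, drop = FALSE]
  correlations <- spearman_fdr(X)
  dom_log <- dominance(X, factor(features$group, c("CONTROL", "ADHD")),
                       family = "logistic")
  dom_lin <- dominance(X, features$asrs, family = "linear")
  structure(list(group_tests = group_tests, correlations = correlations,
                 dominance_logistic = dom_log, dominance_linear = dom_lin),
            class = "vr_report")
}

#' Write pipeline outputs to a directory
#'
#' Writes `features.tsv` plus, when group statistics were computed,
#' `group_tests.tsv`, `correlation_matrix.tsv`, `dominance_logistic.tsv`,
#' `dominance_linear.tsv`, and `omnibus.json`. All files use the
#' deterministic TSV dialect, so identical results give identical bytes.
#'
#' @param result a `vr_pipeline`.
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_output <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  .write_tsv(result$features, file.path(out_dir, "features.tsv"))
  rep <- result$report
  if (!is.null(rep)) {
    .write_tsv(rep$group_tests, file.path(out_dir, "group_tests.tsv"))
    cm <- as.data.frame(rep$correlations$rho)
    cm <- cbind(measure = rownames(cm), cm)
    .write_tsv(cm, file.path(out_dir, "correlation_matrix.tsv"))
    .write_tsv(rep$dominance_logistic$table,
               file.path(out_dir, "dominance_logistic.tsv"))
    .write_tsv(rep$dominance_linear$table,
               file.path(out_dir, "dominance_linear.tsv"))
    om <- list(
      note = "delta_index = index(omnibus) - index(held_out); delta_aic = AIC(held_out) - AIC(omnibus)",
      logistic = list(auc = rep$dominance_logistic$omnibus$auc,
                      chi_sq = rep$dominance_logistic$omnibus$chi_sq,
                      p = rep$dominance_logistic$omnibus$p,
                      aic = rep$dominance_logistic$omnibus$aic),
      linear = list(r_squared = rep$dominance_linear$omnibus$r_squared,
                    F = rep$dominance_linear$omnibus$F,
                    p = rep$dominance_linear$omnibus$p,
                    aic = rep$dominance_linear$omnibus$aic),
      lambda_enc = result$lambda_enc, lambda_dec = result$lambda_dec
    )
    writeLines(jsonlite::toJSON(om, auto_unbox = TRUE, digits = 9,
                                pretty = TRUE),
               file.path(out_dir, "omnibus.json"), useBytes = TRUE)
  }
  invisible(out_dir)
}
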