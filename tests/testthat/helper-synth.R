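# Shared helpers: reduced-size simulation settings used to keep test runtimes
# at desk scale, and small forward-model builders for oracle tests. The
# reduced settings shrink session length / channel count only; all analysis
# parameters keep their defaults.

sim_config_small <- function(...) {
  sim_config(n_trials = 6, n_event_trials = 4, n_channels = 16,
             fs_eeg = 128, trial_dur_mean = 25, trial_dur_sd = 2,
             trial_dur_range = c(15, 40), isi_range_s = c(2, 4), ...)
}

analysis_config_small <- function(...) {
  analysis_config(fs_trf = 50, ...)
}

# tiny valid session bundle built by hand (1 trial, 2 events, 4 channels)
make_mini_bundle <- function() {
  mont <- default_montage(4)
  fs <- 64
  dur <- 10
  n <- dur * fs
  trials <- data.frame(trial_index = 1L, condition = "EVENTS",
                       onset_s = 0, duration_s = dur)
  events <- data.frame(trial_index = c(1L, 1L), onset_s = c(2, 6),
                       event_type = c("ARTIFICIAL", "HUMAN"),
                       side = c("LEFT", "RIGHT"), duration_s = c(0.3, 0.3))
  eeg <- timeseries(matrix(sin(seq_len(n * 4) / 17), n, 4), fs, 0,
                    mont$channel_names)
  t_g <- seq(0, dur - 1 / 120, by = 1 / 120)
  dirm <- matrix(rep(c(0, 1, 0), each = length(t_g)), ncol = 3)
  gaze <- gaze_record(t_g, dirm, fs = 120)
  sc <- timeseries(rep(2, dur * 16), 16, 0, "sc")
  stim <- timeseries(abs(sin(seq_len(n) / 11)), fs, 0, "envelope")
  behavior <- data.frame(trial_index = 1L, accuracy = 0.75)
  structure(list(
    meta = list(subject_id = "MINI", group = "CONTROL", asrs_score = 20,
                handedness = "RIGHT"),
    montage = mont, trials = trials, events = events, eeg = eeg, gaze = gaze,
    sc = sc, stim = stim, behavior = behavior, ground_truth = NULL
  ), class = "vr_session")
}

# forward TRF simulation on a known kernel: R = conv(S, kernel) x topo + noise
simulate_trf_trials <- function(n_trials, dur_s, fs, kernel, n_channels,
                                noise_sd = 0, topo = NULL) {
  if (is.null(topo)) topo <- seq(1, 0.5, length.out = n_channels)
  S_trials <- list()
  R_trials <- list()
  for (i in seq_len(n_trials)) {
    env <- generate_envelope_regressor(dur_s, fs)$data[, 1]
    s <- (env - mean(env)) / sd(env)
    drive <- stats::convolve(s, rev(kernel), type = "open")[seq_along(s)]
    R <- outer(drive, topo)
    if (noise_sd > 0) R <- R + matrix(rnorm(length(R), 0, noise_sd), nrow(R))
    R <- scale(R)
    S_trials[[i]] <- matrix(s, ncol = 1)
    R_trials[[i]] <- R
  }
  list(S = S_trials, R = R_trials)
}
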