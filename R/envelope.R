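#' Analytic-signal magnitude (Hilbert envelope)
#'
#' Computes |x + i H(x)| via the frequency-domain construction of the
#' analytic signal.
#'
#' @param x numeric vector.
#' @return nonnegative envelope vector of the same length.
#' @export
hilbert_envelope <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

# ERB-rate scale (Glasberg & Moore): frequencies equally spaced on this scale
# approximate the spacing of cochlear filters.
.erb_scale <- function(f) 21.4 * log10(1 + 0.00437 * f)
.erb_scale_inv <- function(e) (10^(e / 21.4) - 1) / 0.00437

#' Broadband envelope through a cochlear-style filterbank
#'
#' Filters the audio through a bank of band-pass filters with center
#' frequencies equally spaced on an ERB-like auditory scale, extracts each
#' narrow-band envelope with the analytic-signal transform, and averages
#' across bands. This is the standard broadband temporal envelope used as the
#' speech regressor for TRF analysis.
#'
#' @param audio a `vr_timeseries` with one channel (mono audio).
#' @param n_bands number of filterbank bands (default 16).
#' @param f_range two-element band-edge range in Hz (default c(100, 8000)).
#' @param order per-band Butterworth order (default 2; applied zero-phase).
#' @return a `vr_timeseries` with the nonnegative envelope; attribute
#'   `degenerate` is TRUE when the input was silent.
#' @export
cochlear_envelope <- function(audio, n_bands = 16, f_range = c(100, 8000),
                              order = 2) {
  if (ncol(audio$data) != 1) stop("audio must be mono")
  x <- audio$data[, 1]
  if (all(x == 0)) {
    out <- timeseries(x, audio$fs, audio$t0, "envelope")
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  ny <- audio$fs / 2
  f_range[2] <- min(f_range[2], 0.95 * ny)
  if (audio$fs < 2 * f_range[1]) stop("sampling rate too low for band range")
  edges <- .erb_scale_inv(seq(.erb_scale(f_range[1]), .erb_scale(f_range[2]),
                              length.out = n_bands + 1))
  env <- numeric(length(x))
  for (b in seq_len(n_bands)) {
    bf <- signal::butter(order, c(edges[b], edges[b + 1]) / ny, type = "pass")
    xb <- signal::filtfilt(bf, x)
    env <- env + hilbert_envelope(xb)
  }
  out <- timeseries(env / n_bands, audio$fs, audio$t0, "envelope")
  attr(out, "degenerate") <- FALSE
  out
}

#' Sound-event regressor
#'
#' Builds the sound-event stimulus regressor: a rectangular pulse of
#' `pulse_dur` seconds (default 0.3 s, the event duration) at each event
#' onset. Overlapping pulses are summed with a warning.
#'
#' @param events data frame of sound events (needs column `onset_s`; a
#'   `duration_s` column overrides `pulse_dur` per event).
#' @param duration_s total regressor duration in seconds.
#' @param fs sampling rate in Hz.
#' @param t0 start time on the session clock (default 0).
#' @param pulse_dur pulse duration in seconds when events carry none.
#' @param amplitude pulse height (default 1).
#' @return a `vr_timeseries` with one channel `events`.
#' @export
event_regressor <- function(events, duration_s, fs, t0 = 0, pulse_dur = 0.3,
                            amplitude = 1) {
  n <- round(duration_s * fs)
  x <- numeric(n)
  if (!is.null(events) && nrow(events) > 0) {
    durs <- if ("duration_s" %in% names(events)) events$duration_s else
      rep(pulse_dur, nrow(events))
    if (any(events$onset_s < t0 | events$onset_s + durs > t0 + duration_s)) {
      stop("event outside the regressor window")
    }
    overlap <- FALSE
    for (i in seq_len(nrow(events))) {
      i0 <- round((events$onset_s[i] - t0) * fs) + 1
      i1 <- round((events$onset_s[i] - t0 + durs[i]) * fs)
      i1 <- min(i1, n)
      if (any(x[i0:i1] != 0)) overlap <- TRUE
      x[i0:i1] <- x[i0:i1] + amplitude
    }
    if (overlap) warning("overlapping events: pulse values summed")
  }
  timeseries(x, fs, t0, "events")
}

#' Assemble the TRF regressor set
#'
#' Resamples the teacher-speech envelope and (optionally) the sound-event
#' regressor to the analysis rate and z-scores each column over the segment,
#' producing the stimulus matrix S for TRF estimation.
#'
#' @param teacher_env a `vr_timeseries` (teacher speech envelope).
#' @param event_env optional `vr_timeseries` (sound-event regressor); NULL
#'   for the univariate (teacher-only) model.
#' @param fs_target analysis sampling rate (default 100 Hz).
#' @return a `vr_regressors`: list with `S` (samples x k matrix), `fs`,
#'   `labels`.
#' @export
build_regressors <- function(teacher_env, event_env = NULL, fs_target = 100) {
  te <- resample_ts(teacher_env, fs_target)
  cols <- list(teacher = te$data[, 1])
  if (!is.null(event_env)) {
    ee <- resample_ts(event_env, fs_target)
    n <- min(length(cols$teacher), nrow(ee$data))
    cols$teacher <- cols$teacher[seq_len(n)]
    cols$events <- ee$data[seq_len(n), 1]
  }
  S <- do.call(cbind, cols)
  sds <- apply(S, 2, stats::sd)
  if (any(sds == 0)) stop("degenerate (constant) regressor cannot be z-scored")
  S <- scale(S)
  attr(S, "scaled:center") <- NULL
  attr(S, "scaled:scale") <- NULL
  structure(list(S = S, fs = fs_target, labels = colnames(S)),
            class = "vr_regressors")
}
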