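#' Preprocess a skin-conductance recording
#'
#' Resamples the raw signal to the analysis rate (16 Hz) with anti-aliasing,
#' then repairs jump artifacts: samples where the absolute first difference
#' exceeds `jump_threshold` (in signal units per sample) are removed together
#' with `pad` neighbors on each side and bridged by linear interpolation.
#'
#' @param sc_raw a `vr_timeseries` with one channel (microsiemens).
#' @param fs_target analysis rate (default 16 Hz).
#' @param jump_threshold per-sample jump magnitude treated as artifact
#'   (default 0.5 uS; recorded SC rises much more slowly).
#' @param pad samples removed on each side of a jump (default 2).
#' @return preprocessed `vr_timeseries` at `fs_target`.
#' @export
preprocess_sc <- function(sc_raw, fs_target = 16, jump_threshold = 0.5, pad = 2) {
  ts <- if (sc_raw$fs > fs_target) resample_ts(sc_raw, fs_target) else sc_raw
  x <- ts$data[, 1]
  n <- length(x)
  jumps <- which(abs(diff(x)) > jump_threshold)
  if (length(jumps) > 0) {
    bad <- unique(unlist(lapply(jumps, function(i) {
      max(1, i - pad):min(n, i + 1 + pad)
    })))
    good <- setdiff(seq_len(n), bad)
    x[bad] <- stats::approx(good, x[good], xout = bad, rule = 2)$y
  }
  timeseries(x, ts$fs, ts$t0, "sc")
}

#' Bateman skin-conductance response kernel
#'
#' The canonical biexponential impulse response of the sudomotor system:
#' `h(t) = exp(-t / tau_decay) - exp(-t / tau_rise)`, normalized to unit
#' peak, truncated at `t_max`. Its peak time is
#' `(log(tau_decay) - log(tau_rise)) * tau_rise * tau_decay /
#' (tau_decay - tau_rise)`.
#'
#' @param tau_rise rise time constant in seconds (default 0.75).
#' @param tau_decay decay time constant in seconds (default 2.0; must exceed
#'   `tau_rise`).
#' @param fs sampling rate in Hz.
#' @param t_max kernel support in seconds (default 10).
#' @return numeric kernel vector starting at t = 0.
#' @export
bateman_kernel <- function(tau_rise = 0.75, tau_decay = 2.0, fs = 16,
                           t_max = 10) {
  if (tau_rise >= tau_decay) stop("tau_rise must be smaller than tau_decay")
  t <- seq(0, t_max, by = 1 / fs)
  h <- exp(-t / tau_decay) - exp(-t / tau_rise)
  h / max(h)
}

#' Decompose skin conductance into tonic, phasic, and driver
#'
#' Tonic level is estimated as a smoothed sliding-window low percentile
#' (robust to phasic bursts riding on top); the phasic component is the
#' remainder; the driver (sudomotor nerve activity surrogate) is recovered
#' from the phasic signal by non-negative least-squares deconvolution against
#' the Bateman kernel. `conv(driver, kernel) + tonic` reconstructs the input
#' up to the optimization residual.
#'
#' @param sc a `vr_timeseries` (preprocessed, 16 Hz).
#' @param kernel response kernel from [bateman_kernel()] at the same rate.
#' @param tonic_window sliding window length in seconds (default 20).
#' @param tonic_percentile percentile tracked as tonic level (default 0.1).
#' @param driver run the non-negative deconvolution (default TRUE; FALSE
#'   returns only the tonic/phasic split, which is all the trial-level and
#'   event-related summaries need).
#' @return A `vr_scdecomp`: list with `tonic`, `phasic`, `driver`
#'   (`vr_timeseries`; NULL when `driver = FALSE`), `residual_rms`,
#'   `converged` (TRUE when the reconstruction residual is below 5% of the
#'   input SD, or the input was effectively constant).
#' @export
sc_decompose <- function(sc, kernel = bateman_kernel(fs = sc$fs),
                         tonic_window = 20, tonic_percentile = 0.1,
                         driver = TRUE) {
  x <- sc$data[, 1]
  n <- length(x)
  fs <- sc$fs
  half <- max(1L, round(tonic_window * fs / 2))
  # percentile track evaluated on a coarse grid (tonic is slow by
  # definition), then interpolated and smoothed
  step <- max(1L, round(fs / 2))
  centers <- unique(c(seq(1L, n, by = step), n))
  q <- vapply(centers, function(i) {
    stats::quantile(x[max(1, i - half):min(n, i + half)], tonic_percentile,
                    names = FALSE)
  }, numeric(1))
  tonic <- stats::approx(centers, q, xout = seq_len(n), rule = 2)$y
  ksm <- max(3L, round(fs * 4))
  tonic <- as.numeric(stats::filter(tonic, rep(1 / ksm, ksm), sides = 2))
  nas <- is.na(tonic)
  if (any(nas)) {
    tonic[nas] <- stats::approx(which(!nas), tonic[!nas], xout = which(nas),
                                rule = 2)$y
  }
  phasic <- x - tonic
  if (!driver) {
    return(structure(list(
      tonic = timeseries(tonic, fs, sc$t0, "tonic"),
      phasic = timeseries(phasic, fs, sc$t0, "phasic"),
      driver = NULL, kernel = kernel, residual_rms = NA_real_,
      converged = NA
    ), class = "vr_scdecomp"))
  }
  K <- length(kernel)
  # Non-negative deconvolution in sequential chunks: each chunk solves NNLS
  # on a banded convolution design over its own onset columns, against the
  # residual left after subtracting responses already attributed to earlier
  # chunks (responses decay within the kernel support, so the coupling
  # between chunks is exactly the kernel tail that is carried forward).
  chunk <- 1024L
  target <- pmax(phasic, 0)
  recon <- numeric(n)
  driver <- numeric(n)
  a <- 1L
  while (a <= n) {
    b <- min(n, a + chunk - 1L)
    rows <- a:min(n, b + K - 1L)
    cols <- a:b
    Cm <- matrix(0, length(rows), length(cols))
    for (jj in seq_along(cols)) {
      j <- cols[jj]
      len <- min(K, rows[length(rows)] - j + 1L)
      if (len > 0) Cm[(j - a + 1L):(j - a + len), jj] <- kernel[seq_len(len)]
    }
    d <- pmax(target[rows] - recon[rows], 0)
    sol <- pracma::lsqnonneg(Cm, d)
    driver[cols] <- sol$x
    recon[rows] <- recon[rows] + as.numeric(Cm %*% sol$x)
    a <- b + 1L
  }
  residual_rms <- sqrt(mean((phasic - recon)^2))
  sdx <- stats::sd(x)
  converged <- sdx < 1e-12 || residual_rms < 0.05 * sdx ||
    residual_rms < 0.05 * stats::sd(phasic) + 1e-12
  structure(list(
    tonic = timeseries(tonic, fs, sc$t0, "tonic"),
    phasic = timeseries(phasic, fs, sc$t0, "phasic"),
    driver = timeseries(driver, fs, sc$t0, "driver"),
    kernel = kernel, residual_rms = residual_rms, converged = converged
  ), class = "vr_scdecomp")
}

#' Event-related skin-conductance response
#'
#' Cuts `[0, 5]` s epochs of the phasic signal after each sound-event,
#' subtracts the mean over `[0, 1]` s (the response is slow, so the first
#' second serves as baseline), and summarizes each epoch as the mean response
#' between 2 and 3 s, where the event-related response peaks.
#'
#' @param phasic a `vr_timeseries` (phasic component).
#' @param events data frame with `onset_s` and optionally `event_type`.
#' @param window epoch window in seconds (default c(0, 5)).
#' @param baseline baseline window (default c(0, 1)).
#' @param summary_window summary window (default c(2, 3)).
#' @return A `vr_eventscr`: list with `curves` (events x samples matrix),
#'   `times`, `summary` (per-event mean in the summary window), `by_type`
#'   (named mean summary per event type, when types are given), `mean`.
#' @export
event_related_scr <- function(phasic, events, window = c(0, 5),
                              baseline = c(0, 1), summary_window = c(2, 3)) {
  ep <- epoch_ts(phasic, events$onset_s, window[1], window[2],
                 baseline_window = baseline)
  curves <- matrix(ep$epochs[, , 1], nrow = dim(ep$epochs)[1])
  ssel <- ep$times >= summary_window[1] & ep$times <= summary_window[2]
  summaries <- rowMeans(curves[, ssel, drop = FALSE])
  by_type <- NULL
  if ("event_type" %in% names(events)) {
    types <- events$event_type[ep$kept]
    by_type <- tapply(summaries, types, mean)
  }
  structure(list(curves = curves, times = ep$times, summary = summaries,
                 by_type = by_type, mean = mean(summaries)),
            class = "vr_eventscr")
}
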