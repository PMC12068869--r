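#' Trial-wise power spectral density
#'
#' Computes the PSD of each full-trial segment with a Hann taper and FFT,
#' zero-padding every trial to a common length (at least `1/resolution_hz`
#' seconds) so all trials share one frequency grid, then averages power
#' across trials.
#'
#' @param trial_ts list of `vr_timeseries`, one per trial (same channels and
#'   sampling rate).
#' @param fmax upper frequency of the returned grid (default 45 Hz).
#' @param resolution_hz required grid resolution (default 0.25 Hz; grids are
#'   finer when trials are long).
#' @return A `vr_psd`: list with `freqs`, `power` (channels x freqs,
#'   trial-averaged), `n_trials`, `channel_names`, `fs`.
#' @export
psd_trials <- function(trial_ts, fmax = 45, resolution_hz = 0.25) {
  if (length(trial_ts) == 0) stop("no trials")
  fs <- trial_ts[[1]]$fs
  n_c <- ncol(trial_ts[[1]]$data)
  n_max <- max(vapply(trial_ts, ts_length, 1L))
  nfft <- 2^ceiling(log2(max(n_max, fs / resolution_hz)))
  freqs <- (0:(nfft / 2)) * fs / nfft
  keep <- freqs <= fmax
  freqs <- freqs[keep]
  acc <- matrix(0, n_c, length(freqs))
  for (tr in trial_ts) {
    n <- ts_length(tr)
    w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))  # Hann
    u <- sum(w^2)                                            # taper power
    for (j in seq_len(n_c)) {
      x <- tr$data[, j]
      x <- (x - mean(x)) * w
      X <- stats::fft(c(x, numeric(nfft - n)))
      p <- Mod(X[seq_along(freqs)])^2 / (u * fs)
      p[-1] <- 2 * p[-1]                                     # one-sided
      acc[j, ] <- acc[j, ] + p
    }
  }
  structure(list(freqs = freqs, power = acc / length(trial_ts),
                 n_trials = length(trial_ts),
                 channel_names = trial_ts[[1]]$channel_names, fs = fs),
            class = "vr_psd")
}

#' Fit the aperiodic (1/f) component of a PSD
#'
#' Robust linear fit of log10 power against log10 frequency over
#' `fit_range`, iteratively excluding bins whose residual exceeds 2.5 SD
#' (oscillatory peaks) and refitting, so the aperiodic estimate is not pulled
#' up by alpha/beta bumps. No knee term is modeled.
#'
#' @param freqs frequency grid in Hz.
#' @param power power values on the grid (one channel or a cluster mean).
#' @param fit_range frequency range used for the fit (default c(2, 35) Hz).
#' @param max_iter maximum exclusion-refit iterations (default 5).
#' @return list with `offset` (log10 power at 1 Hz), `exponent` (positive for
#'   decaying spectra), `fitted` (log10 aperiodic power over the full grid).
#' @export
fit_aperiodic <- function(freqs, power, fit_range = c(2, 35), max_iter = 5) {
  sel <- freqs >= fit_range[1] & freqs <= fit_range[2] & power > 0
  lx <- log10(freqs[sel])
  ly <- log10(power[sel])
  use <- rep(TRUE, length(lx))
  for (it in seq_len(max_iter)) {
    fit <- stats::lm.fit(cbind(1, lx[use]), ly[use])
    co <- fit$coefficients
    resid_all <- ly - (co[1] + co[2] * lx)
    s <- stats::sd(resid_all[use])
    new_use <- resid_all <= 2.5 * s   # drop only upward outliers (peaks)
    if (all(new_use == use)) break
    use <- new_use
    if (sum(use) < 5) break
  }
  fitted_full <- co[1] + co[2] * log10(pmax(freqs, freqs[freqs > 0][1]))
  list(offset = unname(co[1]), exponent = unname(-co[2]), fitted = fitted_full)
}

#' Periodic (oscillatory) residual spectrum
#'
#' Subtracts the fitted aperiodic component from the log10 PSD, leaving the
#' periodic portion: positive around oscillatory peaks, near zero (possibly
#' slightly negative) elsewhere.
#'
#' @param freqs frequency grid.
#' @param power PSD values.
#' @param aperiodic result of [fit_aperiodic()] on the same grid.
#' @return numeric vector of residual log10 power.
#' @export
periodic_spectrum <- function(freqs, power, aperiodic) {
  lp <- log10(pmax(power, .Machine$double.xmin))
  lp - aperiodic$fitted
}

#' Personal spectral peak within a band
#'
#' Finds the frequency with the largest periodic (aperiodic-removed) power
#' within a band, averaged over an electrode cluster. When the maximum
#' residual is below `min_height` the subject is flagged as having no
#' detectable peak in that band.
#'
#' @param psd a `vr_psd`.
#' @param band two-element frequency range (e.g. c(8, 12) for alpha,
#'   c(15, 25) for beta).
#' @param cluster electrode names of the detection cluster (default: all
#'   channels).
#' @param fit_range aperiodic fit range (default c(2, 35) Hz).
#' @param min_height minimum residual log10 power to accept a peak
#'   (default 0.05).
#' @return list with `freq`, `power` (residual log10 power at the peak),
#'   `has_peak`, `aperiodic` (offset/exponent of the cluster-mean fit).
#' @export
personal_peak <- function(psd, band, cluster = NULL, fit_range = c(2, 35),
                          min_height = 0.05) {
  idx <- if (is.null(cluster)) seq_along(psd$channel_names) else {
    i <- match(cluster, psd$channel_names)
    i[!is.na(i)]
  }
  if (length(idx) == 0) stop("no cluster channel present in the PSD")
  pw <- colMeans(psd$power[idx, , drop = FALSE])
  ap <- fit_aperiodic(psd$freqs, pw, fit_range)
  resid <- periodic_spectrum(psd$freqs, pw, ap)
  sel <- which(psd$freqs >= band[1] & psd$freqs <= band[2])
  if (length(sel) == 0) stop("band outside the frequency grid")
  imax <- sel[which.max(resid[sel])]
  has_peak <- resid[imax] >= min_height
  list(freq = if (has_peak) psd$freqs[imax] else NA_real_,
       power = resid[imax], has_peak = has_peak,
       aperiodic = list(offset = ap$offset, exponent = ap$exponent))
}
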