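#' Filter specification
#'
#' Describes a Butterworth IIR filter as used throughout the EEG pipeline:
#' fourth order, applied forward and backward (zero phase) by default.
#'
#' @param kind one of "bandpass", "lowpass", "highpass".
#' @param cutoffs cutoff frequency in Hz (two values for bandpass).
#' @param order filter order (default 4).
#' @param zero_phase apply forward-backward (default TRUE).
#' @return a `vr_filterspec` list.
#' @export
filter_spec <- function(kind = c("bandpass", "lowpass", "highpass"),
                        cutoffs, order = 4, zero_phase = TRUE) {
  kind <- match.arg(kind)
  cutoffs <- as.numeric(cutoffs)
  if (kind == "bandpass") {
    if (length(cutoffs) != 2 || diff(cutoffs) <= 0) {
      stop("bandpass needs two ordered cutoffs")
    }
  } else if (length(cutoffs) != 1) {
    stop(sprintf("%s needs one cutoff", kind))
  }
  if (any(cutoffs <= 0)) stop("cutoffs must be positive")
  structure(list(kind = kind, cutoffs = cutoffs, order = order,
                 zero_phase = zero_phase),
            class = "vr_filterspec")
}

.butter_for <- function(spec, fs) {
  ny <- fs / 2
  if (any(spec$cutoffs >= ny)) {
    stop(sprintf("cutoff %g Hz at or above Nyquist (%g Hz)",
                 max(spec$cutoffs), ny))
  }
  w <- spec$cutoffs / ny
  type <- switch(spec$kind, bandpass = "pass", lowpass = "low", highpass = "high")
  signal::butter(spec$order, w, type = type)
}

#' Filter a time series
#'
#' Applies a Butterworth IIR filter channel by channel. With
#' `spec$zero_phase = TRUE` the filter runs forward and backward
#' (`signal::filtfilt`), doubling the effective order and cancelling phase
#' delay; output length equals input length.
#'
#' @param ts a `vr_timeseries`.
#' @param spec a `vr_filterspec`.
#' @return filtered `vr_timeseries`.
#' @export
filter_ts <- function(ts, spec) {
  bf <- .butter_for(spec, ts$fs)
  out <- ts$data
  for (j in seq_len(ncol(out))) {
    out[, j] <- if (spec$zero_phase) {
      signal::filtfilt(bf, ts$data[, j])
    } else {
      as.numeric(signal::filter(bf, ts$data[, j]))
    }
  }
  timeseries(out, ts$fs, ts$t0, ts$channel_names)
}

#' Resample a time series
#'
#' Downsampling applies an anti-aliasing zero-phase Butterworth low-pass at
#' 0.9 x the new Nyquist frequency before interpolating onto the new sample
#' grid. Upsampling (fs_new > fs) is supported through plain band-limited
#' interpolation and raises a warning, since the pipeline only ever reduces
#' rates.
#'
#' @param ts a `vr_timeseries`.
#' @param fs_new target sampling rate in Hz.
#' @param aa_order anti-aliasing filter order (default 6, zero-phase).
#' @return resampled `vr_timeseries` starting at the same `t0`.
#' @export
resample_ts <- function(ts, fs_new, aa_order = 6) {
  if (fs_new == ts$fs) return(ts)
  x <- ts$data
  if (fs_new > ts$fs) {
    warning("upsampling requested; interpolating without rate-change filtering")
  } else {
    spec <- filter_spec("lowpass", 0.9 * fs_new / 2, order = aa_order)
    x <- filter_ts(ts, spec)$data
  }
  t_old <- (seq_len(nrow(x)) - 1) / ts$fs
  n_new <- floor(ts_duration(ts) * fs_new)
  t_new <- (seq_len(n_new) - 1) / fs_new
  out <- matrix(0, n_new, ncol(x))
  for (j in seq_len(ncol(x))) {
    out[, j] <- stats::approx(t_old, x[, j], xout = t_new, rule = 2)$y
  }
  timeseries(out, fs_new, ts$t0, ts$channel_names)
}

#' Re-reference EEG channels
#'
#' Subtracts the mean of the reference channels from every channel.
#'
#' @param ts a `vr_timeseries`.
#' @param ref_channels channel names (or indices) forming the reference.
#' @return re-referenced `vr_timeseries`.
#' @export
rereference <- function(ts, ref_channels) {
  idx <- if (is.character(ref_channels)) {
    match(ref_channels, ts$channel_names)
  } else as.integer(ref_channels)
  if (any(is.na(idx))) stop("unknown reference channel")
  ref <- rowMeans(ts$data[, idx, drop = FALSE])
  timeseries(ts$data - ref, ts$fs, ts$t0, ts$channel_names)
}

#' Epoch a time series around event onsets
#'
#' Cuts epochs `[tmin, tmax]` (both endpoints included on the sample grid;
#' sample index = round(t * fs)) around each onset and optionally subtracts
#' the per-epoch, per-channel mean over `baseline_window`. Onsets whose
#' epoch would extend beyond the recording are dropped (with a message).
#'
#' @param ts a `vr_timeseries`.
#' @param onsets event onsets in seconds (session clock).
#' @param tmin,tmax epoch window relative to onset, in seconds.
#' @param baseline_window length-2 vector (seconds, relative to onset) over
#'   which the baseline mean is computed, or NULL for no correction.
#' @return list with `epochs` (events x samples x channels array), `times`
#'   (seconds relative to onset), `kept` (logical per input onset), and
#'   `n_dropped`.
#' @export
epoch_ts <- function(ts, onsets, tmin, tmax, baseline_window = NULL) {
  fs <- ts$fs
  n <- nrow(ts$data)
  rel <- seq(round(tmin * fs), round(tmax * fs))
  times <- rel / fs
  centers <- round((onsets - ts$t0) * fs) + 1
  first <- centers + rel[1]
  last <- centers + rel[length(rel)]
  kept <- first >= 1 & last <= n
  if (!any(kept)) stop("no epoch fits inside the recording")
  n_dropped <- sum(!kept)
  if (n_dropped > 0) {
    message(sprintf("epoch_ts: dropped %d onset(s) outside the recording", n_dropped))
  }
  idx_keep <- which(kept)
  ep <- array(0, dim = c(length(idx_keep), length(rel), ncol(ts$data)))
  for (i in seq_along(idx_keep)) {
    rows <- centers[idx_keep[i]] + rel
    ep[i, , ] <- ts$data[rows, , drop = FALSE]
  }
  if (!is.null(baseline_window)) {
    bsel <- times >= baseline_window[1] & times <= baseline_window[2]
    if (!any(bsel)) stop("baseline window contains no samples")
    for (i in seq_len(dim(ep)[1])) {
      bmean <- colMeans(matrix(ep[i, bsel, ], nrow = sum(bsel)))
      ep[i, , ] <- sweep(matrix(ep[i, , ], nrow = length(rel)), 2, bmean, "-")
    }
  }
  list(epochs = ep, times = times, kept = kept, n_dropped = n_dropped,
       channel_names = ts$channel_names, fs = fs)
}

#' Interpolate bad channels
#'
#' Replaces each bad channel by the inverse-distance-weighted mean of its
#' `k` nearest neighbors on the montage sphere (bad channels are excluded
#' from the donor set).
#'
#' @param ts a `vr_timeseries`.
#' @param bad character vector of bad channel names.
#' @param montage a `vr_montage` covering the channels of `ts`.
#' @param k number of neighbors (default 4).
#' @return repaired `vr_timeseries`.
#' @export
interpolate_channels <- function(ts, bad, montage, k = 4) {
  if (length(bad) == 0) return(ts)
  pos <- montage$positions[ts$channel_names, , drop = FALSE]
  good <- setdiff(ts$channel_names, bad)
  if (length(good) < k) stop("not enough good channels for interpolation")
  out <- ts$data
  for (b in bad) {
    d <- sqrt(rowSums((pos[good, , drop = FALSE] -
                         matrix(pos[b, ], length(good), 3, byrow = TRUE))^2))
    nb <- good[order(d)[seq_len(k)]]
    w <- 1 / pmax(sort(d)[seq_len(k)], 1e-9)
    w <- w / sum(w)
    out[, b] <- ts$data[, nb, drop = FALSE] %*% w
  }
  timeseries(out, ts$fs, ts$t0, ts$channel_names)
}

#' Ocular-artifact removal stub
#'
#' Placeholder for ICA-based ocular artifact removal. The synthetic sessions
#' carry no ocular artifacts, so this stage passes data through unchanged and
#' records a note; it marks the insertion point for an ICA step when the
#' pipeline is applied to recorded data.
#'
#' @param ts a `vr_timeseries`.
#' @return `ts`, unchanged.
#' @export
remove_ocular_ica <- function(ts) {
  message("remove_ocular_ica: pass-through stub (no ICA applied)")
  ts
}
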