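#' Multichannel time series
#'
#' Light container used for every sampled modality in a session (EEG, skin
#' conductance, stimulus envelopes). Data are stored as a samples x channels
#' numeric matrix with a sampling rate and a start time on the session clock
#' (seconds from session start, continuous across trials).
#'
#' @param data numeric matrix (samples x channels) or vector (one channel).
#' @param fs sampling rate in Hz (> 0).
#' @param t0 start time in seconds on the session clock.
#' @param channel_names optional character vector, one per column.
#' @return An object of class `vr_timeseries`.
#' @export
timeseries <- function(data, fs, t0 = 0, channel_names = NULL) {
  if (is.vector(data)) data <- matrix(data, ncol = 1)
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop("fs must be a single positive number")
  }
  if (any(!is.finite(data))) stop("time series data must be finite")
  if (is.null(channel_names)) {
    channel_names <- if (ncol(data) == 1) "ch1" else paste0("ch", seq_len(ncol(data)))
  }
  if (length(channel_names) != ncol(data)) {
    stop("channel_names length must match number of columns")
  }
  colnames(data) <- channel_names
  structure(
    list(data = data, fs = as.numeric(fs), t0 = as.numeric(t0),
         channel_names = as.character(channel_names)),
    class = "vr_timeseries"
  )
}

#' @export
print.vr_timeseries <- function(x, ...) {
  cat(sprintf("<vr_timeseries> %d samples x %d channels @ %g Hz, t0 = %g s (%.2f s)\n",
              nrow(x$data), ncol(x$data), x$fs, x$t0, nrow(x$data) / x$fs))
  invisible(x)
}

#' Number of samples in a time series
#' @param ts a `vr_timeseries`.
#' @return integer sample count.
#' @export
ts_length <- function(ts) nrow(ts$data)

#' Duration of a time series in seconds
#' @param ts a `vr_timeseries`.
#' @return duration in seconds (samples / fs).
#' @export
ts_duration <- function(ts) nrow(ts$data) / ts$fs

#' Sample times of a time series
#' @param ts a `vr_timeseries`.
#' @return numeric vector of session-clock times, one per sample.
#' @export
ts_times <- function(ts) ts$t0 + (seq_len(nrow(ts$data)) - 1) / ts$fs

#' Extract a time window from a time series
#'
#' Returns the samples with session-clock time in `[from, to)`. The returned
#' object keeps the sampling rate and records the actual start time of the
#' first retained sample.
#'
#' @param ts a `vr_timeseries`.
#' @param from,to window bounds in seconds (session clock).
#' @return a `vr_timeseries` restricted to the window.
#' @export
ts_window <- function(ts, from, to) {
  i0 <- round((from - ts$t0) * ts$fs) + 1
  i1 <- round((to - ts$t0) * ts$fs)
  i0 <- max(1L, as.integer(i0))
  i1 <- min(nrow(ts$data), as.integer(i1))
  if (i1 < i0) stop("empty window")
  timeseries(ts$data[i0:i1, , drop = FALSE], ts$fs,
             t0 = ts$t0 + (i0 - 1) / ts$fs, channel_names = ts$channel_names)
}

#' Column-wise z-score of a time series
#'
#' @param ts a `vr_timeseries`.
#' @return a `vr_timeseries` with each channel centered and scaled to unit SD.
#' @export
ts_zscore <- function(ts) {
  m <- colMeans(ts$data)
  s <- apply(ts$data, 2, stats::sd)
  if (any(s == 0)) stop("degenerate (constant) channel cannot be z-scored")
  z <- sweep(sweep(ts$data, 2, m, "-"), 2, s, "/")
  timeseries(z, ts$fs, ts$t0, ts$channel_names)
}
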