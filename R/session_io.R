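#' Validate a session bundle
#'
#' Checks every bundle invariant: metadata ranges, montage consistency,
#' strictly increasing trial onsets with positive durations, events inside
#' their trial's window, modality coverage of the trial span, and behavior
#' values in `[0, 1]`. Stops with an error naming the offending field.
#'
#' @param bundle a `vr_session`.
#' @return `bundle`, invisibly.
#' @export
validate_bundle <- function(bundle) {
  m <- bundle$meta
  if (is.null(m$group) || !m$group %in% c("ADHD", "CONTROL")) {
    stop("validation error: meta$group must be ADHD or CONTROL")
  }
  if (!is.null(m$asrs_score) && (m$asrs_score < 0 || m$asrs_score > 72)) {
    stop("validation error: meta$asrs_score outside [0, 72]")
  }
  tr <- bundle$trials
  if (any(diff(tr$onset_s) <= 0)) {
    stop("validation error: trials$onset_s not strictly increasing")
  }
  if (any(tr$duration_s <= 0)) stop("validation error: trials$duration_s <= 0")
  if (!all(tr$condition %in% c("EVENTS", "QUIET"))) {
    stop("validation error: trials$condition")
  }
  ev <- bundle$events
  if (nrow(ev) > 0) {
    ti <- match(ev$trial_index, tr$trial_index)
    if (any(is.na(ti))) stop("validation error: events$trial_index unknown")
    inside <- ev$onset_s >= tr$onset_s[ti] &
      ev$onset_s + ev$duration_s <= tr$onset_s[ti] + tr$duration_s[ti]
    if (!all(inside)) {
      stop("validation error: events$onset_s outside its trial window")
    }
  }
  span_end <- max(tr$onset_s + tr$duration_s)
  for (mod in c("eeg", "sc", "stim")) {
    ts <- bundle[[mod]]
    if (!is.null(ts) && ts$t0 + ts_duration(ts) < span_end - 1 / ts$fs - 1e-6) {
      stop(sprintf("validation error: %s does not cover the trial span", mod))
    }
  }
  if (!is.null(bundle$gaze) &&
      max(bundle$gaze$t) < span_end - 2 / bundle$gaze$fs) {
    stop("validation error: gaze does not cover the trial span")
  }
  if (ncol(bundle$eeg$data) != length(bundle$montage$channel_names)) {
    stop("validation error: eeg channels do not match montage")
  }
  if (any(bundle$behavior$accuracy < 0 | bundle$behavior$accuracy > 1)) {
    stop("validation error: behavior$accuracy outside [0, 1]")
  }
  invisible(bundle)
}

.fmt_num <- function(x) {
  out <- sprintf("%.9g", x)
  out[!is.finite(x)] <- "NA"
  out
}

.write_tsv <- function(df, path) {
  # deterministic TSV: tab separator, '.' decimal, fixed %.9g floats,
  # no quoting, UTF-8, LF line endings
  cols <- lapply(df, function(col) {
    if (is.numeric(col) && !is.integer(col)) .fmt_num(col) else as.character(col)
  })
  lines <- c(paste(names(df), collapse = "\t"),
             if (nrow(df) > 0) do.call(paste, c(cols, sep = "\t")))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
}

.read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Write a session bundle to a directory
#'
#' Serializes a bundle as a documented directory of plain files:
#' `session.json` (metadata, montage, array shapes), `trials.tsv`,
#' `events.tsv`, `gaze.tsv`, `sc.tsv`, `stim.tsv`, `behavior.tsv`, and the
#' EEG as row-major little-endian float32 (`eeg.bin`) or CSV for tiny
#' fixtures. Output bytes are deterministic for identical bundles (stable
#' column order, fixed float formatting).
#'
#' @param bundle a valid `vr_session`.
#' @param path directory to create/fill.
#' @param eeg_format "bin" (float32 binary) or "csv".
#' @param ground_truth write `groundtruth.json` when the bundle carries
#'   simulation truth (default TRUE).
#' @return `path`, invisibly.
#' @export
write_bundle <- function(bundle, path, eeg_format = c("bin", "csv"),
                         ground_truth = TRUE) {
  eeg_format <- match.arg(eeg_format)
  validate_bundle(bundle)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    format_version = 1L,
    meta = bundle$meta,
    montage = list(channel_names = bundle$montage$channel_names,
                   positions = unname(apply(bundle$montage$positions, 1,
                                            function(r) round(r, 9),
                                            simplify = FALSE)),
                   reference = bundle$montage$reference),
    eeg = list(fs = bundle$eeg$fs, t0 = bundle$eeg$t0,
               n_samples = ts_length(bundle$eeg),
               n_channels = ncol(bundle$eeg$data), format = eeg_format),
    gaze = list(fs = bundle$gaze$fs),
    sc = list(fs = bundle$sc$fs, t0 = bundle$sc$t0),
    stim = list(fs = bundle$stim$fs, t0 = bundle$stim$t0)
  )
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = 9,
                              pretty = TRUE),
             file.path(path, "session.json"), useBytes = TRUE)
  .write_tsv(bundle$trials, file.path(path, "trials.tsv"))
  .write_tsv(bundle$events, file.path(path, "events.tsv"))
  g <- bundle$gaze
  .write_tsv(data.frame(t = g$t, x = g$dir[, 1], y = g$dir[, 2],
                        z = g$dir[, 3], blink = as.integer(g$blink),
                        valid = as.integer(g$valid)),
             file.path(path, "gaze.tsv"))
  .write_tsv(data.frame(t = ts_times(bundle$sc), sc = bundle$sc$data[, 1]),
             file.path(path, "sc.tsv"))
  .write_tsv(data.frame(t = ts_times(bundle$stim),
                        envelope = bundle$stim$data[, 1]),
             file.path(path, "stim.tsv"))
  .write_tsv(bundle$behavior, file.path(path, "behavior.tsv"))
  if (eeg_format == "bin") {
    con <- file(file.path(path, "eeg.bin"), "wb")
    writeBin(as.numeric(t(bundle$eeg$data)), con, size = 4, endian = "little")
    close(con)
  } else {
    .write_tsv(as.data.frame(bundle$eeg$data), file.path(path, "eeg.csv"))
  }
  if (ground_truth && !is.null(bundle$ground_truth)) {
    gt <- bundle$ground_truth
    keep <- list(
      subject_params = gt$subject_params,
      alpha_freq = gt$alpha_freq, beta_freq = gt$beta_freq,
      alpha_amp = gt$alpha_amp, one_f_exponent = gt$one_f_exponent,
      scr_impulse_times = gt$scr$impulse_times,
      scr_impulse_amps = gt$scr$impulse_amps
    )
    writeLines(jsonlite::toJSON(keep, auto_unbox = TRUE, digits = 9,
                                pretty = TRUE),
               file.path(path, "groundtruth.json"), useBytes = TRUE)
    .write_tsv(gt$fixations, file.path(path, "fixations_truth.tsv"))
  }
  invisible(path)
}

#' Read a session bundle from a directory
#'
#' Counterpart of [write_bundle()]: reads and validates all components.
#' A missing required file raises an "incomplete bundle" error; invariant
#' violations raise validation errors naming the field.
#'
#' @param path bundle directory.
#' @return a validated `vr_session`.
#' @export
read_bundle <- function(path) {
  need <- c("session.json", "trials.tsv", "events.tsv", "gaze.tsv", "sc.tsv",
            "stim.tsv", "behavior.tsv")
  missing <- need[!file.exists(file.path(path, need))]
  if (!file.exists(file.path(path, "eeg.bin")) &&
      !file.exists(file.path(path, "eeg.csv"))) {
    missing <- c(missing, "eeg.bin|eeg.csv")
  }
  if (length(missing) > 0) {
    stop("incomplete bundle: missing ", paste(missing, collapse = ", "))
  }
  meta <- jsonlite::fromJSON(file.path(path, "session.json"),
                             simplifyVector = TRUE)
  pos <- meta$montage$positions
  if (is.list(pos)) pos <- do.call(rbind, pos)
  mont <- montage(meta$montage$channel_names, pos, meta$montage$reference)
  trials <- .read_tsv(file.path(path, "trials.tsv"))
  events <- .read_tsv(file.path(path, "events.tsv"))
  gz <- .read_tsv(file.path(path, "gaze.tsv"))
  gaze <- gaze_record(gz$t, cbind(gz$x, gz$y, gz$z),
                      blink = gz$blink == 1, valid = gz$valid == 1,
                      fs = meta$gaze$fs)
  scd <- .read_tsv(file.path(path, "sc.tsv"))
  sc <- timeseries(scd$sc, meta$sc$fs, meta$sc$t0, "sc")
  st <- .read_tsv(file.path(path, "stim.tsv"))
  stim <- timeseries(st$envelope, meta$stim$fs, meta$stim$t0, "envelope")
  if (meta$eeg$format == "bin") {
    con <- file(file.path(path, "eeg.bin"), "rb")
    raw <- readBin(con, numeric(), n = meta$eeg$n_samples * meta$eeg$n_channels,
                   size = 4, endian = "little")
    close(con)
    eegm <- matrix(raw, nrow = meta$eeg$n_samples,
                   ncol = meta$eeg$n_channels, byrow = TRUE)
  } else {
    eegm <- as.matrix(.read_tsv(file.path(path, "eeg.csv")))
  }
  eeg <- timeseries(eegm, meta$eeg$fs, meta$eeg$t0,
                    meta$montage$channel_names)
  behavior <- .read_tsv(file.path(path, "behavior.tsv"))
  gt <- NULL
  if (file.exists(file.path(path, "groundtruth.json"))) {
    gt <- jsonlite::fromJSON(file.path(path, "groundtruth.json"),
                             simplifyVector = TRUE)
    if (file.exists(file.path(path, "fixations_truth.tsv"))) {
      gt$fixations <- .read_tsv(file.path(path, "fixations_truth.tsv"))
    }
  }
  bundle <- structure(list(
    meta = meta$meta, montage = mont, trials = trials, events = events,
    eeg = eeg, gaze = gaze, sc = sc, stim = stim, behavior = behavior,
    ground_truth = gt
  ), class = "vr_session")
  validate_bundle(bundle)
  bundle
}

#' @export
print.vr_session <- function(x, ...) {
  cat(sprintf("<vr_session> subject %s (%s), %d trials (%d EVENTS), %d events\n",
              x$meta$subject_id, x$meta$group, nrow(x$trials),
              sum(x$trials$condition == "EVENTS"), nrow(x$events)))
  invisible(x)
}
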