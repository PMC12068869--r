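#' Gaze record constructor
#'
#' Holds binocular-averaged 3D gaze directions sampled at the eye-tracker
#' rate (120 Hz): session-clock times, unit direction vectors, and blink /
#' validity flags.
#'
#' @param t sample times (seconds, session clock, increasing).
#' @param dir n x 3 matrix of gaze direction vectors (unit length for valid
#'   samples).
#' @param blink logical blink flag per sample.
#' @param valid logical validity flag per sample (default: all valid).
#' @param fs nominal sampling rate (default 120 Hz).
#' @return a `vr_gaze` object.
#' @export
gaze_record <- function(t, dir, blink = NULL, valid = NULL, fs = 120) {
  dir <- as.matrix(dir)
  if (ncol(dir) != 3 || nrow(dir) != length(t)) stop("dir must be n x 3")
  if (is.null(blink)) blink <- rep(FALSE, length(t))
  if (is.null(valid)) valid <- rep(TRUE, length(t))
  nrm <- sqrt(rowSums(dir^2))
  ok <- valid & !blink
  if (any(ok) && any(abs(nrm[ok] - 1) > 1e-3)) {
    stop("valid gaze directions must be unit vectors (|dir| = 1 +/- 1e-3)")
  }
  structure(list(t = as.numeric(t), dir = dir, blink = as.logical(blink),
                 valid = as.logical(valid), fs = fs),
            class = "vr_gaze")
}

#' Default classroom regions of interest
#'
#' Anchor gaze directions (unit vectors) for the eight classroom ROIs. The
#' teacher is straight ahead; boards flank the teacher; students sit to the
#' sides; window, ceiling and floor complete the scene.
#'
#' @return named 8 x 3 matrix of unit anchor directions.
#' @export
roi_anchors <- function() {
  deg <- pi / 180
  sph <- function(az, el) c(sin(az * deg) * cos(el * deg),
                            cos(az * deg) * cos(el * deg),
                            sin(el * deg))
  a <- rbind(
    Teacher = sph(0, 0),
    LeftBoard = sph(-20, 5),
    RightBoard = sph(20, 5),
    Ceiling = sph(0, 45),
    Floor = sph(0, -40),
    MiddleWindow = sph(60, 5),
    LeftStudent = sph(-45, -10),
    RightStudent = sph(45, -10)
  )
  a / sqrt(rowSums(a^2))
}

#' Scrub blinks and invalid samples from a gaze record
#'
#' Removes samples flagged invalid and all samples from 100 ms before each
#' blink onset to 200 ms after its end (eyelid motion contaminates gaze
#' estimates around the blink). The removed spans remain as gaps: nothing is
#' interpolated, and fixation detection treats gaps as cluster breaks.
#'
#' @param record a `vr_gaze`.
#' @param pre seconds removed before each blink onset (default 0.1).
#' @param post seconds removed after each blink end (default 0.2).
#' @return cleaned `vr_gaze`.
#' @export
clean_gaze <- function(record, pre = 0.1, post = 0.2) {
  drop <- !record$valid | record$blink
  b <- record$blink
  if (any(b)) {
    r <- rle(b)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (i in which(r$values)) {
      t_on <- record$t[starts[i]]
      t_off <- record$t[ends[i]]
      drop <- drop | (record$t >= t_on - pre & record$t <= t_off + post)
    }
  }
  keep <- !drop
  gaze_record(record$t[keep], record$dir[keep, , drop = FALSE],
              blink = rep(FALSE, sum(keep)), valid = rep(TRUE, sum(keep)),
              fs = record$fs)
}

#' Dispersion-based fixation detection on 3D gaze directions
#'
#' Greedy dispersion clustering over consecutive samples: a running cluster
#' is extended while every member stays within `radius` (Euclidean distance
#' between unit direction vectors; 0.01 is about 0.57 degrees) of the running
#' centroid. Temporal gaps longer than `gap_tol` times the sample period
#' (blinks, dropouts) break clusters. Clusters lasting at least `min_dur`
#' become fixations; gaze-shifts are the transitions between consecutive
#' fixations.
#'
#' @param record a cleaned `vr_gaze`.
#' @param radius dispersion radius (default 0.01).
#' @param min_dur minimum fixation duration in seconds (default 0.08).
#' @param gap_tol gap tolerance in sample periods (default 1.5).
#' @return data frame with `start_s`, `end_s`, `duration_s`, centroid
#'   components `cx`, `cy`, `cz`, and `n_samples`.
#' @export
detect_fixations <- function(record, radius = 0.01, min_dur = 0.08,
                             gap_tol = 1.5) {
  n <- length(record$t)
  if (n == 0) stop("empty gaze record")
  t <- record$t
  D <- record$dir
  max_gap <- gap_tol / record$fs
  fix <- list()
  emit <- function(i0, i1) {
    dur <- t[i1] - t[i0] + 1 / record$fs
    if (dur >= min_dur) {
      ctr <- colMeans(D[i0:i1, , drop = FALSE])
      ctr <- ctr / sqrt(sum(ctr^2))
      fix[[length(fix) + 1]] <<- data.frame(
        start_s = t[i0], end_s = t[i1] + 1 / record$fs, duration_s = dur,
        cx = ctr[1], cy = ctr[2], cz = ctr[3], n_samples = i1 - i0 + 1)
    }
  }
  i0 <- 1L
  csum <- D[1, ]
  cn <- 1L
  i <- 2L
  while (i <= n) {
    broke <- (t[i] - t[i - 1]) > max_gap
    if (!broke) {
      ctr <- csum / cn
      cand <- (csum + D[i, ]) / (cn + 1)
      # distance of the new point (and implicitly all members) to the
      # updated running centroid
      d_new <- sqrt(sum((D[i, ] - cand / sqrt(sum(cand^2)))^2))
      broke <- d_new >= radius
    }
    if (broke) {
      emit(i0, i - 1L)
      i0 <- i
      csum <- D[i, ]
      cn <- 1L
    } else {
      csum <- csum + D[i, ]
      cn <- cn + 1L
    }
    i <- i + 1L
  }
  emit(i0, n)
  if (length(fix) == 0) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      duration_s = numeric(0), cx = numeric(0),
                      cy = numeric(0), cz = numeric(0), n_samples = integer(0)))
  }
  do.call(rbind, fix)
}

#' Assign fixations to regions of interest
#'
#' Labels each fixation with the nearest ROI anchor by angular distance, or
#' `"NONE"` when the nearest anchor is farther than `max_angle` degrees.
#'
#' @param fixations data frame from [detect_fixations()].
#' @param anchors named m x 3 matrix of unit anchor directions (default
#'   [roi_anchors()]).
#' @param max_angle maximum angular distance in degrees (default 10).
#' @return `fixations` with an added `roi` column.
#' @export
assign_roi <- function(fixations, anchors = roi_anchors(), max_angle = 10) {
  if (nrow(fixations) == 0) {
    fixations$roi <- character(0)
    return(fixations)
  }
  C <- as.matrix(fixations[, c("cx", "cy", "cz")])
  cosang <- C %*% t(anchors)
  cosang <- pmin(pmax(cosang, -1), 1)
  ang <- acos(cosang) * 180 / pi
  best <- max.col(-ang)
  bestang <- ang[cbind(seq_len(nrow(ang)), best)]
  roi <- rownames(anchors)[best]
  roi[bestang > max_angle] <- "NONE"
  fixations$roi <- roi
  fixations
}

#' Per-trial dwell and gaze-shift metrics
#'
#' For each trial: the percentage of trial time covered by Teacher fixations
#' and the number of gaze-shifts away from the teacher (transitions from a
#' Teacher fixation to a non-Teacher fixation).
#'
#' @param fixations ROI-labelled fixations (from [assign_roi()]).
#' @param trials data frame with `trial_index`, `condition`, `onset_s`,
#'   `duration_s`.
#' @return data frame per trial: `trial_index`, `condition`,
#'   `pct_time_on_teacher`, `n_shifts_away`.
#' @export
dwell_and_shift_metrics <- function(fixations, trials) {
  out <- lapply(seq_len(nrow(trials)), function(i) {
    t0 <- trials$onset_s[i]
    t1 <- t0 + trials$duration_s[i]
    f <- fixations[fixations$start_s < t1 & fixations$end_s > t0, , drop = FALSE]
    teach <- f$roi == "Teacher"
    dwell <- sum(pmin(f$end_s[teach], t1) - pmax(f$start_s[teach], t0))
    shifts <- 0L
    if (nrow(f) > 1) {
      shifts <- sum(f$roi[-nrow(f)] == "Teacher" & f$roi[-1] != "Teacher")
    }
    data.frame(trial_index = trials$trial_index[i],
               condition = trials$condition[i],
               pct_time_on_teacher = 100 * dwell / (t1 - t0),
               n_shifts_away = shifts)
  })
  do.call(rbind, out)
}

# shift times: start of the non-Teacher fixation in a Teacher -> elsewhere
# transition
.shift_away_times <- function(fixations) {
  if (nrow(fixations) < 2) return(numeric(0))
  from_teacher <- fixations$roi[-nrow(fixations)] == "Teacher" &
    fixations$roi[-1] != "Teacher"
  fixations$start_s[-1][from_teacher]
}

#' Event-locked gaze-shift analysis
#'
#' Computes the proportion of sound-event epochs (`[onset, onset + window]`)
#' containing at least one gaze-shift away from the teacher, the same
#' proportion over an equal number of random control epochs drawn from Quiet
#' trials, and their difference (the event-locked excess shift rate).
#'
#' @param fixations ROI-labelled fixations.
#' @param events data frame with `onset_s` (and optionally `event_type`).
#' @param quiet_trials data frame of Quiet trials (`onset_s`, `duration_s`).
#' @param window epoch length in seconds (default 2).
#' @return list with `event_prop`, `control_prop`, `normalized`
#'   (event - control), `by_type` (per event type proportions when types are
#'   given), and `control_available`.
#' @export
event_locked_shifts <- function(fixations, events, quiet_trials, window = 2) {
  shifts <- .shift_away_times(fixations)
  hit <- function(onsets) {
    vapply(onsets, function(o) any(shifts >= o & shifts < o + window),
           logical(1))
  }
  ev_hit <- hit(events$onset_s)
  event_prop <- mean(ev_hit)
  control_available <- !is.null(quiet_trials) && nrow(quiet_trials) > 0
  control_prop <- NA_real_
  if (control_available) {
    usable <- quiet_trials[quiet_trials$duration_s > window, , drop = FALSE]
    if (nrow(usable) == 0) {
      control_available <- FALSE
    } else {
      pick_trial <- sample.int(nrow(usable), length(ev_hit), replace = TRUE)
      starts <- usable$onset_s[pick_trial] +
        stats::runif(length(ev_hit)) * (usable$duration_s[pick_trial] - window)
      control_prop <- mean(hit(starts))
    }
  }
  if (!control_available) {
    warning("no usable Quiet trials: control epochs unavailable")
  }
  by_type <- NULL
  if ("event_type" %in% names(events)) {
    by_type <- tapply(ev_hit, events$event_type, mean)
  }
  list(event_prop = event_prop, control_prop = control_prop,
       normalized = if (control_available) event_prop - control_prop else NA_real_,
       by_type = by_type, control_available = control_available)
}
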