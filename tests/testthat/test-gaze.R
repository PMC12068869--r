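mk_record <- function(t, dirs, blink = NULL, fs = 120) {
  gaze_record(t, dirs, blink = blink, fs = fs)
}

test_that("blink scrubbing removes the padded span and nothing else", {
  fs <- 120
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  dirs <- matrix(rep(c(0, 1, 0), each = length(t)), ncol = 3)
  # no blinks -> identity
  r <- mk_record(t, dirs)
  expect_equal(length(clean_gaze(r)$t), length(t))
  # one 100 ms blink removes >= 0.4 s of samples (0.1 + 0.1 + 0.2)
  blink <- t >= 1 & t < 1.1
  rb <- mk_record(t, dirs, blink = blink)
  cl <- clean_gaze(rb)
  removed <- length(t) - length(cl$t)
  expect_gte(removed, round(0.4 * fs) - 1)
  blink_end <- max(t[blink])
  expect_true(all(cl$t < 0.9 + 1e-9 | cl$t > blink_end + 0.2 - 1e-9))
})

test_that("fixation detection follows the dispersion contract", {
  fs <- 120
  # constant direction for 1 s -> exactly one 1 s fixation
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  dirs <- matrix(rep(c(0, 1, 0), each = length(t)), ncol = 3)
  fx <- detect_fixations(mk_record(t, dirs))
  expect_equal(nrow(fx), 1)
  expect_equal(fx$duration_s, 1, tolerance = 1e-9)
  # two anchors 0.1 apart, 0.5 s each -> two fixations, one shift
  a <- c(0, 1, 0)
  b <- a + c(0.1, 0, 0); b <- b / sqrt(sum(b^2))
  t2 <- seq(0, 1 - 1 / fs, by = 1 / fs)
  dirs2 <- rbind(matrix(rep(a, each = 60), ncol = 3),
                 matrix(rep(b, each = 60), ncol = 3))
  fx2 <- detect_fixations(mk_record(t2, dirs2))
  expect_equal(nrow(fx2), 2)
  expect_error(detect_fixations(mk_record(numeric(0),
                                          matrix(0, 0, 3))), "empty")
})

test_that("fixation segmentation is invariant to a global rotation", {
  set.seed(1)
  fs <- 120
  t <- seq(0, 3 - 1 / fs, by = 1 / fs)
  anchors <- rbind(c(0, 1, 0), c(0.08, 1, 0), c(0, 1, 0.08))
  anchors <- anchors / sqrt(rowSums(anchors^2))
  seg <- rep(1:3, each = length(t) / 3)
  dirs <- anchors[seg, ] + matrix(rnorm(3 * length(t), 0, 0.002), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  fx1 <- detect_fixations(mk_record(t, dirs))
  fx2 <- detect_fixations(mk_record(t, dirs %*% t(R)))
  expect_equal(fx1$start_s, fx2$start_s, tolerance = 1e-9)
  expect_equal(fx1$duration_s, fx2$duration_s, tolerance = 1e-9)
})

test_that("ROI assignment picks the nearest anchor within the angular limit", {
  anchors <- roi_anchors()
  fx <- data.frame(start_s = 0, end_s = 1, duration_s = 1,
                   cx = anchors["Teacher", 1], cy = anchors["Teacher", 2],
                   cz = anchors["Teacher", 3], n_samples = 120)
  expect_equal(assign_roi(fx)$roi, "Teacher")
  # 20 degrees away from everything -> NONE
  odd <- c(sin(0.6), cos(0.6) * cos(1.2), sin(1.2))
  odd <- odd / sqrt(sum(odd^2))
  fx2 <- fx; fx2[, c("cx", "cy", "cz")] <- rbind(odd)
  expect_equal(assign_roi(fx2, max_angle = 10)$roi, "NONE")
})

test_that("dwell and shift metrics count teacher time and departures", {
  trials <- data.frame(trial_index = 1L, condition = "EVENTS",
                       onset_s = 0, duration_s = 10)
  fx <- data.frame(
    start_s = c(0, 3, 5, 8), end_s = c(3, 5, 8, 10),
    duration_s = c(3, 2, 3, 2),
    cx = 0, cy = 1, cz = 0, n_samples = 1,
    roi = c("Teacher", "LeftBoard", "Teacher", "RightBoard"))
  m <- dwell_and_shift_metrics(fx, trials)
  expect_equal(m$pct_time_on_teacher, 60)
  expect_equal(m$n_shifts_away, 2)
  # all-teacher trial: 100%, zero shifts
  fx_t <- fx; fx_t$roi <- "Teacher"
  m2 <- dwell_and_shift_metrics(fx_t, trials)
  expect_equal(m2$pct_time_on_teacher, 100)
  expect_equal(m2$n_shifts_away, 0)
})

test_that("event-locked shift proportions are zero without shifts and flag missing controls", {
  fx <- data.frame(start_s = 0, end_s = 60, duration_s = 60, cx = 0, cy = 1,
                   cz = 0, n_samples = 1, roi = "Teacher")
  events <- data.frame(onset_s = c(5, 15, 25))
  quiet <- data.frame(trial_index = 9L, condition = "QUIET", onset_s = 40,
                      duration_s = 20)
  set.seed(2)
  res <- event_locked_shifts(fx, events, quiet)
  expect_equal(res$event_prop, 0)
  expect_equal(res$control_prop, 0)
  expect_equal(res$normalized, 0)
  expect_warning(event_locked_shifts(fx, events, quiet[0, ]), "control")
})

test_that("fixation + gap durations tile the cleaned record", {
  set.seed(3)
  cfg <- sim_config_small(gaze_noise = 0.001)
  sched <- generate_event_schedule(cfg)
  subject <- list(shift_gain = 1)
  g <- simulate_gaze(sched, subject, cfg)
  cl <- clean_gaze(g$gaze)
  fx <- detect_fixations(cl)
  span <- max(cl$t) + 1 / cl$fs - min(cl$t)
  covered <- sum(fx$duration_s)
  expect_lte(covered, span + 1e-6)
  expect_gt(covered / span, 0.5)
})
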