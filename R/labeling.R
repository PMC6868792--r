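#' Build the cued training posture schedule
#'
#' The training protocol cycles through all 27 combinations of the three
#' DOFs each at full negative, neutral or full positive excursion, in seeded
#' random order, with each posture repeated `repetitions` times. Every trial
#' is Prepare (2 s), Go (2 s), Rest (1 s), contiguous and non-overlapping.
#'
#' @param repetitions Number of repetitions of each of the 27 codes
#'   (default 5, giving 135 trials).
#' @param seed Integer seed for the presentation order.
#' @param prepare_s,go_s,rest_s Phase durations in seconds.
#' @return Object of class `cue_schedule`: data frame with one row per
#'   trial (`trial`, `pronation`, `wrist`, `aperture`, `start`, `prepare_s`,
#'   `go_s`, `rest_s`), attribute `duration` = total schedule length.
#' @export
build_cue_schedule <- function(repetitions = 5L, seed = 1L,
                               prepare_s = 2, go_s = 2, rest_s = 1) {
  if (repetitions < 1L) stopf("repetitions must be >= 1")
  if (prepare_s <= 0 || go_s <= 0 || rest_s <= 0) {
    stopf("phase durations must be positive")
  }
  codes <- as.matrix(expand.grid(pronation = -1:1, wrist = -1:1, aperture = -1:1))
  codes <- codes[rep(seq_len(27L), repetitions), , drop = FALSE]
  ord <- with_seed(seed, sample.int(nrow(codes)))
  codes <- codes[ord, , drop = FALSE]
  n <- nrow(codes)
  span <- prepare_s + go_s + rest_s
  sched <- data.frame(
    trial = seq_len(n),
    pronation = codes[, 1], wrist = codes[, 2], aperture = codes[, 3],
    start = (seq_len(n) - 1) * span,
    prepare_s = prepare_s, go_s = go_s, rest_s = rest_s,
    row.names = NULL
  )
  structure(sched, class = c("cue_schedule", "data.frame"),
            duration = n * span)
}

#' Active-movement window of a cued trial
#'
#' EMG activity under the protocol runs through the Go phase and spills
#' roughly 1.5 s into the following Rest (and next Prepare), so training
#' labels are taken from Go start to Go end + 1.5 s, truncated at the
#' schedule end.
#'
#' @param schedule A [build_cue_schedule()] result.
#' @param trial Trial index (row of the schedule).
#' @return Numeric `(start_s, end_s)` of the active window.
#' @export
active_window <- function(schedule, trial) {
  tr <- schedule[trial, ]
  start <- tr$start + tr$prepare_s
  end <- min(start + tr$go_s + 1.5, attr(schedule, "duration"))
  c(start = start, end = end)
}

#' Nominal intent trajectory executed by the virtual subject during training
#'
#' During each trial's active window the subject drives toward the cued
#' posture code at a sustained effort level, with a linear ramp up at
#' window start and a ramp down at window end; intent is zero elsewhere.
#' Used to synthesize training EMG for the cue protocol.
#'
#' @param schedule A [build_cue_schedule()] result.
#' @param effort Plateau intent magnitude in `(0, 1]` (default 0.8, a
#'   low-to-moderate sustained contraction).
#' @param step_s Cadence of the returned series (default 0.05 s).
#' @param ramp_s Rise time at window start (default 0.1 s).
#' @param fall_s Fall time at window end (default 0.3 s).
#' @return An [intent_series()] spanning the schedule.
#' @export
training_intent <- function(schedule, effort = 0.8, step_s = 0.05,
                            ramp_s = 0.1, fall_s = 0.3) {
  duration <- attr(schedule, "duration")
  times <- seq(step_s, duration, by = step_s)
  values <- matrix(0, length(times), 3)
  for (i in seq_len(nrow(schedule))) {
    win <- active_window(schedule, i)
    idx <- which(times > win[1] & times <= win[2])
    if (!length(idx)) next
    t_rel <- times[idx] - win[1]
    t_left <- win[2] - times[idx]
    e <- effort * pmin(1, t_rel / ramp_s, pmax(0, t_left) / fall_s)
    code <- as.numeric(schedule[i, c("pronation", "wrist", "aperture")])
    values[idx, ] <- outer(e, code)
  }
  intent_series(times, values)
}

#' Construct assumed-intent training labels
#'
#' The regression target for each feature frame: outside every active
#' window the intent is `[0, 0, 0]`; inside a trial's window it is the
#' trial's posture code scaled by the momentary effort
#' `e(t) = m(t) / mean(m over the window)`, where `m(t)` is the mean of the
#' 8 MAV features, clipped to `[0, 1]` so labels stay within the code cube.
#' Frames falling in two overlapping windows are assigned to the earlier
#' trial (later cues have not yet been acted on).
#'
#' @param features A [extract_features()] `feature_frame` covering the
#'   schedule (normalized or raw; effort scaling is scale-invariant).
#' @param schedule The matching [build_cue_schedule()].
#' @param clip_effort Clip `e(t)` to `[0, 1]`? Default `TRUE`.
#' @param per_trial_scalar If `TRUE`, use a constant effort of 1 per trial
#'   (labels are the bare codes inside windows); sensitivity-analysis mode.
#' @return An [intent_series()] aligned to `features$times`.
#' @export
assumed_intent <- function(features, schedule, clip_effort = TRUE,
                           per_trial_scalar = FALSE) {
  times <- features$times
  duration <- attr(schedule, "duration")
  if (!length(times) || min(times) > duration || max(times) < duration / 2) {
    stopf("feature frame does not cover the cue schedule (time-base mismatch)")
  }
  n_ch <- ncol(features$values) %/% 2L
  m <- rowMeans(features$values[, seq_len(n_ch), drop = FALSE])
  values <- matrix(0, length(times), 3)
  assigned <- logical(length(times))
  for (i in seq_len(nrow(schedule))) {
    win <- active_window(schedule, i)
    idx <- which(!assigned & times > win[1] & times <= win[2])
    if (!length(idx)) next
    assigned[idx] <- TRUE
    code <- as.numeric(schedule[i, c("pronation", "wrist", "aperture")])
    if (per_trial_scalar) {
      e <- rep(1, length(idx))
    } else {
      mbar <- mean(m[idx])
      if (mbar <= 0) {
        warning(sprintf("trial %d: zero mean MAV in active window; labels left at 0", i))
        next
      }
      e <- m[idx] / mbar
      if (clip_effort) e <- clip(e, 0, 1)
    }
    values[idx, ] <- outer(e, code)
  }
  intent_series(times, values, range_check = clip_effort || per_trial_scalar)
}
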