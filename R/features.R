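#' Mean absolute value of a window
#'
#' Time-domain EMG amplitude feature: the mean of the rectified signal.
#'
#' @param window Non-empty numeric vector.
#' @return Non-negative scalar.
#' @export
mav <- function(window) {
  if (length(window) < 1L) stopf("mav: empty window")
  mean(abs(window))
}

#' Waveform length of a window
#'
#' Cumulative absolute first difference over the window; mixes amplitude and
#' frequency content. No carry-over across windows.
#'
#' @param window Numeric vector of length >= 2.
#' @return Non-negative scalar.
#' @export
wfl <- function(window) {
  if (length(window) < 2L) stopf("wfl: window must have length >= 2")
  sum(abs(diff(window)))
}

#' Sliding-window sample index blocks
#'
#' Frame k (1-based) covers samples `[(k-1)*step + 1, (k-1)*step + window]`;
#' trailing partial windows are dropped (causal semantics: a frame's features
#' describe the preceding `window_s` of signal).
#'
#' @param recording An [emg_recording()].
#' @param window_s Window length in seconds (default 0.2).
#' @param step_s Step in seconds (default 0.05).
#' @return List with `starts` (integer vector of first sample per frame),
#'   `window` (samples per frame) and `times` (frame end-times in seconds).
#' @export
sliding_windows <- function(recording, window_s = 0.2, step_s = 0.05) {
  fs <- recording$sample_rate
  w <- window_s * fs
  s <- step_s * fs
  if (abs(w - round(w)) > 1e-9 || abs(s - round(s)) > 1e-9 || w < 1 || s < 1) {
    stopf("window_s and step_s must be whole positive numbers of samples")
  }
  w <- as.integer(round(w)); s <- as.integer(round(s))
  n <- ncol(recording$samples)
  if (n < w) stopf("recording (%d samples) shorter than one window (%d)", n, w)
  n_frames <- (n - w) %/% s + 1L
  starts <- (seq_len(n_frames) - 1L) * s + 1L
  list(starts = starts, window = w, times = (starts - 1L + w) / fs)
}

#' Extract MAV and WFL features on the standard 200 ms / 50 ms grid
#'
#' Produces one feature row per frame: all channels' MAV first, then all
#' channels' WFL, channel order preserved (16 columns for 8 channels).
#'
#' @param recording An [emg_recording()].
#' @param window_s,step_s Window and step in seconds (defaults 0.2 / 0.05).
#' @return Object of class `feature_frame`: list with `times` (frame
#'   end-times), `values` (`n_frames x 2*n_channels` matrix), `window_s`,
#'   `step_s` and `channel_labels`.
#' @export
extract_features <- function(recording, window_s = 0.2, step_s = 0.05) {
  sw <- sliding_windows(recording, window_s, step_s)
  x <- recording$samples
  n_ch <- nrow(x)
  n_frames <- length(sw$starts)
  vals <- matrix(0, n_frames, 2L * n_ch)
  for (k in seq_len(n_frames)) {
    block <- x[, sw$starts[k]:(sw$starts[k] + sw$window - 1L), drop = FALSE]
    vals[k, seq_len(n_ch)] <- rowMeans(abs(block))
    vals[k, n_ch + seq_len(n_ch)] <- rowSums(abs(block[, -1L, drop = FALSE] -
                                                   block[, -sw$window, drop = FALSE]))
  }
  colnames(vals) <- c(paste0("mav_", recording$channel_labels),
                      paste0("wfl_", recording$channel_labels))
  structure(
    list(times = sw$times, values = vals, window_s = window_s, step_s = step_s,
         channel_labels = recording$channel_labels),
    class = "feature_frame"
  )
}

#' @export
print.feature_frame <- function(x, ...) {
  cat(sprintf("<feature_frame> %d frames x %d features (%g ms window / %g ms step)\n",
              nrow(x$values), ncol(x$values), 1000 * x$window_s, 1000 * x$step_s))
  invisible(x)
}

#' Fit per-dimension max normalization
#'
#' Each feature dimension of the training set is divided by its training
#' maximum so the training data has per-dimension max exactly 1. The scale
#' is then applied unchanged to later (online) frames, which may exceed 1.
#'
#' @param train A training [extract_features()] `feature_frame`.
#' @return Object of class `feature_scale`: named vector of positive divisors.
#' @export
fit_normalization <- function(train) {
  if (nrow(train$values) < 1L) stopf("empty training feature frame")
  divisors <- apply(train$values, 2, max)
  dead <- which(divisors <= 0)
  if (length(dead)) {
    stopf("degenerate feature dimension(s) with max 0: %s",
          paste(colnames(train$values)[dead], collapse = ", "))
  }
  structure(divisors, class = "feature_scale")
}

#' Apply a fitted normalization scale
#'
#' @param frame A `feature_frame` (or bare numeric matrix / vector laid out
#'   like one).
#' @param scale A [fit_normalization()] `feature_scale`.
#' @return Same shape as the input, with each dimension divided by its
#'   training divisor. No clipping is applied.
#' @export
apply_normalization <- function(frame, scale) {
  d <- unclass(scale)
  if (inherits(frame, "feature_frame")) {
    if (ncol(frame$values) != length(d)) stopf("feature/scale dimension mismatch")
    frame$values <- sweep(frame$values, 2, d, "/")
    return(frame)
  }
  if (is.matrix(frame)) {
    if (ncol(frame) != length(d)) stopf("feature/scale dimension mismatch")
    return(sweep(frame, 2, d, "/"))
  }
  if (length(frame) != length(d)) stopf("feature/scale dimension mismatch")
  frame / d
}
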