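#' Path efficiency of a trial trajectory
#'
#' Straightness of the hand path: the straight-line distance from the
#' starting posture to the arrival point, divided by the distance actually
#' traveled to get there, as a percentage. Distances are Euclidean in
#' ROM-normalized coordinates (each DOF mapped to `[0, 1]`), so degrees and
#' percent are commensurable. By default the path is measured up to the
#' point where the successful dwell began (holding still does not count as
#' travel); `end_index` selects that point.
#'
#' @param trajectory `n x 3` matrix of hand states (or a `trial_record`'s
#'   trajectory), `n >= 2`.
#' @param target Target [hand_state()] (used only through the trajectory
#'   endpoint; retained for interface symmetry).
#' @param end_index Row of the trajectory taken as the arrival point
#'   (default: last row).
#' @return Percent in `[0, 100]`; conventions: zero travel with zero
#'   straight-line distance gives 100 (already on target), zero travel with
#'   positive distance gives 0.
#' @export
path_efficiency <- function(trajectory, target = NULL, end_index = NULL) {
  tr <- as.matrix(trajectory)
  if (nrow(tr) < 2L) stopf("path_efficiency needs a trajectory of length >= 2")
  if (is.null(end_index) || is.na(end_index)) end_index <- nrow(tr)
  tr <- tr[seq_len(end_index), , drop = FALSE]
  norm <- sweep(sweep(tr, 2, ROM_LIMITS["lower", ]), 2, rom_span(), "/")
  if (nrow(norm) < 2L) return(100)
  steps <- diff(norm)
  traveled <- sum(sqrt(rowSums(steps^2)))
  straight <- sqrt(sum((norm[nrow(norm), ] - norm[1L, ])^2))
  if (traveled == 0) return(if (straight == 0) 100 else 0)
  100 * straight / traveled
}

#' Posture-matching success rate of a session
#'
#' @param session A [run_session()] `session_result` (or list of
#'   `trial_record`s).
#' @return Percent of trials successfully matched.
#' @export
success_rate <- function(session) {
  trials <- if (inherits(session, "session_result")) session$trials else session
  if (!length(trials)) stopf("empty session")
  100 * mean(vapply(trials, function(t) isTRUE(t$success), logical(1)))
}

#' Trial time used
#'
#' Seconds from trial start to dwell completion (including the 1 s dwell);
#' failed trials report the 30 s timeout, flagged via the `failed`
#' attribute.
#'
#' @param trial A `trial_record`.
#' @return Seconds, with attribute `failed`.
#' @export
trial_time <- function(trial) {
  structure(trial$trial_time_s, failed = !trial$success)
}

#' Session-level metric summary
#'
#' Mean and SD of path efficiency and trial time plus the success rate,
#' mirroring per-session performance summaries. Failed trials are included
#' by default (path efficiency over the full 30 s, time = 30 s).
#'
#' @param session A `session_result`.
#' @param include_failures Include failed trials in the PE/time summaries?
#'   Default `TRUE`.
#' @return List of class `session_summary`.
#' @export
summarize_session <- function(session, include_failures = TRUE) {
  trials <- session$trials
  if (!length(trials)) stopf("empty session")
  ok <- vapply(trials, function(t) isTRUE(t$success), logical(1))
  keep <- if (include_failures) rep(TRUE, length(trials)) else ok
  pe <- vapply(trials[keep], function(t) t$path_efficiency, numeric(1))
  tt <- vapply(trials[keep], function(t) t$trial_time_s, numeric(1))
  structure(
    list(n_trials = length(trials),
         success_rate = 100 * mean(ok),
         path_efficiency_mean = mean(pe), path_efficiency_sd = sd(pe),
         trial_time_mean = mean(tt), trial_time_sd = sd(tt),
         path_efficiencies = pe, trial_times = tt),
    class = "session_summary"
  )
}

#' Tabulate per-trial metrics of one or more sessions
#'
#' @param sessions Named list of `session_result`s (names become condition
#'   labels), or a single session.
#' @return Data frame with one row per trial: `condition`, `block`,
#'   `trial`, target triple, `success`, `trial_time_s`, `path_efficiency`.
#' @export
session_table <- function(sessions) {
  if (inherits(sessions, "session_result")) sessions <- list(session = sessions)
  rows <- lapply(names(sessions), function(nm) {
    s <- sessions[[nm]]
    if (!length(s$trials)) return(NULL)
    do.call(rbind, lapply(seq_along(s$trials), function(i) {
      t <- s$trials[[i]]
      data.frame(condition = nm, block = s$block[i], trial = i,
                 target_pronation = t$target[1], target_wrist = t$target[2],
                 target_aperture = t$target[3], success = t$success,
                 trial_time_s = t$trial_time_s,
                 path_efficiency = t$path_efficiency)
    }))
  })
  do.call(rbind, rows)
}
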