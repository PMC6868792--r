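#' Virtual hand posture
#'
#' One posture of the 3-DOF virtual hand: forearm pronation/supination in
#' `[0, 180]` degrees, wrist flexion/extension in `[-60, 70]` degrees, and
#' hand aperture in `[0, 100]` percent.
#'
#' @param pronation,wrist,aperture DOF values; default is the neutral
#'   posture (per-DOF ROM midpoints: 90 deg, 5 deg, 50%).
#' @return Named numeric 3-vector of class `hand_state`.
#' @export
hand_state <- function(pronation = 90, wrist = 5, aperture = 50) {
  x <- c(pronation = pronation, wrist = wrist, aperture = aperture)
  if (any(x < ROM_LIMITS["lower", ] - 1e-9) || any(x > ROM_LIMITS["upper", ] + 1e-9)) {
    stopf("hand state outside range of motion")
  }
  structure(as.numeric(x), names = DOF_NAMES, class = "hand_state")
}

#' Neutral hand posture (per-DOF ROM midpoints)
#' @return A [hand_state()].
#' @export
neutral_hand <- function() do.call(hand_state, as.list(rom_neutral()))

#' Velocity controller configuration
#'
#' Per-DOF shaping of the decoder's normalized velocity command: values
#' below the threshold are treated as noise and zeroed, the rest are
#' multiplied by the gain, and the result is mapped to physical units
#' (deg/s for pronation and wrist, %/s for aperture) with magnitude capped
#' at `max_speed`.
#'
#' @param threshold Per-DOF dead-zone as a fraction of the normalized
#'   velocity range, in `[0, 1)` (default 0.10).
#' @param gain Per-DOF multiplier (> 0; typical 3, up to 10).
#' @param dt Control-loop period in seconds (default 0.05).
#' @param max_speed Per-DOF physical speed of a saturated command; default
#'   one full ROM per second: `c(180, 130, 100)`.
#' @return Object of class `controller_config`.
#' @export
controller_config <- function(threshold = 0.10, gain = 3, dt = 0.05,
                              max_speed = c(180, 130, 100)) {
  threshold <- rep_len(threshold, 3L)
  gain <- rep_len(gain, 3L)
  max_speed <- rep_len(max_speed, 3L)
  if (any(threshold < 0 | threshold >= 1)) stopf("thresholds must be in [0, 1)")
  if (any(gain <= 0)) stopf("gains must be > 0")
  if (dt <= 0) stopf("dt must be > 0")
  structure(list(threshold = threshold, gain = gain, dt = dt,
                 max_speed = max_speed),
            class = "controller_config")
}

#' Shape a raw decoder command into a physical velocity
#'
#' @param raw Normalized command 3-vector in `[-1, 1]`.
#' @param cfg A [controller_config()].
#' @return Physical velocity 3-vector (deg/s, deg/s, %/s), magnitude capped
#'   at `cfg$max_speed` per DOF.
#' @export
shape_velocity <- function(raw, cfg) {
  v <- ifelse(abs(raw) < cfg$threshold, 0, raw * cfg$gain)
  clip(v, -1, 1) * cfg$max_speed
}

#' Integrate the hand state one control step
#'
#' @param state A [hand_state()].
#' @param v Physical velocity 3-vector (units/s).
#' @param dt Step in seconds.
#' @return New [hand_state()], saturated at the ROM bounds (no wrap).
#' @export
integrate_hand <- function(state, v, dt) {
  x <- clip(as.numeric(state) + v * dt, ROM_LIMITS["lower", ], ROM_LIMITS["upper", ])
  structure(x, names = DOF_NAMES, class = "hand_state")
}

#' Session specification for the posture-matching task
#'
#' @param n_targets Total targets (default 80).
#' @param block_size Targets per block (default 16; must divide `n_targets`).
#' @param protocol `"temporal"` (random separated targets) or `"postural"`
#'   (alternating neutral/extreme blocks).
#' @param seed Integer seed.
#' @return Object of class `session_spec`.
#' @export
session_spec <- function(n_targets = 80L, block_size = 16L,
                         protocol = c("temporal", "postural"), seed = 1L) {
  protocol <- match.arg(protocol)
  if (n_targets > 0 && n_targets %% block_size != 0) {
    stopf("n_targets must be divisible by block_size")
  }
  structure(list(n_targets = as.integer(n_targets),
                 block_size = as.integer(block_size),
                 protocol = protocol, seed = as.integer(seed)),
            class = "session_spec")
}

#' Generate the random target sequence of a temporal-stability session
#'
#' Seeded rejection sampling: every target is at least 15% of the ROM away
#' from both ROM bounds in every DOF (so all targets can be overshot), and
#' every consecutive pair differs by at least 30% of the ROM in every DOF.
#'
#' @param spec A [session_spec()] with `protocol = "temporal"`.
#' @param max_draws Rejection-sampling cap (default 1e5).
#' @return List of `n_targets` [hand_state()]s, attribute `block` giving
#'   each target's block index.
#' @export
generate_session_targets <- function(spec, max_draws = 1e5) {
  stopifnot(inherits(spec, "session_spec"))
  if (spec$protocol != "temporal") stopf("temporal protocol required")
  lo <- ROM_LIMITS["lower", ] + 0.15 * rom_span()
  hi <- ROM_LIMITS["upper", ] - 0.15 * rom_span()
  min_sep <- 0.30 * rom_span()
  targets <- with_seed(spec$seed, {
    out <- vector("list", spec$n_targets)
    prev <- NULL
    draws <- 0L
    for (i in seq_len(spec$n_targets)) {
      repeat {
        draws <- draws + 1L
        if (draws > max_draws) {
          stopf("target generation exceeded %d draws", max_draws)
        }
        cand <- lo + runif(3) * (hi - lo)
        if (is.null(prev) || all(abs(cand - prev) >= min_sep)) break
      }
      out[[i]] <- do.call(hand_state, as.list(cand))
      prev <- cand
    }
    out
  })
  attr(targets, "block") <- rep(seq_len(spec$n_targets %/% spec$block_size),
                                each = spec$block_size)
  targets
}

#' Generate one postural-stability block of 16 targets
#'
#' Alternates the neutral posture (per-DOF ROM midpoints) with extreme
#' targets whose DOFs each sit at 10% or 90% of the ROM (chosen with seeded
#' randomness), starting with neutral.
#'
#' @param seed Integer seed.
#' @return List of 16 [hand_state()]s.
#' @export
generate_postural_block <- function(seed = 1L) {
  lo <- ROM_LIMITS["lower", ]
  span <- rom_span()
  with_seed(seed, {
    lapply(seq_len(16L), function(i) {
      if (i %% 2L == 1L) {
        neutral_hand()
      } else {
        frac <- ifelse(runif(3) < 0.5, 0.10, 0.90)
        do.call(hand_state, as.list(lo + frac * span))
      }
    })
  })
}

# One 200 ms constant-intent EMG window from the generator, as a raw
# 16-feature vector. Draws from the current RNG stream; cfg must carry a
# fixed noise_sd (online calibration is frozen at training time).
online_feature_vector <- function(intent, cfg, filt, n_window) {
  act <- as.numeric(cfg$synergy %*% intent)
  act <- pmax(0, act) + cfg$baseline_activation
  carriers <- vapply(seq_len(cfg$n_muscles), function(m) make_carrier(n_window, filt),
                     numeric(n_window))
  sources <- t(carriers) * act                      # n_muscles x n
  n_ch <- nrow(cfg$crosstalk)
  sigma <- rep_len(cfg$noise_sd, n_ch)
  chans <- cfg$crosstalk %*% sources +
    matrix(rnorm(n_ch * n_window), n_ch, n_window) * sigma
  c(rowMeans(abs(chans)),
    rowSums(abs(chans[, -1L, drop = FALSE] - chans[, -n_window, drop = FALSE])))
}

#' Run one closed-loop posture-matching trial
#'
#' The loop at `dt = 50` ms: the virtual subject forms a proportional
#' intent from the (reaction-delayed) target error; the generator
#' synthesizes a 200 ms EMG window at that intent; MAV/WFL features are
#' extracted, normalized with the decoder's training scale and decoded to a
#' velocity command; the command is threshold/gain shaped and integrated
#' into the hand state. Success requires all three DOFs simultaneously
#' within ±15% of ROM of the target for 20 consecutive frames (1 s dwell,
#' counted from scratch after any excursion); otherwise the trial fails at
#' 30 s.
#'
#' @param decoder A [knn_decoder()], a `function(feature_vector) -> 3-vector`
#'   custom decoder, or `NULL` for the oracle bypass (the subject's intent
#'   is used directly as the raw command; ceiling condition).
#' @param policy A [subject_policy()].
#' @param generator_cfg A [virtual_subject_config()] with `noise_sd` set
#'   (see [calibrate_generator()]); may be `NULL` with `decoder = NULL`.
#' @param target Target [hand_state()].
#' @param start Initial [hand_state()] (previous trial's final state, or
#'   neutral).
#' @param cfg A [controller_config()].
#' @param seed Integer seed for this trial's EMG and intent noise.
#' @param tolerance In-target tolerance as a fraction of ROM (default 0.15,
#'   closed: exactly 15% counts as in).
#' @param dwell_s Required hold time (default 1 s).
#' @param timeout_s Trial cap (default 30 s).
#' @return Object of class `trial_record`: `target`, `trajectory`
#'   (`frames x 3` matrix of hand states, first row = start), `success`,
#'   `trial_time_s`, `path_efficiency`, `dwell_start` (frame index where
#'   the successful dwell began, `NA` on failure).
#' @export
run_trial <- function(decoder, policy, generator_cfg, target,
                      start = neutral_hand(), cfg = controller_config(),
                      seed = 1L, tolerance = 0.15, dwell_s = 1,
                      timeout_s = 30) {
  use_emg <- !is.null(decoder)
  if (use_emg && inherits(decoder, "knn_decoder") &&
      (is.null(generator_cfg) || is.null(generator_cfg$noise_sd))) {
    stopf("generator_cfg must carry a fixed noise_sd for closed-loop use; see calibrate_generator()")
  }
  dt <- cfg$dt
  n_frames <- round(timeout_s / dt)
  n_dwell <- round(dwell_s / dt)
  delay_frames <- round(policy$reaction_delay / dt)
  tol <- tolerance * rom_span()
  tgt <- as.numeric(target)

  filt <- NULL; n_window <- NULL
  if (use_emg && !is.function(decoder)) {
    filt <- carrier_filter(generator_cfg)
    n_window <- as.integer(round(0.2 * generator_cfg$sample_rate))
  }

  with_seed(seed, {
    traj <- matrix(NA_real_, n_frames + 1L, 3,
                   dimnames = list(NULL, DOF_NAMES))
    traj[1L, ] <- as.numeric(start)
    hand <- start
    run <- 0L
    success <- FALSE
    dwell_start <- NA_integer_
    last_frame <- n_frames
    for (f in seq_len(n_frames)) {
      seen <- traj[max(1L, f - delay_frames), ]   # reaction-delayed hand state
      intent <- virtual_subject_intent(seen, tgt, policy)
      raw <- if (!use_emg) {
        intent
      } else if (is.function(decoder)) {
        decoder(intent)
      } else {
        feats <- online_feature_vector(intent, generator_cfg, filt, n_window)
        predict(decoder, feats)
      }
      hand <- integrate_hand(hand, shape_velocity(raw, cfg), dt)
      traj[f + 1L, ] <- as.numeric(hand)
      if (all(abs(as.numeric(hand) - tgt) <= tol + 1e-12)) {
        run <- run + 1L
        if (run >= n_dwell) {
          success <- TRUE
          dwell_start <- f - n_dwell + 2L   # trajectory row where dwell began
          last_frame <- f
          break
        }
      } else {
        run <- 0L
      }
    }
    traj <- traj[seq_len(last_frame + 1L), , drop = FALSE]
    trial_time <- if (success) last_frame * dt else timeout_s
    pe_end <- if (success) dwell_start else nrow(traj)
    pe <- path_efficiency(traj, target, end_index = pe_end)
    structure(
      list(target = target, trajectory = traj, success = success,
           trial_time_s = trial_time, path_efficiency = pe,
           dwell_start = dwell_start),
      class = "trial_record"
    )
  })
}

#' Freeze a generator's noise calibration for online use
#'
#' Copies the per-channel noise SD realized in a (training) recording into
#' the configuration, so closed-loop EMG windows share the training
#' amplitude scale.
#'
#' @param cfg A [virtual_subject_config()].
#' @param recording The [simulate_emg()] training recording.
#' @return The configuration with `noise_sd` set.
#' @export
calibrate_generator <- function(cfg, recording) {
  sigma <- attr(recording, "noise_sd")
  if (is.null(sigma)) stopf("recording carries no noise_sd attribute")
  cfg$noise_sd <- sigma
  cfg
}

#' Run a full posture-matching session
#'
#' Trials run in order; the hand state carries over between trials within a
#' block and resets to neutral at each block start. Trial seeds are derived
#' from the session seed.
#'
#' @param targets List of [hand_state()] targets (e.g. from
#'   [generate_session_targets()]), or a `session_spec` from which temporal
#'   targets are generated.
#' @param decoder,policy,generator_cfg,cfg As in [run_trial()].
#' @param seed Session seed for per-trial seeds.
#' @param block_size Targets per block (used when `targets` is a bare list;
#'   default 16).
#' @param ... Passed to [run_trial()].
#' @return Object of class `session_result`: list with `trials` (list of
#'   `trial_record`), `block` (per-trial block index) and `summary` (from
#'   [summarize_session()]).
#' @export
run_session <- function(targets, decoder, policy,
                        generator_cfg = NULL, cfg = controller_config(),
                        seed = 1L, block_size = 16L, ...) {
  if (inherits(targets, "session_spec")) {
    spec <- targets
    targets <- generate_session_targets(spec)
    block_size <- spec$block_size
  }
  n <- length(targets)
  if (n == 0L) {
    return(structure(list(trials = list(), block = integer(0),
                          summary = NULL), class = "session_result"))
  }
  blocks <- attr(targets, "block")
  if (is.null(blocks)) blocks <- ((seq_len(n) - 1L) %/% block_size) + 1L
  trial_seeds <- with_seed(seed, sample.int(.Machine$integer.max %/% 2L, n))
  trials <- vector("list", n)
  hand <- neutral_hand()
  for (i in seq_len(n)) {
    if (i > 1L && blocks[i] != blocks[i - 1L]) hand <- neutral_hand()
    trials[[i]] <- run_trial(decoder, policy, generator_cfg, targets[[i]],
                             start = hand, cfg = cfg, seed = trial_seeds[i], ...)
    hand <- do.call(hand_state,
                    as.list(trials[[i]]$trajectory[nrow(trials[[i]]$trajectory), ]))
  }
  res <- structure(list(trials = trials, block = blocks, summary = NULL),
                   class = "session_result")
  res$summary <- summarize_session(res)
  res
}

#' @export
print.session_result <- function(x, ...) {
  if (!length(x$trials)) {
    cat("<session_result> empty session (summary undefined)\n")
    return(invisible(x))
  }
  s <- x$summary
  cat(sprintf("<session_result> %d trials | success %.1f%% | PE %.1f +/- %.1f%% | time %.2f +/- %.2f s\n",
              length(x$trials), s$success_rate, s$path_efficiency_mean,
              s$path_efficiency_sd, s$trial_time_mean, s$trial_time_sd))
  invisible(x)
}
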