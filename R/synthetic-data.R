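#' EMG recording container
#'
#' Bundles a multichannel EMG signal with its sampling metadata. Amplitudes
#' are in arbitrary units; channels are rows.
#'
#' @param samples Numeric matrix, `n_channels x n_samples`, all finite.
#' @param sample_rate Sampling rate in Hz (> 0).
#' @param channel_labels Character vector of channel names; defaults to
#'   `ch1..chN`.
#' @param condition Recording condition tag, one of `"intramuscular"`,
#'   `"surface"` or `"other"`.
#' @return An object of class `emg_recording`.
#' @export
emg_recording <- function(samples, sample_rate,
                          channel_labels = NULL,
                          condition = c("other", "intramuscular", "surface")) {
  condition <- match.arg(condition)
  samples <- as.matrix(samples)
  if (nrow(samples) < 1L) stopf("recording needs at least one channel")
  if (!all(is.finite(samples))) stopf("recording contains non-finite samples")
  if (!is.numeric(sample_rate) || sample_rate <= 0) {
    stopf("sample_rate must be positive")
  }
  if (is.null(channel_labels)) {
    channel_labels <- paste0("ch", seq_len(nrow(samples)))
  }
  if (length(channel_labels) != nrow(samples)) {
    stopf("channel_labels length (%d) != number of channels (%d)",
          length(channel_labels), nrow(samples))
  }
  rownames(samples) <- channel_labels
  structure(
    list(samples = samples, sample_rate = sample_rate,
         channel_labels = channel_labels, condition = condition),
    class = "emg_recording"
  )
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %d channels x %d samples @ %g Hz (%.2f s), condition: %s\n",
              nrow(x$samples), ncol(x$samples), x$sample_rate,
              ncol(x$samples) / x$sample_rate, x$condition))
  invisible(x)
}

#' Intent time series container
#'
#' Three degree-of-freedom intent vectors in `[-1, 1]` aligned to a time
#' base (typically the feature-frame cadence). DOF order is
#' `[pronation/supination, wrist flexion/extension, hand close/open]`.
#'
#' @param times Numeric vector of times in seconds, strictly increasing.
#' @param values Numeric matrix `length(times) x 3` with entries in `[-1, 1]`.
#' @param range_check Enforce the `[-1, 1]` cube (default `TRUE`; disabled
#'   only for diagnostic series such as unclipped assumed-intent labels).
#' @return An object of class `intent_series`.
#' @export
intent_series <- function(times, values, range_check = TRUE) {
  values <- as.matrix(values)
  if (length(times) != nrow(values)) stopf("times/values length mismatch")
  if (ncol(values) != 3L) stopf("intent must have 3 columns (DOFs)")
  if (any(!is.finite(values))) stopf("intent values must be finite")
  if (range_check && any(abs(values) > 1 + 1e-12)) {
    stopf("intent values must be within [-1, 1]")
  }
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stopf("times must be strictly increasing")
  }
  colnames(values) <- DOF_NAMES
  structure(list(times = as.numeric(times), values = values),
            class = "intent_series")
}

#' Random directional tuning (synergy) matrix
#'
#' Draws unit-norm tuning vectors mapping 3-DOF intent to muscle drive.
#' The first six muscles are jittered antagonist pairs along the three DOF
#' axes (each DOF pulled by one agonist/antagonist pair, as in a wrist and
#' hand muscle set); remaining muscles get random oblique tunings.
#'
#' @param n_muscles Number of muscles (>= 3).
#' @param seed Integer seed; output is deterministic given the seed.
#' @param jitter Standard deviation of Gaussian jitter applied to the
#'   axis-aligned pairs before renormalization.
#' @return `n_muscles x 3` matrix with unit-norm rows whose column space has
#'   rank 3 (all DOFs observable).
#' @export
make_synergy_matrix <- function(n_muscles = 8L, seed = 1L, jitter = 0.15) {
  if (n_muscles < 3L) {
    stopf("need at least 3 muscles for 3 observable DOFs (got %d)", n_muscles)
  }
  axes <- rbind(diag(3), -diag(3))  # +p, +w, +a, -p, -w, -a
  W <- with_seed(seed, {
    base <- axes[((seq_len(n_muscles) - 1L) %% 6L) + 1L, , drop = FALSE]
    extra <- matrix(rnorm(n_muscles * 3, sd = jitter), n_muscles, 3)
    base + extra
  })
  W <- W / sqrt(rowSums(W^2))
  if (qr(W)$rank < 3L) {
    stopf("degenerate synergy draw: intent space not fully observable")
  }
  dimnames(W) <- list(paste0("m", seq_len(n_muscles)), DOF_NAMES)
  W
}

#' Virtual subject / signal generator configuration
#'
#' Describes the synthetic EMG source model: directionally tuned muscles
#' driving band-limited stochastic carriers, mixed into channels through a
#' crosstalk matrix, with additive sensor noise calibrated to a target
#' signal-to-noise ratio.
#'
#' @param n_muscles Number of muscles (default 8).
#' @param synergy `n_muscles x 3` tuning matrix with unit-norm rows; defaults
#'   to [make_synergy_matrix()] with the given seed.
#' @param baseline_activation Resting drive as a fraction in `[0, 1)`.
#' @param carrier_band Two-element passband in Hz, inside `(0, sample_rate/2)`.
#' @param sample_rate Sampling rate in Hz.
#' @param crosstalk `n_channels x n_muscles` non-negative mixing matrix with
#'   rows summing to 1; defaults to the identity (one channel per muscle).
#' @param target_snr_db Target channel SNR in dB (active RMS over quiet RMS).
#' @param noise_sd Optional fixed per-channel sensor-noise SD. When `NULL`
#'   (the default) the noise is calibrated per recording to hit
#'   `target_snr_db`; a fixed value is used for online windows so that
#'   training and closed-loop features share one amplitude scale.
#' @param seed Integer seed for all stochastic draws.
#' @return An object of class `virtual_subject_config`.
#' @export
virtual_subject_config <- function(n_muscles = 8L,
                                   synergy = NULL,
                                   baseline_activation = 0,
                                   carrier_band = c(15, 375),
                                   sample_rate = 2000,
                                   crosstalk = NULL,
                                   target_snr_db = 34,
                                   noise_sd = NULL,
                                   seed = 1L) {
  if (is.null(synergy)) synergy <- make_synergy_matrix(n_muscles, seed = seed)
  synergy <- as.matrix(synergy)
  if (nrow(synergy) != n_muscles || ncol(synergy) != 3L) {
    stopf("synergy must be %d x 3", n_muscles)
  }
  if (any(abs(sqrt(rowSums(synergy^2)) - 1) > 1e-8)) {
    stopf("synergy rows must have unit Euclidean norm")
  }
  if (baseline_activation < 0 || baseline_activation >= 1) {
    stopf("baseline_activation must be in [0, 1)")
  }
  if (length(carrier_band) != 2L || carrier_band[1] <= 0 ||
      carrier_band[2] <= carrier_band[1] || carrier_band[2] >= sample_rate / 2) {
    stopf("carrier_band must satisfy 0 < low < high < sample_rate/2")
  }
  if (is.null(crosstalk)) crosstalk <- diag(n_muscles)
  crosstalk <- as.matrix(crosstalk)
  if (ncol(crosstalk) != n_muscles) stopf("crosstalk must have %d columns", n_muscles)
  if (any(crosstalk < 0)) stopf("crosstalk entries must be >= 0")
  if (any(abs(rowSums(crosstalk) - 1) > 1e-8)) {
    stopf("each crosstalk row must sum to 1")
  }
  structure(
    list(n_muscles = as.integer(n_muscles), synergy = synergy,
         baseline_activation = baseline_activation,
         carrier_band = as.numeric(carrier_band),
         sample_rate = sample_rate, crosstalk = crosstalk,
         target_snr_db = target_snr_db, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "virtual_subject_config"
  )
}

# Band-limiting filter shared by generator and per-window synthesis.
carrier_filter <- function(cfg) {
  signal::butter(4, cfg$carrier_band / (cfg$sample_rate / 2), type = "pass")
}

# White Gaussian noise -> zero-phase band-limited carrier, unit RMS.
make_carrier <- function(n, filt) {
  x <- signal::filtfilt(filt, rnorm(n))
  x / sqrt(mean(x^2))
}

# Rectified-linear muscle drive: baseline + max(0, w . intent).
muscle_activation <- function(intent_values, cfg) {
  drive <- pmax(intent_values %*% t(cfg$synergy), 0)
  drive + cfg$baseline_activation
}

#' Simulate multichannel EMG from an intent trajectory
#'
#' Each muscle's source is an activation envelope (rectified-linear tuning of
#' the intent plus a baseline, linearly interpolated to the sample rate)
#' multiplying a unit-RMS band-limited Gaussian carrier. Channels are the
#' crosstalk mixture of the sources plus white sensor noise, scaled so the
#' realized channel SNR (RMS over active segments / RMS over zero-intent
#' segments, in dB) matches `cfg$target_snr_db`.
#'
#' @param intent An [intent_series()]; values in `[-1, 1]^3`.
#' @param cfg A [virtual_subject_config()].
#' @return An [emg_recording()] with attributes `noise_sd` (per-channel
#'   calibrated noise SD) and `active_mask` (logical per-sample activity
#'   indicator derived from the commanded intent).
#' @export
simulate_emg <- function(intent, cfg) {
  stopifnot(inherits(intent, "intent_series"),
            inherits(cfg, "virtual_subject_config"))
  fs <- cfg$sample_rate
  duration <- max(intent$times)
  t_grid <- seq(1 / fs, duration, by = 1 / fs)
  n <- length(t_grid)

  act_frames <- muscle_activation(intent$values, cfg)
  env <- vapply(seq_len(cfg$n_muscles), function(m) {
    approx(intent$times, act_frames[, m], xout = t_grid, rule = 2)$y
  }, numeric(n))                                     # n x n_muscles

  intent_mag <- approx(intent$times, rowSums(abs(intent$values)),
                       xout = t_grid, rule = 2)$y
  active <- intent_mag > 0.01
  quiet <- intent_mag < 1e-9

  filt <- carrier_filter(cfg)
  out <- with_seed(cfg$seed, {
    sources <- vapply(seq_len(cfg$n_muscles), function(m) {
      env[, m] * make_carrier(n, filt)
    }, numeric(n))                                   # n x n_muscles
    clean <- cfg$crosstalk %*% t(sources)            # n_channels x n
    n_ch <- nrow(clean)
    sigma <- cfg$noise_sd
    if (is.null(sigma)) {
      if (any(active)) {
        r <- 10^(cfg$target_snr_db / 20)
        if (r <= 1) {
          stopf("target_snr_db = %g dB is unreachable (needs negative noise variance)",
                cfg$target_snr_db)
        }
        s2 <- rowMeans(clean[, active, drop = FALSE]^2)
        sigma <- sqrt(s2 / (r^2 - 1))
      } else {
        sigma <- rep(1, n_ch)  # no activity: nominal unit noise
      }
    }
    sigma <- rep_len(sigma, n_ch)
    noise <- matrix(rnorm(n_ch * n), n_ch, n) * sigma
    list(samples = clean + noise, sigma = sigma)
  })

  rec <- emg_recording(out$samples, fs, condition = "other")
  attr(rec, "noise_sd") <- out$sigma
  attr(rec, "active_mask") <- active
  attr(rec, "quiet_mask") <- quiet
  attr(rec, "seed") <- cfg$seed
  rec
}

#' Realized signal-to-noise ratio of a simulated recording
#'
#' The generator's own SNR oracle: per-channel RMS over samples where the
#' commanded intent was active, divided by RMS over zero-intent samples,
#' in dB.
#'
#' @param recording An [emg_recording()] produced by [simulate_emg()].
#' @return Numeric vector of per-channel SNR in dB.
#' @export
realized_snr <- function(recording) {
  active <- attr(recording, "active_mask")
  quiet <- attr(recording, "quiet_mask")
  if (is.null(active) || is.null(quiet)) {
    stopf("realized_snr needs a recording from simulate_emg (activity masks missing)")
  }
  x <- recording$samples
  rms <- function(v) sqrt(mean(v^2))
  a <- apply(x[, active, drop = FALSE], 1, rms)
  q <- apply(x[, quiet, drop = FALSE], 1, rms)
  20 * log10(a / q)
}

#' Apply a recording-condition preset to a generator configuration
#'
#' Intramuscular electrodes are modeled as nearly channel-selective
#' (off-diagonal mixing mass at most 2% per channel) with a high-SNR preset;
#' surface electrodes as a circumferential ring whose channels each blend at
#' least three neighboring muscles, with a lower SNR preset. The input
#' configuration is not modified.
#'
#' @param cfg A [virtual_subject_config()] with square crosstalk
#'   (one channel per muscle).
#' @param condition `"intramuscular"` or `"surface"`.
#' @param snr_db SNR preset override; defaults to 34 dB (intramuscular) or
#'   25 dB (surface).
#' @return A new `virtual_subject_config`.
#' @export
apply_recording_condition <- function(cfg, condition = c("intramuscular", "surface"),
                                      snr_db = NULL) {
  condition <- match.arg(condition)
  m <- cfg$n_muscles
  idx <- seq_len(m)
  circ <- function(offset) ((idx - 1L + offset) %% m) + 1L
  X <- matrix(0, m, m)
  if (condition == "intramuscular") {
    # 1% total off-diagonal leakage to the two circular neighbors
    X[cbind(idx, idx)] <- 0.99
    X[cbind(idx, circ(1L))] <- X[cbind(idx, circ(1L))] + 0.005
    X[cbind(idx, circ(-1L))] <- X[cbind(idx, circ(-1L))] + 0.005
    if (is.null(snr_db)) snr_db <- 34
  } else {
    # spatially smeared ring: each channel mixes 5 neighboring muscles
    w <- c(0.4, 0.2, 0.2, 0.1, 0.1)
    for (j in seq_along(c(0L, 1L, -1L, 2L, -2L))) {
      off <- c(0L, 1L, -1L, 2L, -2L)[j]
      X[cbind(idx, circ(off))] <- X[cbind(idx, circ(off))] + w[j]
    }
    if (is.null(snr_db)) snr_db <- 25
  }
  out <- cfg
  out$crosstalk <- X
  out$target_snr_db <- snr_db
  out
}

#' Virtual subject control policy
#'
#' Proportional-with-saturation stand-in for the human user closing the
#' loop: intent is the ROM-normalized position error scaled by a gain,
#' clipped to `[-1, 1]`, with Gaussian intent noise and a reaction delay.
#'
#' @param gain Per-DOF proportional gain (intent units per unit normalized
#'   error); recycled to length 3.
#' @param reaction_delay Seconds between a change in the hand/target state
#'   and the subject reacting to it (default 0.2 s).
#' @param intent_noise_sd SD of additive intent noise (default 0.05).
#' @return An object of class `subject_policy`.
#' @export
subject_policy <- function(gain = 2, reaction_delay = 0.2, intent_noise_sd = 0.05) {
  if (reaction_delay < 0) stopf("reaction_delay must be >= 0")
  if (intent_noise_sd < 0) stopf("intent_noise_sd must be >= 0")
  structure(
    list(gain = rep_len(gain, 3L), saturation = 1,
         reaction_delay = reaction_delay, intent_noise_sd = intent_noise_sd),
    class = "subject_policy"
  )
}

#' One intent sample from the virtual subject
#'
#' @param hand,target [hand_state()] vectors within ROM.
#' @param policy A [subject_policy()].
#' @param noise Logical: add intent noise (draws from the current RNG
#'   stream)? Default `TRUE`.
#' @return Intent 3-vector in `[-1, 1]`.
#' @export
virtual_subject_intent <- function(hand, target, policy, noise = TRUE) {
  err <- (as.numeric(target) - as.numeric(hand)) / rom_span()
  intent <- clip(policy$gain * err, -1, 1)
  if (noise && policy$intent_noise_sd > 0) {
    intent <- intent + rnorm(3, sd = policy$intent_noise_sd)
  }
  unname(clip(intent, -1, 1))
}

#' Simulate a single-muscle cyclic contraction with known ground truth
#'
#' Burst train used to validate the SNR estimator: a square on/off envelope
#' multiplying a band-limited carrier, plus white noise of known RMS. The
#' clean burst amplitude is set so that the total in-burst RMS over the
#' noise RMS equals the requested SNR exactly.
#'
#' @param n_cycles Number of on/off cycles (>= 2).
#' @param on_s,off_s Burst and silence durations in seconds (> 0).
#' @param snr_db Ground-truth SNR in dB (in-burst RMS over noise RMS).
#' @param cfg A [virtual_subject_config()] supplying sample rate and band
#'   (crosstalk/synergy unused); defaults to a 1-muscle config.
#' @param seed Integer seed.
#' @return List of class `cyclic_contraction` with elements `recording`
#'   (1-channel [emg_recording()]), `noise_rms`, `burst_rms`, `duty_cycle`,
#'   `snr_db` and `burst_mask`.
#' @export
simulate_cyclic_contraction <- function(n_cycles = 10L, on_s = 2, off_s = 1,
                                        snr_db = 20,
                                        cfg = virtual_subject_config(n_muscles = 3L),
                                        seed = 1L) {
  if (n_cycles < 2L) stopf("need at least 2 cycles")
  if (on_s <= 0 || off_s <= 0) stopf("on_s and off_s must be > 0")
  fs <- cfg$sample_rate
  period <- on_s + off_s
  t_total <- n_cycles * period
  n <- round(t_total * fs)
  t_grid <- (seq_len(n) - 1L) / fs
  # each cycle: off_s of silence then on_s of burst
  in_burst <- (t_grid %% period) >= off_s

  sigma <- 1
  r <- 10^(snr_db / 20)
  if (r <= 1) stopf("snr_db must be positive")
  a <- sigma * sqrt(r^2 - 1)      # clean burst RMS so total burst RMS = sigma * r

  filt <- carrier_filter(cfg)
  x <- with_seed(seed, {
    carrier <- make_carrier(n, filt)
    clean <- ifelse(in_burst, a, 0) * carrier
    clean + sigma * rnorm(n)
  })

  rec <- emg_recording(matrix(x, 1, n), fs, channel_labels = "m1")
  structure(
    list(recording = rec,
         noise_rms = sigma,
         burst_rms = sigma * r,
         duty_cycle = on_s / period,
         snr_db = snr_db,
         burst_mask = in_burst),
    class = "cyclic_contraction"
  )
}
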