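test_that("synergy matrices are unit-norm, rank-3 and deterministic", {
  W <- make_synergy_matrix(8, seed = 1)
  expect_equal(dim(W), c(8L, 3L))
  expect_equal(sqrt(rowSums(W^2)), rep(1, 8), ignore_attr = TRUE)
  # independent SVD oracle for the rank
  expect_equal(sum(svd(W)$d > 1e-10), 3L)
  expect_identical(W, make_synergy_matrix(8, seed = 1))
  expect_false(identical(W, make_synergy_matrix(8, seed = 2)))

  # 3-muscle identity-like case: rows close to the DOF axes
  W3 <- make_synergy_matrix(3, seed = 5, jitter = 0.01)
  expect_true(all(abs(diag(W3)) > 0.99))
  expect_error(make_synergy_matrix(2), "at least 3")
})

test_that("simulated EMG hits the target SNR and is seed-reproducible", {
  sched <- build_cue_schedule(repetitions = 1, seed = 3)
  intent <- training_intent(sched)
  for (s in c(3L, 11L)) {
    cfg <- apply_recording_condition(virtual_subject_config(seed = s),
                                     "intramuscular")
    rec <- simulate_emg(intent, cfg)
    expect_true(all(abs(realized_snr(rec) - 34) < 1.5))
  }
  cfg <- apply_recording_condition(virtual_subject_config(seed = 3), "surface")
  expect_true(all(abs(realized_snr(simulate_emg(intent, cfg)) - 25) < 1.5))

  rec1 <- simulate_emg(intent, cfg)
  rec2 <- simulate_emg(intent, cfg)
  expect_identical(rec1$samples, rec2$samples)
})

test_that("zero intent with zero baseline yields uncorrelated pure noise", {
  times <- seq(0.05, 5, by = 0.05)
  intent <- intent_series(times, matrix(0, length(times), 3))
  cfg <- virtual_subject_config(seed = 8, baseline_activation = 0)
  rec <- simulate_emg(intent, cfg)
  # activity/noise ratio ~ 0 dB: all-quiet signal has uniform RMS
  x <- rec$samples
  half <- ncol(x) %/% 2
  r <- sqrt(mean(x[, 1:half]^2)) / sqrt(mean(x[, (half + 1):ncol(x)]^2))
  expect_lt(abs(20 * log10(r)), 0.5)
  # channels uncorrelated with any muscle envelope (flat envelope): check
  # inter-channel correlations are near zero under identity crosstalk
  ct <- crosstalk_matrix(rec)
  expect_lt(max(abs(ct[upper.tri(ct)])), 0.1)
})

test_that("a muscle tuned to the commanded direction dominates its channel", {
  # only muscle 1 is tuned to +pronation; the rest are orthogonal or opposed
  s2 <- 1 / sqrt(2)
  syn <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(-1, 0, 0),
               c(0, -1, 0), c(0, 0, -1), c(0, s2, s2), c(0, -s2, s2))
  times <- seq(0.05, 4, by = 0.05)
  vals <- matrix(rep(c(1, 0, 0), each = length(times)), ncol = 3)
  cfg <- virtual_subject_config(synergy = syn, target_snr_db = 30, seed = 2)
  rec <- simulate_emg(intent_series(times, vals), cfg)
  rms <- sqrt(rowMeans(rec$samples^2))
  # muscle 1 is tuned exactly to +pronation; its channel must dominate
  expect_equal(which.max(rms), 1L, ignore_attr = TRUE)
  expect_true(all(rms[1] > rms[-1]))
})

test_that("recording-condition presets satisfy their mixing contracts", {
  cfg <- virtual_subject_config(seed = 1)
  im <- apply_recording_condition(cfg, "intramuscular")
  offdiag_mass <- rowSums(im$crosstalk) - diag(im$crosstalk)
  expect_true(all(offdiag_mass <= 0.02 + 1e-12))
  expect_equal(im$target_snr_db, 34)

  sf <- apply_recording_condition(cfg, "surface")
  expect_true(all(rowSums(sf$crosstalk > 0.05) >= 3))
  expect_equal(sf$target_snr_db, 25)
  # input unchanged
  expect_identical(cfg$crosstalk, diag(8))
  expect_error(apply_recording_condition(cfg, "epidural"))
})

test_that("surface recordings show more inter-channel correlation than intramuscular", {
  sched <- build_cue_schedule(repetitions = 1, seed = 2)
  intent <- training_intent(sched)
  for (s in c(2L, 9L, 17L)) {
    base <- virtual_subject_config(seed = s)
    im <- mean_offdiagonal(
      crosstalk_matrix(simulate_emg(intent, apply_recording_condition(base, "intramuscular"))),
      absolute = TRUE)
    sf <- mean_offdiagonal(
      crosstalk_matrix(simulate_emg(intent, apply_recording_condition(base, "surface"))),
      absolute = TRUE)
    expect_gt(sf, im)
  }
})

test_that("virtual subject intent follows the proportional-saturation law", {
  quiet_policy <- subject_policy(gain = 2, intent_noise_sd = 0)
  h <- neutral_hand()
  expect_equal(virtual_subject_intent(h, h, quiet_policy), c(0, 0, 0))
  # gain 2, normalized error 0.25 -> 0.5 (pronation: 0.25 * 180 = 45 deg)
  tgt <- hand_state(pronation = 135, wrist = 5, aperture = 50)
  expect_equal(virtual_subject_intent(h, tgt, quiet_policy), c(0.5, 0, 0))
  # extreme-to-extreme with large gain saturates at +1
  lo <- hand_state(0, -60, 0); hi <- hand_state(180, 70, 100)
  expect_equal(virtual_subject_intent(lo, hi, subject_policy(gain = 50, intent_noise_sd = 0)),
               c(1, 1, 1))
  # noise is clipped back into [-1, 1]
  set.seed(1)
  noisy <- replicate(50, virtual_subject_intent(lo, hi, subject_policy(gain = 50)))
  expect_true(all(noisy >= -1 & noisy <= 1))
})

test_that("cyclic contractions carry correct ground truth", {
  cc <- simulate_cyclic_contraction(n_cycles = 10, on_s = 2, off_s = 1,
                                    snr_db = 20, seed = 4)
  expect_equal(cc$duty_cycle, 2 / 3)
  expect_equal(ncol(cc$recording$samples) / cc$recording$sample_rate, 30)
  expect_equal(cc$burst_rms / cc$noise_rms, 10)   # 20 dB
  expect_equal(mean(cc$burst_mask), 2 / 3, tolerance = 1e-3)

  sym <- simulate_cyclic_contraction(n_cycles = 3, on_s = 1.5, off_s = 1.5,
                                     snr_db = 15, seed = 1)
  expect_equal(sym$duty_cycle, 0.5)
  expect_error(simulate_cyclic_contraction(n_cycles = 1), "2 cycles")
})
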