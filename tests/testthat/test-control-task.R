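test_that("velocity shaping applies dead-zone, gain and speed cap", {
  cfg <- controller_config(threshold = 0.10, gain = 3,
                           max_speed = c(180, 130, 100))
  expect_equal(shape_velocity(c(0.05, 0, 0), cfg), c(0, 0, 0))
  # raw 0.2, gain 3 -> 0.6 of range before unit scaling
  expect_equal(shape_velocity(c(0.2, 0, 0), cfg), c(0.6 * 180, 0, 0))
  expect_equal(shape_velocity(c(1, 1, 1), cfg), c(180, 130, 100))   # capped
  expect_equal(shape_velocity(c(-1, -0.5, 0.09), cfg), c(-180, -130, 0))
  expect_error(controller_config(threshold = 1.2))
  expect_error(controller_config(gain = 0))
})

test_that("hand integration saturates at the range of motion", {
  h <- neutral_hand()
  expect_equal(as.numeric(integrate_hand(h, c(0, 0, 0), 0.05)), as.numeric(h))
  near <- hand_state(pronation = 179, wrist = 5, aperture = 50)
  out <- integrate_hand(near, c(90, 0, 0), 0.05)
  expect_equal(out[["pronation"]], 180)                  # clipped, no wrap
  w <- integrate_hand(hand_state(90, -10, 50), c(0, 40, 0), 0.05)
  expect_equal(w[["wrist"]], -8)
  expect_error(hand_state(pronation = 190))
})

test_that("session targets satisfy separation and bounds margins", {
  # independent post-hoc validator over the published constraints
  rom_lo <- c(0, -60, 0); rom_hi <- c(180, 70, 100)
  span <- rom_hi - rom_lo
  for (s in c(1L, 2L, 3L)) {
    targets <- generate_session_targets(session_spec(seed = s))
    expect_length(targets, 80L)
    expect_equal(attr(targets, "block"), rep(1:5, each = 16))
    M <- do.call(rbind, lapply(targets, as.numeric))
    for (d in 1:3) {
      expect_true(all(M[, d] >= rom_lo[d] + 0.15 * span[d] - 1e-9))
      expect_true(all(M[, d] <= rom_hi[d] - 0.15 * span[d] + 1e-9))
    }
    seps <- abs(diff(M)) / matrix(span, 79, 3, byrow = TRUE)
    expect_gte(min(seps), 0.30)
  }
  expect_identical(generate_session_targets(session_spec(seed = 4)),
                   generate_session_targets(session_spec(seed = 4)))
})

test_that("postural blocks alternate neutral and 10/90% extreme targets", {
  blk <- generate_postural_block(seed = 6)
  expect_length(blk, 16L)
  for (i in seq(1, 15, by = 2)) {                # 0-based even = neutral
    expect_equal(as.numeric(blk[[i]]), c(90, 5, 50))
  }
  for (i in seq(2, 16, by = 2)) {
    x <- as.numeric(blk[[i]])
    expect_true(x[1] %in% c(18, 162))            # 10% / 90% of [0, 180]
    expect_true(x[2] %in% c(-47, 57))            # 10% / 90% of [-60, 70]
    expect_true(x[3] %in% c(10, 90))
  }
})

test_that("an immobile controller fails at exactly 30 s", {
  # scripted decoder pinned below the dead-zone: the hand never moves
  still <- function(intent) c(0.05, 0.05, 0.05)
  tr <- run_trial(still, subject_policy(intent_noise_sd = 0), NULL,
                  hand_state(150, 50, 85), seed = 1)
  expect_false(tr$success)
  expect_identical(tr$trial_time_s, 30)
  expect_true(attr(trial_time(tr), "failed"))
  expect_true(all(tr$trajectory == tr$trajectory[rep(1, nrow(tr$trajectory)), ]))
})

test_that("the oracle subject succeeds quickly with a direct path", {
  tgt <- hand_state(160, 60, 90)
  tr <- run_trial(NULL, subject_policy(intent_noise_sd = 0, reaction_delay = 0),
                  NULL, tgt, seed = 2)
  expect_true(tr$success)
  expect_gte(tr$trial_time_s, 1.05)              # dwell + at least one move frame
  expect_lt(tr$trial_time_s, 30)
  expect_gt(tr$path_efficiency, 90)              # near-direct approach
  # trajectory never leaves the ROM
  expect_true(all(t(tr$trajectory) >= c(0, -60, 0) - 1e-9))
  expect_true(all(t(tr$trajectory) <= c(180, 70, 100) + 1e-9))
})

test_that("dwell must be 20 consecutive in-tolerance frames", {
  # decoder that dives into tolerance, bounces out once, then settles:
  # driven by a mutable frame counter
  env <- new.env(); env$f <- 0L
  tgt <- hand_state(90, 5, 80)                   # aperture-only task
  bouncer <- function(intent) {
    env$f <- env$f + 1L
    f <- env$f
    a <- if (f <= 16) 1 else if (f <= 19) 0 else if (f <= 24) -1 else
      if (f <= 29) 1 else 0
    c(0, 0, a)
  }
  tr <- run_trial(bouncer, subject_policy(intent_noise_sd = 0), NULL, tgt,
                  start = hand_state(90, 5, 0), seed = 3)
  expect_true(tr$success)
  aper <- tr$trajectory[, "aperture"]
  in_tol <- abs(aper - 80) <= 15
  # the final 20 trajectory rows are in tolerance and contiguous
  n <- length(aper)
  expect_true(all(in_tol[(n - 19):n]))
  # the excursion reset the dwell: success came well after the first 20
  # frames following first tolerance entry
  first_in <- which(in_tol)[1]
  expect_gt(n, first_in + 20)
  expect_equal(tr$dwell_start, n - 19)
})

test_that("sessions carry hand state within blocks and summarize trials", {
  tr <- small_trained()
  s <- run_session(session_spec(n_targets = 4, block_size = 2, seed = 5),
                   tr$model, subject_policy(), tr$generator_cfg,
                   controller_config(), seed = 5)
  expect_length(s$trials, 4L)
  expect_equal(s$block, rep(1:2, each = 2))
  # within a block the next trial starts at the previous final state
  end1 <- s$trials[[1]]$trajectory[nrow(s$trials[[1]]$trajectory), ]
  expect_equal(unname(s$trials[[2]]$trajectory[1, ]), unname(end1))
  # at a block boundary the hand resets to neutral
  expect_equal(unname(s$trials[[3]]$trajectory[1, ]), c(90, 5, 50))
  expect_s3_class(s$summary, "session_summary")

  # bitwise reproducibility of trial outcomes
  s2 <- run_session(session_spec(n_targets = 4, block_size = 2, seed = 5),
                    tr$model, subject_policy(), tr$generator_cfg,
                    controller_config(), seed = 5)
  expect_identical(s$trials[[4]]$trajectory, s2$trials[[4]]$trajectory)

  empty <- run_session(list(), tr$model, subject_policy(), tr$generator_cfg)
  expect_length(empty$trials, 0L)
  expect_null(empty$summary)
})
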