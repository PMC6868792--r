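test_that("cue schedule covers the posture cube the stated number of times", {
  sch <- build_cue_schedule(repetitions = 5, seed = 1)
  expect_equal(nrow(sch), 135L)
  codes <- paste(sch$pronation, sch$wrist, sch$aperture)
  expect_equal(length(unique(codes)), 27L)
  expect_true(all(table(codes) == 5L))
  expect_true(all(sch$pronation %in% -1:1))

  once <- build_cue_schedule(repetitions = 1, seed = 2)
  expect_equal(nrow(once), 27L)
  expect_equal(length(unique(paste(once$pronation, once$wrist, once$aperture))), 27L)

  # contiguous non-overlapping 5 s trials; deterministic order per seed
  expect_equal(diff(sch$start), rep(5, 134))
  expect_identical(sch, build_cue_schedule(repetitions = 5, seed = 1))
  expect_false(identical(build_cue_schedule(seed = 1)$pronation,
                         build_cue_schedule(seed = 2)$pronation))
  expect_error(build_cue_schedule(repetitions = 0))
})

test_that("active windows span Go plus 1.5 s of Rest, clipped at schedule end", {
  sch <- build_cue_schedule(repetitions = 1, seed = 1)
  w1 <- active_window(sch, 1)
  expect_equal(unname(w1), c(2.0, 5.5))           # 3.5 s interior window
  wi <- active_window(sch, 10)
  expect_equal(unname(diff(wi)), 3.5)
  wlast <- active_window(sch, 27)
  expect_equal(unname(wlast[2]), attr(sch, "duration"))   # clipped
  expect_equal(unname(diff(wlast)), 3.0)
})

test_that("assumed intent scales the cue code by normalized MAV effort", {
  sch <- build_cue_schedule(repetitions = 1, seed = 3)
  times <- seq(0.05, attr(sch, "duration"), by = 0.05)
  n <- length(times)

  # constant effort -> labels equal the codes inside windows
  f_const <- manual_feature_frame(times, matrix(1, n, 16))
  lab <- assumed_intent(f_const, sch)
  w <- active_window(sch, 4)
  inside <- times > w[1] & times <= w[2]
  code <- as.numeric(sch[4, c("pronation", "wrist", "aperture")])
  expect_equal(lab$values[which(inside)[1], ], code, ignore_attr = TRUE)
  # zero outside every active window
  in_any <- rep(FALSE, n)
  for (i in seq_len(nrow(sch))) {
    wi <- active_window(sch, i)
    in_any <- in_any | (times > wi[1] & times <= wi[2])
  }
  expect_true(all(lab$values[!in_any, ] == 0))

  # label/feature row counts always match
  expect_equal(nrow(lab$values), n)

  # sign patterns of the labels reproduce the full cue cube (the all-zero
  # pattern covers both the [0,0,0] cue and rest frames)
  signs <- unique(t(apply(lab$values, 1, sign)))
  expect_equal(nrow(signs), 27L)
})

test_that("time-varying effort is mean-one per window and clipped at 1", {
  # single synthetic trial: triangular MAV ramp 0 -> 2x mean inside the window
  sch <- build_cue_schedule(repetitions = 1, seed = 5)
  times <- seq(0.05, attr(sch, "duration"), by = 0.05)
  n <- length(times)
  m <- rep(1, n)
  # first trial whose cue is not the all-zero posture
  tr_i <- which(rowSums(abs(sch[, c("pronation", "wrist", "aperture")])) > 0)[1]
  w <- active_window(sch, tr_i)
  idx <- which(times > w[1] & times <= w[2])
  ramp <- seq(0, 2, length.out = length(idx))     # mean 1, peak 2
  m[idx] <- ramp
  f <- manual_feature_frame(times, matrix(m, n, 16))

  lab_unclipped <- assumed_intent(f, sch, clip_effort = FALSE)
  code <- as.numeric(sch[tr_i, c("pronation", "wrist", "aperture")])
  nz <- which(code != 0)[1]
  e_un <- lab_unclipped$values[idx, nz] / code[nz]
  expect_equal(mean(e_un), 1, tolerance = 1e-10)  # window-mean 1 by construction
  expect_equal(max(e_un), 2, tolerance = 1e-10)

  lab <- assumed_intent(f, sch)
  e_cl <- lab$values[idx, nz] / code[nz]
  expect_equal(max(e_cl), 1)
  expect_equal(e_cl, pmin(e_un, 1), tolerance = 1e-10)
  expect_true(all(abs(lab$values) <= 1))

  # per-trial-scalar mode: bare codes
  lab_s <- assumed_intent(f, sch, per_trial_scalar = TRUE)
  expect_equal(lab_s$values[idx[1], ], code, ignore_attr = TRUE)
})

test_that("overlapping windows are assigned to the earlier trial and zero-MAV warns", {
  sch <- build_cue_schedule(repetitions = 1, seed = 7)
  times <- seq(0.05, attr(sch, "duration"), by = 0.05)
  n <- length(times)
  f <- manual_feature_frame(times, matrix(1, n, 16))
  lab <- assumed_intent(f, sch)
  # frames in trial 1's spillover (rest + next prepare) carry trial 1's code
  w1 <- active_window(sch, 1)
  spill <- which(times > sch$start[2] & times <= w1[2])
  code1 <- as.numeric(sch[1, c("pronation", "wrist", "aperture")])
  expect_true(all(apply(lab$values[spill, , drop = FALSE], 1,
                        function(r) all(r == code1))))

  dead <- manual_feature_frame(times, matrix(0, n, 16))
  warns <- capture_warnings(lab0 <- assumed_intent(dead, sch))
  expect_true(any(grepl("zero mean MAV", warns)))
  expect_true(all(lab0$values == 0))
})
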