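# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Small trained decoder (one repetition of the cue protocol) reused by the
# decoder, control-task and pipeline tests.
small_trained <- function() {
  cached("small_trained", {
    cfg <- apply_recording_condition(virtual_subject_config(seed = 42L),
                                     "intramuscular")
    train_decoder(cfg, repetitions = 1L, seed = 42L)
  })
}

# Independent brute-force oracle for inverse-distance-weighted KNN:
# explicit loops and a full sort, sharing no code with the package path.
oracle_knn_predict <- function(X, targets, query, k, epsilon) {
  n <- nrow(X)
  d <- numeric(n)
  for (i in seq_len(n)) d[i] <- sqrt(sum((query - X[i, ])^2))
  ord <- order(d, seq_len(n))[seq_len(k)]
  w <- 1 / (d[ord] + epsilon)
  out <- c(0, 0, 0)
  for (j in seq_len(k)) out <- out + w[j] * targets[ord[j], ]
  pmin(pmax(out / sum(w), -1), 1)
}

# Bare feature_frame built directly from a values matrix (for label tests).
manual_feature_frame <- function(times, values) {
  structure(list(times = times, values = values, window_s = 0.2,
                 step_s = 0.05, channel_labels = NULL),
            class = "feature_frame")
}

random_model <- function(n, k, seed, epsilon = 1e-9) {
  set.seed(seed)
  X <- matrix(runif(n * 16), n, 16)
  Tgt <- matrix(runif(n * 3, -1, 1), n, 3)
  knn_decoder(X, Tgt, k = k, epsilon = epsilon)
}
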