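#' Fit the inverse-distance-weighted KNN velocity decoder
#'
#' A lazy regression from 16-dimensional EMG features to 3-DOF velocity
#' intent: the model stores the (max-normalized) training features and
#' their assumed-intent targets verbatim; prediction averages the targets
#' of the K nearest training rows, weighted by inverse Euclidean distance.
#'
#' @param features Training [extract_features()] `feature_frame` (raw; the
#'   per-dimension max normalization is fitted here and stored), or a bare
#'   numeric matrix of already-normalized features (then `scale` must be
#'   supplied or defaults to unit divisors).
#' @param intents Matching [intent_series()] (or `n x 3` matrix) of
#'   assumed-intent targets in `[-1, 1]`.
#' @param k Number of neighbors (default 100).
#' @param epsilon Distance regularizer added to every neighbor distance
#'   before inversion, so exact feature matches degrade gracefully
#'   (default 1e-9).
#' @param scale Optional pre-fitted [fit_normalization()] scale.
#' @param trial_id Optional integer vector grouping training frames into
#'   trials, enabling leave-one-trial-out in [loo_vaf()].
#' @return Object of class `knn_decoder` with elements `train` (normalized
#'   `n x p` feature matrix, per-dimension training max 1 when fitted from
#'   raw features), `targets` (`n x 3`), `k`, `epsilon`, `scale`, `trial_id`.
#' @export
knn_decoder <- function(features, intents, k = 100L, epsilon = 1e-9,
                        scale = NULL, trial_id = NULL) {
  if (inherits(features, "feature_frame")) {
    if (is.null(scale)) scale <- fit_normalization(features)
    X <- apply_normalization(features$values, scale)
  } else {
    X <- as.matrix(features)
    if (is.null(scale)) {
      scale <- structure(rep(1, ncol(X)), class = "feature_scale")
    }
  }
  Tgt <- if (inherits(intents, "intent_series")) intents$values else as.matrix(intents)
  if (nrow(X) != nrow(Tgt)) stopf("feature and target row counts differ")
  if (ncol(Tgt) != 3L) stopf("targets must have 3 columns")
  if (!all(is.finite(X)) || !all(is.finite(Tgt))) stopf("non-finite training values")
  if (nrow(X) < k) {
    stopf("insufficient training data: n = %d < k = %d", nrow(X), k)
  }
  if (epsilon <= 0) stopf("epsilon must be positive")
  if (!is.null(trial_id) && length(trial_id) != nrow(X)) {
    stopf("trial_id length must match training rows")
  }
  structure(
    list(train = X, targets = Tgt, k = as.integer(k), epsilon = epsilon,
         scale = scale, trial_id = trial_id),
    class = "knn_decoder"
  )
}

#' @export
print.knn_decoder <- function(x, ...) {
  cat(sprintf("<knn_decoder> %d training frames x %d features, k = %d, epsilon = %g\n",
              nrow(x$train), ncol(x$train), x$k, x$epsilon))
  invisible(x)
}

#' @export
summary.knn_decoder <- function(object, ...) {
  cat(sprintf("Inverse-distance-weighted KNN velocity decoder\n"))
  print(object)
  tr <- object$targets
  cat("Training target range per DOF:\n")
  print(apply(tr, 2, range))
  invisible(object)
}

# Squared Euclidean distances from each row of Q to each row of X.
# Returns an nrow(Q) x nrow(X) matrix; clamps tiny negatives from rounding.
cross_dist2 <- function(Q, X) {
  d2 <- outer(rowSums(Q^2), rowSums(X^2), "+") - 2 * tcrossprod(Q, X)
  d2[d2 < 0] <- 0
  d2
}

# Indices of the k smallest entries of d, ties broken by ascending index.
smallest_k <- function(d, k) {
  if (length(d) == k) return(seq_len(k))
  thr <- sort(d, partial = k)[k]
  idx <- which(d <= thr)
  if (length(idx) > k) idx <- idx[order(d[idx], idx)[seq_len(k)]]
  idx
}

# Weighted prediction for one query given distances to all candidates.
idw_predict_one <- function(d, targets, k, epsilon) {
  idx <- smallest_k(d, k)
  w <- 1 / (d[idx] + epsilon)
  clip(colSums(targets[idx, , drop = FALSE] * w) / sum(w), -1, 1)
}

#' Predict velocity intent from EMG features
#'
#' For each query the Euclidean distances to all training rows are computed,
#' the `k` smallest selected (ties broken by training-row index, ascending),
#' and the corresponding targets averaged with weights `1/(d + epsilon)`.
#' Outputs are clipped to `[-1, 1]` per component (a no-op for targets
#' already inside the cube; kept as a contract).
#'
#' @param object A [knn_decoder()].
#' @param newdata A `feature_frame`, a numeric matrix (`m x p`) or a single
#'   feature vector, on the raw feature scale unless `normalized = TRUE`.
#' @param normalized Set `TRUE` if `newdata` is already divided by the
#'   training scale.
#' @param ... Unused.
#' @return `m x 3` matrix of intent predictions (a 3-vector for a single
#'   query vector).
#' @export
predict.knn_decoder <- function(object, newdata, normalized = FALSE, ...) {
  single <- FALSE
  if (inherits(newdata, "feature_frame")) {
    Q <- newdata$values
  } else if (is.matrix(newdata)) {
    Q <- newdata
  } else {
    Q <- matrix(newdata, nrow = 1)
    single <- TRUE
  }
  if (ncol(Q) != ncol(object$train)) {
    stopf("query has %d features; model expects %d", ncol(Q), ncol(object$train))
  }
  if (!all(is.finite(Q))) stopf("non-finite query features")
  if (!normalized) Q <- apply_normalization(Q, object$scale)
  D <- sqrt(cross_dist2(Q, object$train))
  out <- t(apply(D, 1, idw_predict_one, targets = object$targets,
                 k = object$k, epsilon = object$epsilon))
  colnames(out) <- DOF_NAMES
  if (single) out[1, ] else out
}

#' Leave-one-out variance accounted for
#'
#' Offline decoding quality per DOF: each training frame is predicted with
#' itself (or its whole trial, with `by_trial = TRUE`) excluded from the
#' candidate set, and
#' `VAF_d = 100 * (1 - var(target_d - prediction_d) / var(target_d))`.
#'
#' @param model A [knn_decoder()].
#' @param by_trial Exclude the query's entire trial instead of just the
#'   identical frame (requires `trial_id` in the model).
#' @param block Number of query rows per distance block (memory knob).
#' @return Named numeric vector of per-DOF VAF percents (may be negative).
#' @export
loo_vaf <- function(model, by_trial = FALSE, block = 512L) {
  X <- model$train
  n <- nrow(X)
  if (n < model$k + 1L) stopf("leave-one-out needs n >= k + 1")
  if (by_trial && is.null(model$trial_id)) {
    stopf("by_trial = TRUE requires a model fitted with trial_id")
  }
  tv <- apply(model$targets, 2, var)
  if (any(tv == 0)) {
    stopf("zero target variance in DOF(s): %s",
          paste(DOF_NAMES[tv == 0], collapse = ", "))
  }
  pred <- matrix(0, n, 3)
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(start + block - 1L, n)
    D <- sqrt(cross_dist2(X[rows, , drop = FALSE], X))
    for (j in seq_along(rows)) {
      i <- rows[j]
      excl <- if (by_trial) which(model$trial_id == model$trial_id[i]) else i
      d <- D[j, ]
      d[excl] <- Inf
      pred[i, ] <- idw_predict_one(d, model$targets, model$k, model$epsilon)
    }
  }
  vaf <- 100 * (1 - apply(model$targets - pred, 2, var) / tv)
  names(vaf) <- DOF_NAMES
  vaf
}
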