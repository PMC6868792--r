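#' Channel crosstalk matrix
#'
#' Pairwise zero-lag Pearson correlations of the raw band-limited signals
#' over the full recording; the correlation-matrix form of a crosstalk heat
#' map (unit diagonal, symmetric).
#'
#' @param recording An [emg_recording()] with >= 2 channels.
#' @return `n x n` correlation matrix of class `crosstalk_matrix`.
#' @export
crosstalk_matrix <- function(recording) {
  x <- recording$samples
  if (nrow(x) < 2L || ncol(x) < 2L) stopf("need >= 2 channels and >= 2 samples")
  v <- apply(x, 1, var)
  if (any(v == 0)) {
    stopf("zero-variance channel(s): %s",
          paste(recording$channel_labels[v == 0], collapse = ", "))
  }
  m <- cor(t(x))
  structure(m, class = c("crosstalk_matrix", "matrix"))
}

#' Mean off-diagonal crosstalk
#'
#' Mean of the strictly off-diagonal correlations, each unordered channel
#' pair counted once.
#'
#' @param m A [crosstalk_matrix()] (or any square correlation matrix).
#' @param absolute Average absolute values instead of signed (default
#'   `FALSE`; both views are informative since signed means can hide
#'   magnitude).
#' @return Scalar mean correlation.
#' @export
mean_offdiagonal <- function(m, absolute = FALSE) {
  m <- unclass(m)
  if (nrow(m) < 2L) stopf("need >= 2 channels")
  vals <- m[upper.tri(m)]
  if (absolute) vals <- abs(vals)
  mean(vals)
}

#' Box's M test for equality of two covariance matrices
#'
#' Classical Box's M with the chi-square approximation (default) or the
#' F approximation. Used to compare channel covariance structure between
#' recording conditions.
#'
#' @param sample_a,sample_b Numeric matrices, observations in rows, the
#'   same `p` variables in columns; each needs more than `p` observations
#'   and a non-singular covariance.
#' @param method `"chisq"` (default) or `"F"`.
#' @return List with `statistic` (M), `approx_statistic`, `df`, `p_value`
#'   and `method`.
#' @export
boxs_m_test <- function(sample_a, sample_b, method = c("chisq", "F")) {
  method <- match.arg(method)
  samples <- list(as.matrix(sample_a), as.matrix(sample_b))
  p <- ncol(samples[[1]])
  if (ncol(samples[[2]]) != p) stopf("samples must share the same variables")
  n <- vapply(samples, nrow, integer(1))
  if (any(n < p + 1L)) stopf("each sample needs at least p + 1 observations")
  g <- 2L
  covs <- lapply(samples, stats::cov)
  logdets <- vapply(covs, function(S) {
    d <- determinant(S, logarithm = TRUE)
    if (d$sign <= 0) stopf("singular covariance matrix")
    as.numeric(d$modulus)
  }, numeric(1))
  nu <- n - 1L
  Sp <- Reduce(`+`, Map(`*`, covs, nu)) / sum(nu)
  dp <- determinant(Sp, logarithm = TRUE)
  if (dp$sign <= 0) stopf("singular pooled covariance matrix")
  M <- sum(nu) * as.numeric(dp$modulus) - sum(nu * logdets)
  c1 <- (2 * p^2 + 3 * p - 1) / (6 * (p + 1) * (g - 1)) *
    (sum(1 / nu) - 1 / sum(nu))
  df1 <- p * (p + 1) * (g - 1) / 2
  if (method == "chisq") {
    stat <- M * (1 - c1)
    pval <- pchisq(stat, df1, lower.tail = FALSE)
    return(list(statistic = M, approx_statistic = stat, df = df1,
                p_value = pval, method = "chisq"))
  }
  c2 <- (p - 1) * (p + 2) / (6 * (g - 1)) * (sum(1 / nu^2) - 1 / sum(nu)^2)
  df2 <- (df1 + 2) / abs(c2 - c1^2)
  b <- df1 / (1 - c1 - df1 / df2)
  Fstat <- M / b
  pval <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  list(statistic = M, approx_statistic = Fstat, df = c(df1, df2),
       p_value = pval, method = "F")
}

# Otsu's between-class-variance threshold on a numeric vector.
otsu_threshold <- function(x, nbins = 256L) {
  h <- hist(x, breaks = nbins, plot = FALSE)
  counts <- as.numeric(h$counts)
  mids <- h$mids
  w <- cumsum(counts)
  total <- w[length(w)]
  mu <- cumsum(counts * mids)
  mu_t <- mu[length(mu)]
  w0 <- w[-length(w)]
  w1 <- total - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, length(w0))
  bcv[valid] <- (mu_t * w0[valid] - total * mu[-length(mu)][valid])^2 /
    (w0[valid] * w1[valid])
  mids[which.max(bcv)]
}

#' Estimate SNR, background noise and duty cycle from cyclic contractions
#'
#' Per channel: the activity envelope is the 2 Hz low-passed rectified
#' signal; the background-noise RMS is taken from the lower mode of the
#' envelope amplitude histogram (Otsu split of the log-envelope, RMS of the
#' raw signal over the lower class; the log domain keeps the split robust
#' when activity dominates the recording). Bursts are detected where the envelope exceeds
#' `threshold_c` times the noise RMS; the working mask is then refined to
#' envelope > midpoint of the quiet and burst envelope levels, which
#' centers the (zero-phase-smoothed) transitions on the true burst edges
#' so the duty cycle is unbiased regardless of burst amplitude. Finally
#' `SNR_db = 20 log10(RMS over active samples / RMS over quiet samples)`
#' and duty cycle = active fraction. The RMS values exclude a guard band
#' around each mask transition (default 0.25 s, the envelope filter's
#' settle time), since envelope smoothing blurs the exact burst edges and a
#' handful of mislabeled high-amplitude samples would otherwise dominate
#' the quiet RMS. This operationalization is this package's own
#' definition, validated against the generator's ground truth.
#'
#' @param recording An [emg_recording()] containing at least 2 activity
#'   bursts per channel.
#' @param lowpass_hz Envelope low-pass cutoff (default 2 Hz).
#' @param threshold_c Activity threshold in noise-RMS-level units
#'   (default 3).
#' @param guard_s Transition guard band excluded from the RMS estimates,
#'   in seconds (default 0.25).
#' @return Object of class `snr_report`: data frame with one row per
#'   channel (`channel`, `noise_rms`, `snr_db`, `duty_cycle`, `n_bursts`).
#' @export
estimate_snr <- function(recording, lowpass_hz = 2, threshold_c = 3,
                         guard_s = 0.25) {
  fs <- recording$sample_rate
  guard_n <- as.integer(round(guard_s * fs))
  lp <- signal::butter(2, lowpass_hz / (fs / 2), type = "low")
  rows <- lapply(seq_len(nrow(recording$samples)), function(ch) {
    x <- recording$samples[ch, ]
    env <- signal::filtfilt(lp, abs(x))
    env <- pmax(env, max(env) * 1e-6)   # filtfilt undershoot guard
    split <- 10^otsu_threshold(log10(env))
    low <- env <= split
    if (!any(low)) stopf("channel %d: no sub-threshold segment found", ch)
    noise_rms <- sqrt(mean(x[low]^2))
    detect <- env > threshold_c * noise_rms
    bursts <- sum(diff(c(FALSE, detect)) == 1L)
    if (bursts < 2L || all(detect)) {
      stopf("channel %d: fewer than 2 activity bursts detected", ch)
    }
    # midpoint-level mask: transitions of the zero-phase envelope cross the
    # midpoint at the true burst edges, so duty is amplitude-independent
    mid <- (mean(env[detect]) + mean(env[!detect])) / 2
    mask <- env > mid
    bursts <- sum(diff(c(FALSE, mask)) == 1L)
    edges <- which(diff(mask) != 0L)
    near_edge <- logical(length(mask))
    for (e in edges) {
      near_edge[max(1L, e - guard_n):min(length(mask), e + guard_n)] <- TRUE
    }
    core_active <- mask & !near_edge
    core_quiet <- !mask & !near_edge
    if (!any(core_active) || !any(core_quiet)) {
      stopf("channel %d: bursts too short for the guard band", ch)
    }
    rms_active <- sqrt(mean(x[core_active]^2))
    rms_quiet <- sqrt(mean(x[core_quiet]^2))
    data.frame(channel = recording$channel_labels[ch],
               noise_rms = noise_rms,
               snr_db = 20 * log10(rms_active / rms_quiet),
               duty_cycle = mean(mask),
               n_bursts = bursts)
  })
  structure(do.call(rbind, rows), class = c("snr_report", "data.frame"))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Thin wrapper around [stats::wilcox.test()] with the tie-corrected normal
#' approximation, returning the statistic and p-value as a pair.
#'
#' @param a,b Non-empty numeric vectors.
#' @return List with `statistic` (rank-sum W) and `p_value`.
#' @export
ranksum_test <- function(a, b) {
  if (!length(a) || !length(b)) stopf("both samples must be non-empty")
  res <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = FALSE))
  list(statistic = unname(res$statistic), p_value = res$p.value)
}
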