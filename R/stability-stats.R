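#' Fit the controller-stability regression
#'
#' Trial-level ordinary least squares of a posture-matching metric on a
#' controller indicator and controller-specific week slopes:
#' `y = Intercept + C_f * [controller == knn] + C_w0 * week * [intact] +
#' C_w1 * week * [knn]`. There is no common week main effect; each
#' controller gets its own time slope (the interaction-only structure
#' selected by [compare_models_anova()]). For trial-time responses a
#' reciprocal transform (`1/y`) is available to remedy non-normal errors.
#'
#' @param table Data frame with columns `controller` (factor/character with
#'   levels `intact` and `knn`), `week` (numeric, >= 2 distinct values) and
#'   the response column.
#' @param response `"path_efficiency"` or `"trial_time"` (a column of
#'   `table`).
#' @param transform `"none"` or `"reciprocal"`.
#' @return Object of class `stability_regression`: list with `coefficients`
#'   data frame (term, estimate, std_error, p_value), `r_squared`,
#'   `adj_r_squared`, `transform`, `response` and the underlying `lm` fit.
#' @export
fit_stability_regression <- function(table,
                                     response = c("path_efficiency", "trial_time"),
                                     transform = c("none", "reciprocal")) {
  response <- match.arg(response)
  transform <- match.arg(transform)
  if (!all(c("controller", "week", response) %in% names(table))) {
    stopf("table must have columns controller, week and %s", response)
  }
  ctrl <- as.character(table$controller)
  if (!all(c("intact", "knn") %in% unique(ctrl))) {
    stopf("both controller levels (intact, knn) must be present")
  }
  if (length(unique(table$week)) < 2L) stopf("need >= 2 distinct weeks")
  y <- table[[response]]
  if (transform == "reciprocal") {
    if (any(y == 0)) stopf("reciprocal transform undefined at y = 0")
    y <- 1 / y
  }
  knn <- as.numeric(ctrl == "knn")
  dat <- data.frame(y = y, knn = knn,
                    week_intact = table$week * (1 - knn),
                    week_knn = table$week * knn)
  fit <- lm(y ~ knn + week_intact + week_knn, data = dat)
  if (fit$rank < 4L) stopf("rank-deficient design (collinear controller/week structure)")
  sm <- summary(fit)
  co <- sm$coefficients
  coefs <- data.frame(
    term = c("Intercept", "C_f", "C_w0", "C_w1"),
    estimate = unname(co[, "Estimate"]),
    std_error = unname(co[, "Std. Error"]),
    p_value = unname(co[, "Pr(>|t|)"])
  )
  structure(
    list(coefficients = coefs, r_squared = sm$r.squared,
         adj_r_squared = sm$adj.r.squared, transform = transform,
         response = response, fit = fit),
    class = "stability_regression"
  )
}

#' @export
print.stability_regression <- function(x, ...) {
  resp <- if (x$transform == "reciprocal") paste0("1/", x$response) else x$response
  cat(sprintf("Stability regression: %s = Intercept + C_f*Controller + C_w0/w1*Week\n", resp))
  print(x$coefficients, row.names = FALSE, digits = 4)
  cat(sprintf("Multiple R-squared: %.3f, Adjusted R-squared: %.3f\n",
              x$r_squared, x$adj_r_squared))
  invisible(x)
}

#' Select the stability-regression structure by nested ANOVA
#'
#' F-test comparing the controller-only model against the model adding
#' controller-specific week slopes; the interaction model is retained when
#' `p < alpha`.
#'
#' @inheritParams fit_stability_regression
#' @param alpha Selection level (default 0.05).
#' @return List with `f_statistic`, `p_value`, `selected`
#'   (`"interaction"` or `"controller_only"`) and the two fits.
#' @export
compare_models_anova <- function(table,
                                 response = c("path_efficiency", "trial_time"),
                                 transform = c("none", "reciprocal"),
                                 alpha = 0.05) {
  response <- match.arg(response)
  transform <- match.arg(transform)
  ctrl <- as.character(table$controller)
  if (length(unique(table$week)) < 2L) stopf("need >= 2 distinct weeks")
  y <- table[[response]]
  if (transform == "reciprocal") y <- 1 / y
  knn <- as.numeric(ctrl == "knn")
  dat <- data.frame(y = y, knn = knn,
                    week_intact = table$week * (1 - knn),
                    week_knn = table$week * knn)
  m0 <- lm(y ~ knn, data = dat)
  m1 <- lm(y ~ knn + week_intact + week_knn, data = dat)
  a <- anova(m0, m1)
  f <- a$F[2]
  p <- a$`Pr(>F)`[2]
  list(f_statistic = f, p_value = p,
       selected = if (p < alpha) "interaction" else "controller_only",
       controller_only = m0, interaction = m1)
}

#' Kruskal-Wallis equality test across conditions
#'
#' Tie-corrected H statistic with the chi-square p-value, via
#' [stats::kruskal.test()]. The fully degenerate case (every observation
#' identical) returns `H = 0, p = 1`.
#'
#' @param groups List of >= 2 non-empty numeric vectors (e.g. a metric per
#'   arm-posture condition).
#' @return List with `statistic` (H), `df` and `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2L || any(!lengths(groups))) {
    stopf("need >= 2 non-empty groups")
  }
  all_vals <- unlist(groups)
  if (length(unique(all_vals)) == 1L) {
    return(list(statistic = 0, df = length(groups) - 1L, p_value = 1))
  }
  res <- kruskal.test(groups)
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value)
}

#' Simulate a stability table with known coefficients
#'
#' Generates per-trial metric observations from the stability-regression
#' model (controller offset plus controller-specific week slopes) with
#' Gaussian noise, for parameter-recovery and power studies. The default
#' session layout mirrors a study with intact-hand reference sessions at
#' two early weeks and tracked sessions across twelve weeks.
#'
#' @param coefficients Named or positional numeric 4-vector
#'   `(Intercept, C_f, C_w0, C_w1)`.
#' @param weeks_intact,weeks_knn Session weeks per controller.
#' @param trials_per_session Trials per session (default 60).
#' @param noise_sd Residual SD (default 10).
#' @param response Name for the generated metric column.
#' @param seed Integer seed.
#' @return Data frame with columns `controller`, `week` and the response.
#' @export
simulate_stability_table <- function(coefficients = c(66.9, -21.8, 3.4, 0.6),
                                     weeks_intact = c(0, 2),
                                     weeks_knn = c(0, 2, 4, 6, 8, 10, 12),
                                     trials_per_session = 60L,
                                     noise_sd = 10,
                                     response = "path_efficiency",
                                     seed = 1L) {
  sessions <- rbind(
    data.frame(controller = "intact", week = weeks_intact),
    data.frame(controller = "knn", week = weeks_knn)
  )
  tab <- sessions[rep(seq_len(nrow(sessions)), each = trials_per_session), ]
  knn <- as.numeric(tab$controller == "knn")
  mu <- coefficients[1] + coefficients[2] * knn +
    coefficients[3] * tab$week * (1 - knn) + coefficients[4] * tab$week * knn
  tab[[response]] <- mu + with_seed(seed, rnorm(nrow(tab), sd = noise_sd))
  rownames(tab) <- NULL
  tab
}
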