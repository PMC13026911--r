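#' Fit a qPCR standard curve
#'
#' Ordinary least-squares regression of Cq on log10 expected copies,
#' `Cq = k log10(N) + m`.  The slope `k` carries the PCR efficiency
#' (`E = 10^(-1/k) - 1`) and the intercept `m` is the Cq of a single
#' double-stranded target molecule.  Negative reactions carry no Cq and are
#' excluded before fitting; levels below a known lower limit of
#' quantification can be excluded with `exclude_below`, which is the
#' recommended alternative to weighted least squares for the
#' heteroscedastic low-copy levels.
#'
#' @param reactions Reaction tibble (`level_id`, `copies`, `replicate`,
#'   `cq`); `"ntc"` rows and negative reactions are dropped.
#' @param ci_level Confidence level for all intervals.
#' @param exclude_below Optional copies threshold; levels with
#'   `copies < exclude_below` are dropped before fitting.
#' @return An object of class `standard_curve_fit`: a list with the fitted
#'   `lm` model, coefficient estimates and standard errors (`slope`,
#'   `intercept`, `se_slope`, `se_intercept`), the residual standard error
#'   `fit_se`, sufficient statistics (`n`, `df`, `mean_cq`, `mean_log10`,
#'   `sxx`), the efficiency estimate with its confidence interval, the
#'   calibration data and residuals.
#' @examples
#' sim <- simulate_dilution_series(10^(1:6), 3, seed = 1)
#' fit <- fit_standard_curve(sim)
#' glance(fit)
#' @export
fit_standard_curve <- function(reactions, ci_level = 0.95,
                               exclude_below = NULL) {
  reactions <- validate_reactions(reactions)
  if (length(ci_level) != 1 || !is.finite(ci_level) ||
      ci_level <= 0 || ci_level >= 1) {
    stop("`ci_level` must be in (0, 1).", call. = FALSE)
  }
  pts <- reactions[tolower(reactions$level_id) != "ntc" &
                     !is.na(reactions$cq), ]
  if (!is.null(exclude_below)) {
    pts <- pts[pts$copies >= exclude_below, ]
  }
  n_levels <- length(unique(pts$copies))
  if (n_levels < 2) {
    stop("degenerate design: need >= 2 distinct concentration levels.",
         call. = FALSE)
  }
  if (nrow(pts) < 3) {
    stop("need >= 3 calibration points (df = n - 2 must be >= 1).",
         call. = FALSE)
  }
  reps_per_level <- table(pts$copies)
  if (n_levels < 9 || any(reps_per_level < 4)) {
    warning("fewer than 9 levels with 4 replicates each; adequate for ",
            "verification, but method development recommends at least ",
            "9 levels in 4 replicates.", call. = FALSE)
  }

  pts$log10_copies <- log10(pts$copies)
  model <- stats::lm(cq ~ log10_copies, data = pts)
  smry <- withCallingHandlers(
    summary(model),
    warning = function(w) {
      # noise-free fixtures trip lm's perfect-fit caution; it is expected
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  cf <- smry$coefficients
  n <- nrow(pts)
  slope <- unname(cf["log10_copies", "Estimate"])
  if (slope >= 0) {
    warning("fitted slope is non-negative; the curve has no amplification ",
            "meaning.", call. = FALSE)
  }

  fit <- structure(
    list(
      model = model,
      data = tibble::as_tibble(pts),
      slope = slope,
      intercept = unname(cf["(Intercept)", "Estimate"]),
      se_slope = unname(cf["log10_copies", "Std. Error"]),
      se_intercept = unname(cf["(Intercept)", "Std. Error"]),
      fit_se = smry$sigma,
      n = n,
      df = n - 2L,
      mean_cq = mean(pts$cq),
      mean_log10 = mean(pts$log10_copies),
      sxx = sum((pts$log10_copies - mean(pts$log10_copies))^2),
      residuals = unname(stats::residuals(model)),
      ci_level = ci_level
    ),
    class = "standard_curve_fit"
  )
  fit$efficiency <- if (slope < 0) efficiency_ci(fit) else NULL
  fit
}

#' PCR efficiency from a standard-curve slope
#'
#' `E = 10^(-1/k) - 1`: the fraction of target molecules duplicated per
#' cycle implied by a slope of `k` cycles per decade.  A slope of
#' `-1/log10(2) = -3.3219` corresponds to perfect doubling (`E = 1`).
#'
#' @param slope Standard-curve slope in cycles per log10 copies; must be
#'   negative.
#' @return Efficiency as a fraction.
#' @examples
#' efficiency_from_slope(-3.33)   # 0.997
#' @export
efficiency_from_slope <- function(slope) {
  if (any(!is.finite(slope)) || any(slope >= 0)) {
    stop("`slope` must be negative for an amplification curve.",
         call. = FALSE)
  }
  10^(-1 / slope) - 1
}

#' @rdname efficiency_from_slope
#' @param efficiency Efficiency as a fraction in `(0, 1]`.
#' @export
slope_from_efficiency <- function(efficiency) {
  if (any(!is.finite(efficiency)) || any(efficiency <= 0)) {
    stop("`efficiency` must be > 0.", call. = FALSE)
  }
  -1 / log10(1 + efficiency)
}

#' Efficiency estimate with delta-method confidence interval
#'
#' The standard error of the efficiency follows from the slope standard
#' error as `SE(E) = SE(k) (1 + E) ln(10) / k^2`, and the interval is the
#' two-sided Student-t interval with `n - 2` degrees of freedom.
#'
#' @param fit A `standard_curve_fit`.
#' @param ci_level Confidence level; defaults to the fit's.
#' @return A tibble with `estimate`, `se`, `lower`, `upper`, `ci_level`.
#' @export
efficiency_ci <- function(fit, ci_level = fit$ci_level) {
  stopifnot(inherits(fit, "standard_curve_fit"))
  if (fit$df < 1) stop("need df >= 1 for a confidence interval.",
                       call. = FALSE)
  if (fit$slope >= 0) stop("non-negative slope has no efficiency meaning.",
                           call. = FALSE)
  e <- efficiency_from_slope(fit$slope)
  se <- fit$se_slope * (1 + e) * log(10) / fit$slope^2
  tq <- stats::qt(1 - (1 - ci_level) / 2, df = fit$df)
  tibble::tibble(estimate = e, se = se,
                 lower = e - tq * se, upper = e + tq * se,
                 ci_level = ci_level)
}

#' Standardized residuals of a standard-curve fit
#'
#' Residuals scaled by the residual standard error.  Points outside
#' `threshold` (by convention 3) standard deviations show outlying
#' behavior.
#'
#' @param fit A `standard_curve_fit`.
#' @param threshold Flagging threshold in standard deviations.
#' @return A tibble with the calibration points, `std_residual`, and a
#'   logical `flagged` column.  When the fit is exact (`fit_se = 0`) all
#'   standardized residuals are 0 and nothing is flagged.
#' @export
standardized_residuals <- function(fit, threshold = 3) {
  stopifnot(inherits(fit, "standard_curve_fit"))
  # an exact fit leaves only rounding-level residuals; report zeros
  std <- if (fit$fit_se > 1e-8 * max(1, abs(fit$mean_cq))) {
    fit$residuals / fit$fit_se
  } else {
    rep(0, length(fit$residuals))
  }
  out <- fit$data[, c("level_id", "copies", "replicate", "cq")]
  out$residual <- fit$residuals
  out$std_residual <- std
  out$flagged <- abs(std) > threshold
  out
}

#' Grubbs test for a single outlier
#'
#' Two-sided, single-pass Grubbs test on a set of residuals:
#' `G = max |r - mean(r)| / sd(r)` compared with the Student-t based
#' critical value at level `alpha`.  Iterative removal is deliberately not
#' performed.
#'
#' @param residuals Numeric vector, length >= 3.
#' @param alpha Significance level.
#' @return A list with `statistic`, `critical`, `index` (of the most
#'   extreme point, or `NA` when no outlier is declared), `outlier`
#'   (logical) and `alpha`.  Constant input (zero variance) is reported as
#'   no outlier with an `NA` statistic.
#' @export
grubbs_test <- function(residuals, alpha = 0.05) {
  n <- length(residuals)
  if (n < 3) stop("Grubbs test needs at least 3 residuals.", call. = FALSE)
  if (any(!is.finite(residuals))) {
    stop("`residuals` must be finite.", call. = FALSE)
  }
  s <- stats::sd(residuals)
  if (s == 0) {
    return(list(statistic = NA_real_, critical = NA_real_,
                index = NA_integer_, outlier = FALSE, alpha = alpha))
  }
  dev <- abs(residuals - mean(residuals))
  g <- max(dev) / s
  tq <- stats::qt(1 - alpha / (2 * n), df = n - 2)
  crit <- (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
  out <- g > crit
  list(statistic = g, critical = crit,
       index = if (out) which.max(dev) else NA_integer_,
       outlier = out, alpha = alpha)
}

#' Polynomial lack-of-fit test of the linear dynamic range
#'
#' Fits quadratic and cubic polynomials in log10 copies alongside the
#' straight line and tests with nested-model F-tests whether the
#' higher-order terms improve the fit.  The curve passes when neither the
#' quadratic nor the cubic term is significant at `alpha`.  As a
#' complementary, less noise-sensitive criterion, the maximum allowable
#' deviation from linearity is computed: the largest relative difference,
#' across levels and in linear scale, between concentrations back-calculated
#' through the cubic and through the linear fit.  Curves with a maximum
#' deviation below 20% would typically be accepted even when the F-test
#' fires.
#'
#' @inheritParams fit_standard_curve
#' @param alpha Significance level for the F-tests.
#' @return A list of class `linearity_report`: `p_quadratic`, `p_cubic`,
#'   `passes_linear`, `max_deviation_pct` (percent), `alpha`, `notes`.
#' @export
linearity_test <- function(reactions, alpha = 0.05) {
  reactions <- validate_reactions(reactions)
  pts <- reactions[tolower(reactions$level_id) != "ntc" &
                     !is.na(reactions$cq), ]
  pts$x <- log10(pts$copies)
  n_levels <- length(unique(pts$x))
  if (n_levels < 4 || nrow(pts) < 5) {
    stop("linearity test needs at least 4 distinct levels and 5 points ",
         "(5 levels recommended) to fit the cubic model.", call. = FALSE)
  }
  lin <- stats::lm(cq ~ x, data = pts)
  quad <- stats::lm(cq ~ x + I(x^2), data = pts)
  cub <- stats::lm(cq ~ x + I(x^2) + I(x^3), data = pts)
  p_quad <- stats::anova(lin, quad)$`Pr(>F)`[2]
  p_cub <- stats::anova(lin, cub)$`Pr(>F)`[2]

  # back-calculate each level through both fits, compare in linear scale
  k <- stats::coef(lin)[["x"]]
  m <- stats::coef(lin)[["(Intercept)"]]
  xs <- sort(unique(pts$x))
  cq_cubic <- stats::predict(cub, newdata = data.frame(x = xs))
  x_back <- (cq_cubic - m) / k
  max_dev <- max(abs(10^x_back - 10^xs) / 10^xs)

  notes <- character()
  if (max_dev < 0.2 && (p_quad < alpha || p_cub < alpha)) {
    notes <- c(notes, paste0(
      "polynomial terms significant but maximum deviation from linearity ",
      "is below 20%; the curve would typically still be accepted."))
  }
  structure(
    list(p_quadratic = p_quad, p_cubic = p_cub,
         passes_linear = p_quad >= alpha && p_cub >= alpha,
         max_deviation_pct = 100 * max_dev,
         alpha = alpha, notes = notes),
    class = "linearity_report"
  )
}

#' Working-Hotelling band around a standard curve
#'
#' Simultaneous confidence (or prediction) band: at each grid point the
#' half-width is `sqrt(2 F(ci_level; 2, n - 2)) * SEy.x * sqrt(h(x))` with
#' leverage `h(x) = 1/n + (x - mean_log10)^2 / Sxx`, plus `1/b` inside the
#' square root for a prediction band averaging `b` test replicates.  A
#' pointwise Student-t band is available via `simultaneous = FALSE`.
#'
#' @param fit A `standard_curve_fit`.
#' @param x_grid Values of log10 copies at which to evaluate the band.
#' @param kind `"confidence"` for the band on the line, `"prediction"` for
#'   new observations.
#' @param b Number of averaged test replicates (prediction band only).
#' @param ci_level Confidence level; defaults to the fit's.
#' @param simultaneous Use the Working-Hotelling multiplier (default) or a
#'   pointwise t multiplier.
#' @return A tibble with `log10_copies`, `cq_fit`, `lower`, `upper`,
#'   `half_width`.
#' @export
working_hotelling_band <- function(fit, x_grid,
                                   kind = c("confidence", "prediction"),
                                   b = 1, ci_level = fit$ci_level,
                                   simultaneous = TRUE) {
  stopifnot(inherits(fit, "standard_curve_fit"))
  kind <- match.arg(kind)
  if (length(x_grid) == 0) {
    return(tibble::tibble(log10_copies = numeric(), cq_fit = numeric(),
                          lower = numeric(), upper = numeric(),
                          half_width = numeric()))
  }
  if (kind == "prediction" && (b < 1 || b != floor(b))) {
    stop("`b` must be a positive integer.", call. = FALSE)
  }
  h <- 1 / fit$n + (x_grid - fit$mean_log10)^2 / fit$sxx
  if (kind == "prediction") h <- h + 1 / b
  mult <- if (simultaneous) {
    sqrt(2 * stats::qf(ci_level, 2, fit$df))
  } else {
    stats::qt(1 - (1 - ci_level) / 2, fit$df)
  }
  half <- mult * fit$fit_se * sqrt(h)
  cq_fit <- fit$intercept + fit$slope * x_grid
  tibble::tibble(log10_copies = x_grid, cq_fit = cq_fit,
                 lower = cq_fit - half, upper = cq_fit + half,
                 half_width = half)
}

#' Acceptance rules for a fitted standard curve
#'
#' A curve fails outright when the lower confidence bound of the efficiency
#' exceeds 100% -- an efficiency significantly above perfect doubling most
#' likely signals points outside the linear dynamic range tilting the fit.
#' A point estimate above 100% whose interval still spans 100% is accepted
#' with a warning, as is an efficiency below the common 90% working
#' threshold.
#'
#' @param fit A `standard_curve_fit`.
#' @return A list with `pass` (logical), `failures` and `warnings`
#'   (character vectors of reasons).
#' @export
acceptance_check <- function(fit) {
  stopifnot(inherits(fit, "standard_curve_fit"))
  eff <- fit$efficiency
  if (is.null(eff)) {
    return(list(pass = FALSE,
                failures = "no efficiency estimate (non-negative slope).",
                warnings = character()))
  }
  failures <- character()
  warnings <- character()
  if (eff$lower > 1) {
    failures <- c(failures, sprintf(
      "lower confidence bound of the efficiency (%.3f) exceeds 100%%; %s",
      eff$lower,
      "concentrations outside the linear range are likely included."))
  } else if (eff$estimate > 1) {
    warnings <- c(warnings, sprintf(
      "efficiency point estimate %.3f exceeds 100%% but its interval spans 100%%.",
      eff$estimate))
  }
  if (eff$estimate < 0.9) {
    warnings <- c(warnings, sprintf(
      "efficiency %.3f is below the common 90%% threshold.", eff$estimate))
  }
  if (eff$upper - eff$lower > 0.15) {
    warnings <- c(warnings, sprintf(
      "efficiency interval [%.3f, %.3f] is wide; the estimate carries little certainty.",
      eff$lower, eff$upper))
  }
  list(pass = length(failures) == 0, failures = failures,
       warnings = warnings)
}

#' @export
print.standard_curve_fit <- function(x, ...) {
  cat("qPCR standard curve fit\n")
  cat(sprintf("  points: %d (%d levels), df = %d\n", x$n,
              length(unique(x$data$copies)), x$df))
  cat(sprintf("  slope k:     %8.4f  (SE %.4f)\n", x$slope, x$se_slope))
  cat(sprintf("  intercept m: %8.4f  (SE %.4f)\n", x$intercept,
              x$se_intercept))
  cat(sprintf("  fit SE (SEy.x): %.4f cycles\n", x$fit_se))
  if (!is.null(x$efficiency)) {
    cat(sprintf("  efficiency E: %.3f  [%.3f, %.3f] (%d%% CI)\n",
                x$efficiency$estimate, x$efficiency$lower,
                x$efficiency$upper, round(100 * x$ci_level)))
  }
  invisible(x)
}

#' Tidy a standard-curve fit
#'
#' @param x A `standard_curve_fit`.
#' @param ... Unused.
#' @return One row per quantity (`slope`, `intercept`, `efficiency`) with
#'   `estimate`, `std_error`, `conf_low`, `conf_high`.
#' @export
tidy.standard_curve_fit <- function(x, ...) {
  tq <- stats::qt(1 - (1 - x$ci_level) / 2, df = x$df)
  out <- tibble::tibble(
    term = c("slope", "intercept"),
    estimate = c(x$slope, x$intercept),
    std_error = c(x$se_slope, x$se_intercept)
  )
  out$conf_low <- out$estimate - tq * out$std_error
  out$conf_high <- out$estimate + tq * out$std_error
  if (!is.null(x$efficiency)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      term = "efficiency", estimate = x$efficiency$estimate,
      std_error = x$efficiency$se, conf_low = x$efficiency$lower,
      conf_high = x$efficiency$upper))
  }
  out
}

#' Glance at a standard-curve fit
#'
#' @inheritParams tidy.standard_curve_fit
#' @return A one-row tibble with fit-level summaries.
#' @export
glance.standard_curve_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, df = x$df, slope = x$slope, intercept = x$intercept,
    fit_se = x$fit_se, r_squared = summary(x$model)$r.squared,
    efficiency = if (!is.null(x$efficiency)) x$efficiency$estimate
      else NA_real_,
    mean_cq = x$mean_cq, mean_log10 = x$mean_log10, sxx = x$sxx
  )
}
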