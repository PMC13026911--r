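#' Inverse prediction of log10 concentration from a measured Cq
#'
#' `log10(N) = (Cq - m) / k` through a fitted standard curve.  A warning is
#' raised when the result falls outside the calibrated concentration
#' interval (extrapolation).
#'
#' @param fit A `standard_curve_fit`.
#' @param cq Measured Cq value(s), cycles.
#' @return log10 copies per reaction, same length as `cq`.
#' @export
predict_log_n <- function(fit, cq) {
  stopifnot(inherits(fit, "standard_curve_fit"))
  if (fit$slope == 0) stop("slope is zero; cannot invert.", call. = FALSE)
  out <- (cq - fit$intercept) / fit$slope
  rng <- range(fit$data$log10_copies)
  if (any(out < rng[1] | out > rng[2])) {
    warning("prediction outside the calibrated interval [",
            signif(rng[1], 4), ", ", signif(rng[2], 4),
            "] log10 copies (extrapolation).", call. = FALSE)
  }
  out
}

#' Standard error of an inverse prediction
#'
#' \deqn{SE(\log N) = \frac{SE_{y.x}}{|k|}
#'   \sqrt{\frac{1}{b} + \frac{1}{n} +
#'         \frac{(Cq - \bar{Cq})^2}{k^2 \sum_i (\log N_i - \bar{\log N})^2}}}
#'
#' The three terms are the measurement variance of the averaged test-sample
#' Cq (`b` replicates), the uncertainty of the curve's height, and the
#' uncertainty of its slope, which grows quadratically with distance from
#' the calibration centroid -- precision is highest at the center of the
#' standard curve.
#'
#' @inheritParams predict_log_n
#' @param b Number of test-sample replicates averaged into `cq`.
#' @return Standard error of log10 copies.
#' @export
prediction_se <- function(fit, cq, b = 1) {
  stopifnot(inherits(fit, "standard_curve_fit"))
  if (any(b < 1) || any(b != floor(b))) {
    stop("`b` must be a positive integer.", call. = FALSE)
  }
  if (fit$df < 1) stop("need df >= 1.", call. = FALSE)
  (fit$fit_se / abs(fit$slope)) *
    sqrt(1 / b + 1 / fit$n + (cq - fit$mean_cq)^2 / (fit$slope^2 * fit$sxx))
}

#' Relative error of a confidence interval
#'
#' `100 * (upper - lower) / point`, the paper-style relative error used for
#' both log- and linear-scale intervals.
#'
#' @param point Point estimate.
#' @param lower,upper Interval bounds.
#' @return Relative error in percent.
#' @examples
#' relative_error(4.91, 4.73, 5.09)   # ~7.3
#' @export
relative_error <- function(point, lower, upper) {
  100 * (upper - lower) / point
}

#' Inverse prediction with confidence interval
#'
#' Combines [predict_log_n()] and [prediction_se()] into a full prediction:
#' the symmetric Student-t interval on the log10 scale (with the
#' calibration fit's `n - 2` degrees of freedom) and its back-transformed,
#' asymmetric linear-scale counterpart, plus relative errors on both
#' scales.
#'
#' @inheritParams prediction_se
#' @param ci_level Confidence level; defaults to the fit's.
#' @param sample_id Optional label carried into the output.
#' @return A one-row tibble: `sample_id`, `cq_mean`, `b`, `log10_n`,
#'   `se_log10`, `ci_log10_lower`, `ci_log10_upper`, `n_linear`,
#'   `ci_linear_lower`, `ci_linear_upper`, `re_log_pct`, `re_linear_pct`.
#' @export
prediction_ci <- function(fit, cq, b = 1, ci_level = fit$ci_level,
                          sample_id = NA_character_) {
  log_n <- predict_log_n(fit, cq)
  se <- prediction_se(fit, cq, b)
  tq <- stats::qt(1 - (1 - ci_level) / 2, df = fit$df)
  lo <- log_n - tq * se
  hi <- log_n + tq * se
  tibble::tibble(
    sample_id = sample_id, cq_mean = cq, b = as.integer(b),
    log10_n = log_n, se_log10 = se,
    ci_log10_lower = lo, ci_log10_upper = hi,
    n_linear = 10^log_n,
    ci_linear_lower = 10^lo, ci_linear_upper = 10^hi,
    re_log_pct = relative_error(log_n, lo, hi),
    re_linear_pct = relative_error(10^log_n, 10^lo, 10^hi)
  )
}

#' Predict test-sample concentrations from replicate Cq values
#'
#' Tidy front end to inverse prediction: takes replicate-level test-sample
#' measurements, averages the Cq values per sample on the Cq scale (so the
#' replicate count `b` entering the standard error equals the averaging
#' actually applied), and returns one prediction per sample.  With
#' `mode = "separate"` each replicate instead yields an independent
#' prediction with `b = 1`.
#'
#' The calibration and test samples must be measured and averaged the same
#' way; a consistency warning fires when the test replicate counts differ
#' from the calibration's per-level replication.
#'
#' @param fit A `standard_curve_fit`.
#' @param samples Data frame with columns `sample_id` and `cq` (one row per
#'   test replicate; `NA` Cq rows are dropped with a warning).
#' @param mode `"average"` (default) or `"separate"`.
#' @param ci_level Confidence level.
#' @return A tibble as from [prediction_ci()], one row per sample (or per
#'   replicate in `"separate"` mode).
#' @export
predict_samples <- function(fit, samples, mode = c("average", "separate"),
                            ci_level = fit$ci_level) {
  stopifnot(inherits(fit, "standard_curve_fit"))
  mode <- match.arg(mode)
  if (!all(c("sample_id", "cq") %in% names(samples))) {
    stop("`samples` needs columns sample_id and cq.", call. = FALSE)
  }
  samples <- tibble::as_tibble(samples)
  if (anyNA(samples$cq)) {
    warning("dropping negative (NA Cq) test replicates.", call. = FALSE)
    samples <- samples[!is.na(samples$cq), ]
  }
  if (nrow(samples) == 0) stop("no positive test replicates.", call. = FALSE)

  cal_reps <- unique(as.integer(table(fit$data$copies)))
  if (mode == "average") {
    agg <- samples |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::summarise(cq_mean = mean(.data$cq), b = dplyr::n(),
                       .groups = "drop")
    if (!all(agg$b %in% cal_reps)) {
      warning("test-sample replicate counts differ from the calibration ",
              "replication; calibrators and test samples should be ",
              "measured and averaged the same way.", call. = FALSE)
    }
    purrr::pmap_dfr(agg, function(sample_id, cq_mean, b) {
      prediction_ci(fit, cq_mean, b = b, ci_level = ci_level,
                    sample_id = sample_id)
    })
  } else {
    purrr::pmap_dfr(samples[, c("sample_id", "cq")],
                    function(sample_id, cq) {
      prediction_ci(fit, cq, b = 1, ci_level = ci_level,
                    sample_id = sample_id)
    })
  }
}

#' @export
predict.standard_curve_fit <- function(object, newdata, ...) {
  predict_samples(object, newdata, ...)
}

#' Quality-control check of a run against its standard curve
#'
#' For each QC sample with a known nominal copy number, compares the
#' measured Cq with the curve's fitted Cq at that concentration.  The
#' conventional intra-/inter-assay accuracy criterion is an absolute
#' deviation of at most 1 cycle (roughly 50--100% relative error in linear
#' scale); the run passes when every QC sample passes.  QC samples outside
#' the calibrated range are flagged but still evaluated, and fewer than two
#' QC levels triggers a warning (high and low QC levels are recommended).
#'
#' @param fit A `standard_curve_fit`.
#' @param qc_samples Data frame with columns `sample_id`, `copies`
#'   (nominal), `cq` (measured).
#' @param max_delta_cq Pass threshold in cycles.
#' @return A list with `samples` (per-QC tibble including `delta_cq`,
#'   `pass`, `in_range`) and `run_pass`.
#' @export
qc_check <- function(fit, qc_samples, max_delta_cq = 1) {
  stopifnot(inherits(fit, "standard_curve_fit"))
  if (!all(c("sample_id", "copies", "cq") %in% names(qc_samples))) {
    stop("`qc_samples` needs columns sample_id, copies, cq.", call. = FALSE)
  }
  if (length(unique(qc_samples$copies)) < 2) {
    warning("fewer than 2 QC levels; high and low QC samples are ",
            "recommended.", call. = FALSE)
  }
  x <- log10(qc_samples$copies)
  rng <- range(fit$data$log10_copies)
  expected_cq <- fit$intercept + fit$slope * x
  out <- tibble::tibble(
    sample_id = qc_samples$sample_id,
    copies = qc_samples$copies,
    cq = qc_samples$cq,
    expected_cq = expected_cq,
    delta_cq = qc_samples$cq - expected_cq,
    in_range = x >= rng[1] & x <= rng[2],
    pass = abs(qc_samples$cq - expected_cq) <= max_delta_cq
  )
  if (any(!out$in_range)) {
    warning("QC nominal concentration(s) outside the calibrated range; ",
            "evaluated anyway.", call. = FALSE)
  }
  list(samples = out, run_pass = all(out$pass))
}
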