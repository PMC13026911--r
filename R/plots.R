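#' Plot a standard curve with its Working-Hotelling band
#'
#' Calibration points, the fitted line and the simultaneous confidence (or
#' prediction) band.
#'
#' @param object A `standard_curve_fit`.
#' @param kind Band type, `"confidence"` or `"prediction"`.
#' @param b Averaged test replicates for a prediction band.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.standard_curve_fit <- function(object,
                                        kind = c("confidence", "prediction"),
                                        b = 1, ...) {
  kind <- match.arg(kind)
  rng <- range(object$data$log10_copies)
  grid <- seq(rng[1], rng[2], length.out = 100)
  band <- working_hotelling_band(object, grid, kind = kind, b = b)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$log10_copies, y = .data$cq)) +
    ggplot2::geom_ribbon(
      data = band,
      ggplot2::aes(x = .data$log10_copies, ymin = .data$lower,
                   ymax = .data$upper),
      inherit.aes = FALSE, fill = "red", alpha = 0.15) +
    ggplot2::geom_abline(slope = object$slope,
                         intercept = object$intercept) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "log10 copies per reaction", y = "Cq (cycles)",
                  title = sprintf("Standard curve: E = %.3f [%.3f, %.3f]",
                                  object$efficiency$estimate,
                                  object$efficiency$lower,
                                  object$efficiency$upper))
}

#' Plot a precision profile against the quantification criterion
#'
#' Per-level linear-scale RSD versus expected copies on a log axis, with
#' the RSD threshold drawn and levels containing negative reactions marked.
#'
#' @param object A `precision_profile`.
#' @param rsd_threshold Criterion line (fraction).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.precision_profile <- function(object, rsd_threshold = 0.25, ...) {
  dat <- object[!is.na(object$rsd), ]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$copies, y = 100 * .data$rsd)) +
    ggplot2::geom_hline(yintercept = 100 * rsd_threshold,
                        linetype = "dashed", colour = "red") +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$all_positive),
                        size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "black", `FALSE` = "red"),
      labels = c(`TRUE` = "all positive", `FALSE` = "some negative"),
      name = NULL) +
    ggplot2::labs(x = "expected copies per reaction (N)",
                  y = "RSD, linear scale (%)")
}

#' Plot an empirical LOD fit
#'
#' Observed positive fractions and the fitted sigmoid, with the detection
#' criterion and interpolated LOD marked.
#'
#' @param object A `lod_estimate`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lod_estimate <- function(object, ...) {
  prof <- object$profile
  p <- ggplot2::ggplot(prof, ggplot2::aes(x = .data$copies,
                                          y = .data$positive_fraction)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$confidence,
                        linetype = "dashed", colour = "blue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "expected copies per reaction (N)",
                  y = "fraction of positive reactions")
  if (!is.null(object$coefficients)) {
    cf <- object$coefficients
    inv <- if (object$link == "cloglog") {
      function(eta) -expm1(-exp(eta))
    } else {
      stats::plogis
    }
    grid <- 10^seq(log10(min(prof$copies)), log10(max(prof$copies)),
                   length.out = 100)
    curve <- tibble::tibble(copies = grid,
                            positive_fraction = inv(cf[1] + cf[2] *
                                                      log10(grid)))
    p <- p + ggplot2::geom_line(data = curve)
    if (is.finite(object$lod)) {
      p <- p + ggplot2::geom_vline(xintercept = object$lod,
                                   linetype = "dotted")
    }
  }
  p
}

#' Plot the theoretical Poisson RSD curve
#'
#' The hump-shaped relationship between expected copies per reaction and
#' the linear-scale RSD caused by aliquoting alone, with the LOQ criterion
#' drawn.
#'
#' @param efficiency PCR efficiency.
#' @param rsd_threshold Criterion line (fraction).
#' @param n_min,n_max Plotted range of expected copies.
#' @return A ggplot object.
#' @export
plot_theoretical_rsd <- function(efficiency = 1, rsd_threshold = 0.25,
                                 n_min = 0.1, n_max = 1000) {
  curve <- theoretical_rsd_curve(n_min, n_max, efficiency = efficiency)
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$n_expected,
                                      y = 100 * .data$rsd)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 100 * rsd_threshold,
                        linetype = "dashed", colour = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "expected copies per reaction (N)",
                  y = "RSD due to aliquoting, linear scale (%)")
}
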