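#' Per-level precision profile of a dilution series
#'
#' Summarizes each concentration level of a replicate-level reaction table:
#' replicate and positive counts, the SD of Cq over the positive reactions
#' only, and the linear-scale RSD obtained through the efficiency-dependent
#' conversion.  Where negative reactions occur, the SD over positives is a
#' biased (understated) measure of spread because the most extreme
#' low-count aliquots carry no Cq; such levels are marked with
#' `all_positive = FALSE` and still contribute.
#'
#' @param reactions Reaction tibble; `"ntc"` rows are ignored.
#' @param efficiency PCR efficiency used for the RSD conversion.
#' @return A tibble of class `precision_profile`, one row per level, with
#'   columns `copies`, `n_replicates`, `n_positive`, `positive_fraction`,
#'   `sd_cq`, `rsd`, `all_positive`.  Levels with fewer than two positives
#'   have `NA` SD/RSD and are flagged with a warning.  The efficiency is
#'   stored in attribute `"efficiency"`.
#' @export
precision_profile <- function(reactions, efficiency = 1) {
  reactions <- validate_reactions(reactions)
  check_efficiency(efficiency)
  tab <- reactions[tolower(reactions$level_id) != "ntc", ]
  if (nrow(tab) == 0) stop("no non-NTC reactions.", call. = FALSE)

  prof <- tab |>
    dplyr::group_by(.data$copies) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      n_positive = sum(!is.na(.data$cq)),
      positive_fraction = .data$n_positive / .data$n_replicates,
      sd_cq = ifelse(.data$n_positive >= 2,
                     stats::sd(.data$cq[!is.na(.data$cq)]), NA_real_),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$copies)
  prof$rsd <- ifelse(is.na(prof$sd_cq), NA_real_,
                     cq_sd_to_linear_rsd(ifelse(is.na(prof$sd_cq), 0,
                                                prof$sd_cq), efficiency))
  prof$all_positive <- prof$n_positive == prof$n_replicates
  if (!any(prof$n_positive >= 2)) {
    stop("no level has >= 2 positive replicates; SD is undefined everywhere.",
         call. = FALSE)
  }
  if (any(prof$n_positive < 2)) {
    warning("level(s) with fewer than 2 positive replicates have undefined ",
            "SD and are excluded from precision-based limits.",
            call. = FALSE)
  }
  if (any(!prof$all_positive & prof$n_positive >= 2)) {
    message("some levels contain negative reactions; their SD over ",
            "positives understates the true spread.")
  }
  attr(prof, "efficiency") <- efficiency
  class(prof) <- c("precision_profile", class(prof))
  prof
}

#' Empirical limit of detection from positive fractions
#'
#' Fits the per-level fraction of positive reactions against log10 expected
#' copies with a binomial sigmoid and interpolates the concentration at
#' which the fitted probability reaches `confidence` (by convention 95%).
#' The default complementary log-log link has inverse
#' `1 - exp(-exp(eta))`, whose shape coincides with the Poisson occupancy
#' curve `1 - exp(-N)`; a logistic link is available for assays whose
#' positive fraction departs from the Poisson form.  The confidence
#' interval is obtained by parametric bootstrap: per-level binomial
#' resampling of the positive counts, refit, and percentile interval of the
#' interpolated LOD.
#'
#' @param profile A `precision_profile`.
#' @param confidence Required probability of detection.
#' @param n_boot Number of bootstrap resamples for the CI.
#' @param link `"cloglog"` (default) or `"logit"`.
#' @param seed Optional seed for the bootstrap.
#' @return A list of class `lod_estimate`: `lod`, `ci` (length-2 vector),
#'   `confidence`, `link`, `coefficients`, `profile`.  When every level is
#'   fully positive the LOD is reported as below the lowest tested level
#'   (`lod = NA`, `status` field explains).
#' @export
empirical_lod <- function(profile, confidence = 0.95, n_boot = 500,
                          link = c("cloglog", "logit"), seed = NULL) {
  link <- match.arg(link)
  if (length(confidence) != 1 || confidence <= 0 || confidence >= 1) {
    stop("`confidence` must be in (0, 1).", call. = FALSE)
  }
  if (!all(c("copies", "n_replicates", "n_positive") %in% names(profile))) {
    stop("`profile` must be a precision profile.", call. = FALSE)
  }
  prof <- profile[order(profile$copies), ]
  if (all(prof$positive_fraction == 1)) {
    return(structure(list(
      lod = NA_real_, ci = c(NA_real_, NA_real_), confidence = confidence,
      link = link, coefficients = NULL, profile = prof,
      status = sprintf("all levels fully positive; LOD below the lowest tested level (%g).",
                       min(prof$copies))), class = "lod_estimate"))
  }
  if (nrow(prof) < 3) {
    stop("need >= 3 levels to fit the sigmoid.", call. = FALSE)
  }

  interp <- function(pos) {
    fit <- suppressWarnings(stats::glm(
      cbind(pos, prof$n_replicates - pos) ~ log10(prof$copies),
      family = stats::binomial(link)))
    eta <- stats::family(fit)$linkfun(confidence)
    cf <- stats::coef(fit)
    if (!is.finite(cf[2]) || cf[2] <= 0) return(NA_real_)
    unname(10^((eta - cf[1]) / cf[2]))
  }
  lod <- interp(prof$n_positive)
  if (!is.finite(lod)) {
    stop("sigmoid fit failed: positive fraction does not increase with ",
         "concentration.", call. = FALSE)
  }
  fit0 <- suppressWarnings(stats::glm(
    cbind(prof$n_positive, prof$n_replicates - prof$n_positive) ~
      log10(prof$copies), family = stats::binomial(link)))
  p0 <- stats::fitted(fit0)

  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    boots <- replicate(n_boot, {
      pos <- stats::rbinom(nrow(prof), prof$n_replicates, p0)
      interp(pos)
    })
    boots <- boots[is.finite(boots)]
    if (length(boots) >= max(20, n_boot / 2)) {
      ci <- unname(stats::quantile(boots, c(0.025, 0.975)))
    }
  }
  structure(list(lod = lod, ci = ci, confidence = confidence, link = link,
                 coefficients = stats::coef(fit0), profile = prof,
                 status = "ok"),
            class = "lod_estimate")
}

#' @export
print.lod_estimate <- function(x, ...) {
  cat("Empirical limit of detection\n")
  if (is.na(x$lod)) {
    cat(" ", x$status, "\n")
  } else {
    cat(sprintf("  LOD (%d%% detection): %.2f copies/reaction, 95%% CI [%.2f, %.2f]\n",
                round(100 * x$confidence), x$lod, x$ci[1], x$ci[2]))
    cat(sprintf("  sigmoid link: %s\n", x$link))
  }
  invisible(x)
}

#' Empirical limits of quantification from a precision profile
#'
#' The dynamic range is the contiguous interval of tested levels over which
#' the linear-scale RSD stays at or below the threshold (by convention
#' 25%).  The LLOQ is the lowest level of that contiguous interval, the
#' ULOQ its highest; transient sub-threshold dips at lower concentrations do
#' not set the LLOQ.  When the top of the tested range still satisfies the
#' criterion, there is no ULOQ within the studied range.
#'
#' @param profile A `precision_profile`.
#' @param rsd_threshold Precision criterion (fraction).
#' @return A list with `lloq`, `uloq` (`NA` when there is no ULOQ within
#'   range), `status` (`"ok"`, `"no ULOQ within range"` or
#'   `"not quantifiable in range"`), `rsd_threshold` and the per-level
#'   table with a `quantifiable` flag.
#' @export
empirical_loq <- function(profile, rsd_threshold = 0.25) {
  if (!all(c("copies", "rsd") %in% names(profile))) {
    stop("`profile` must be a precision profile.", call. = FALSE)
  }
  prof <- profile[order(profile$copies), ]
  defined <- !is.na(prof$rsd)
  if (sum(defined) < 2) {
    stop("need >= 2 levels with defined RSD.", call. = FALSE)
  }
  ok <- defined & prof$rsd <= rsd_threshold
  prof$quantifiable <- ok
  if (!any(ok)) {
    return(list(lloq = NA_real_, uloq = NA_real_,
                status = "not quantifiable in range",
                rsd_threshold = rsd_threshold, profile = prof))
  }
  # contiguous quantifiable run ending at the highest satisfying level
  idx <- which(defined)
  ok_seq <- ok[idx]
  top <- max(which(ok_seq))
  start <- top
  while (start > 1 && ok_seq[start - 1]) start <- start - 1
  lloq <- prof$copies[idx[start]]
  has_uloq <- top < length(idx)   # a higher tested level violates
  uloq <- if (has_uloq) prof$copies[idx[top]] else NA_real_
  list(lloq = lloq, uloq = uloq,
       status = if (has_uloq) "ok" else "no ULOQ within range",
       rsd_threshold = rsd_threshold, profile = prof)
}
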