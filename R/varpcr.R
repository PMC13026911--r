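#' varPCR: absolute copy number from replicate Cq variance
#'
#' When aliquoting uncertainty dominates replicate variation, the SD of Cq
#' across replicate reactions is determined by the expected copy number `N`
#' alone, so `N` can be estimated by inverting the theoretical Poisson RSD
#' curve at the observed RSD.  The curve is hump-shaped, so each RSD is
#' attained at two copy numbers; the ambiguity is resolved by the presence
#' of negative replicates: any negative reaction puts the sample on the low
#' branch (the drop in RSD at low copy number is caused by replicates
#' becoming negative), otherwise the high branch applies.
#'
#' Technical noise inflates the observed Cq SD and biases the estimate
#' downward on the high branch.  An optional known `sigma_tech` can be
#' subtracted in quadrature on the Cq scale before conversion; this is
#' experimental and off by default.
#'
#' @param cq Numeric vector of replicate Cq values for one sample/level,
#'   with `NA` marking negative reactions.
#' @param efficiency PCR efficiency in `(0, 1]`.
#' @param n_boot Bootstrap resamples for the percentile CI over replicate
#'   reactions (negatives included in the resampling); `0` skips the CI.
#' @param seed Optional seed for the bootstrap.
#' @param sigma_tech Optional technical Cq SD (cycles) subtracted in
#'   quadrature before conversion.
#' @return A list of class `varpcr_estimate`: `n_hat`, `branch`
#'   (`"low"`/`"high"`), `sd_cq`, `rsd`, `negative_fraction`, `ci`,
#'   `n_replicates`, `method = "variance"`.
#' @examples
#' sim <- simulate_dilution_series(100, 96, sigma_tech = 0, seed = 1)
#' varpcr_estimate(sim$cq, n_boot = 200, seed = 2)
#' @export
varpcr_estimate <- function(cq, efficiency = 1, n_boot = 2000, seed = NULL,
                            sigma_tech = 0) {
  check_efficiency(efficiency)
  if (length(cq) < 8) {
    stop("varPCR needs at least 8 replicate reactions.", call. = FALSE)
  }
  if (sum(!is.na(cq)) < 2) {
    stop("varPCR needs at least 2 positive replicates.", call. = FALSE)
  }
  if (sigma_tech < 0) stop("`sigma_tech` must be >= 0.", call. = FALSE)

  point <- function(v) {
    pos <- v[!is.na(v)]
    if (length(pos) < 2) return(NA_real_)
    s <- stats::sd(pos)
    s2 <- s^2 - sigma_tech^2
    if (s2 <= 0) return(Inf)
    branch <- if (anyNA(v)) "low" else "high"
    r <- cq_sd_to_linear_rsd(sqrt(s2), efficiency)
    tryCatch(invert_theoretical_rsd(r, efficiency, branch = branch),
             error = function(e) NA_real_, warning = function(w) Inf)
  }

  pos <- cq[!is.na(cq)]
  sd_obs <- stats::sd(pos)
  s2 <- sd_obs^2 - sigma_tech^2
  branch <- if (anyNA(cq)) "low" else "high"
  if (s2 <= 0) {
    warning("observed Cq variance does not exceed the stated technical ",
            "variance; concentration is above the quantifiable-by-variance ",
            "range.", call. = FALSE)
    return(structure(list(n_hat = Inf, branch = branch, sd_cq = sd_obs,
                          rsd = 0, negative_fraction = mean(is.na(cq)),
                          ci = c(NA_real_, NA_real_),
                          n_replicates = length(cq), method = "variance"),
                     class = "varpcr_estimate"))
  }
  rsd_obs <- cq_sd_to_linear_rsd(sqrt(s2), efficiency)
  n_hat <- invert_theoretical_rsd(rsd_obs, efficiency, branch = branch)

  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    boots <- replicate(n_boot, point(sample(cq, replace = TRUE)))
    boots <- boots[!is.na(boots)]
    if (length(boots) >= max(20, n_boot / 2)) {
      ci <- unname(stats::quantile(boots, c(0.025, 0.975)))
    }
  }
  structure(list(n_hat = n_hat, branch = branch, sd_cq = sd_obs,
                 rsd = rsd_obs, negative_fraction = mean(is.na(cq)),
                 ci = ci, n_replicates = length(cq), method = "variance"),
            class = "varpcr_estimate")
}

#' Occupancy (digital-PCR style) copy number from negative fraction
#'
#' The classical partition estimate `N = -log(f0)` where `f0` is the
#' fraction of negative replicate reactions, with a confidence interval
#' obtained by propagating the Wilson score interval for `f0` through the
#' log transform.  Companion to [varpcr_estimate()] on the low branch:
#' where a substantial share of reactions is negative, counting them is the
#' most precise readout.
#'
#' @param cq Numeric vector of replicate Cq values, `NA` = negative.
#' @param ci_level Confidence level for the Wilson interval.
#' @return A list of class `varpcr_estimate` with `method = "occupancy"`.
#' @examples
#' cq <- c(rep(NA, 37), rnorm(63, 30, 0.2))
#' varpcr_from_negatives(cq)
#' @export
varpcr_from_negatives <- function(cq, ci_level = 0.95) {
  n <- length(cq)
  n_neg <- sum(is.na(cq))
  if (n_neg == 0) {
    stop("no negative replicates; use varpcr_estimate() on the high branch.",
         call. = FALSE)
  }
  if (n_neg == n) {
    stop("no positive replicates; occupancy cannot distinguish the sample ",
         "from blank.", call. = FALSE)
  }
  f0 <- n_neg / n
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  centre <- (n_neg + z^2 / 2) / (n + z^2)
  half <- z * sqrt(n) / (n + z^2) * sqrt(f0 * (1 - f0) + z^2 / (4 * n))
  f_lo <- max(centre - half, 1e-12)
  f_hi <- min(centre + half, 1 - 1e-12)
  # low negative fraction -> high N: interval bounds reverse through -log
  structure(list(n_hat = -log(f0), branch = "low",
                 sd_cq = NA_real_, rsd = NA_real_,
                 negative_fraction = f0,
                 ci = c(-log(f_hi), -log(f_lo)),
                 n_replicates = n, method = "occupancy"),
            class = "varpcr_estimate")
}

#' Combined absolute quantification from replicate reactions
#'
#' Chooses the occupancy estimator whenever negative reactions were
#' observed -- the presence of negatives is exactly what makes partition
#' counting identifiable, and it is also what forces the variance estimator
#' onto its ill-conditioned low branch -- and the variance (varPCR)
#' estimator when every replicate is positive.  Together the two paths
#' extend the dynamic range of absolute quantification from well below one
#' copy per reaction to the point where aliquoting variance drowns in
#' technical noise.
#'
#' @inheritParams varpcr_estimate
#' @return A `varpcr_estimate`; its `method` field records which path was
#'   used.
#' @export
combined_estimate <- function(cq, efficiency = 1, n_boot = 2000,
                              seed = NULL) {
  if (anyNA(cq)) {
    varpcr_from_negatives(cq)
  } else {
    varpcr_estimate(cq, efficiency = efficiency, n_boot = n_boot,
                    seed = seed)
  }
}

#' Per-level varPCR estimates for a reaction table
#'
#' Applies [combined_estimate()] (or [varpcr_estimate()] with
#' `method = "variance"`) to each concentration level of a replicate-level
#' reaction table.
#'
#' @param reactions Reaction tibble.
#' @param efficiency PCR efficiency.
#' @param method `"combined"` (default) or `"variance"`.
#' @param n_boot,seed Passed to the estimator.
#' @return A tibble with one row per level: `copies` (expected), `n_hat`,
#'   `ci_lower`, `ci_upper`, `branch`, `method`, `negative_fraction`,
#'   `n_replicates`.
#' @export
varpcr <- function(reactions, efficiency = 1,
                   method = c("combined", "variance"),
                   n_boot = 0, seed = NULL) {
  method <- match.arg(method)
  reactions <- validate_reactions(reactions)
  tab <- reactions[tolower(reactions$level_id) != "ntc", ]
  est_fun <- if (method == "combined") combined_estimate else
    function(cq, ...) varpcr_estimate(cq, ...)
  tab |>
    dplyr::group_by(.data$copies) |>
    dplyr::group_modify(function(d, key) {
      est <- tryCatch(
        est_fun(d$cq, efficiency = efficiency, n_boot = n_boot, seed = seed),
        error = function(e) NULL, warning = function(w) NULL)
      if (is.null(est)) {
        return(tibble::tibble(n_hat = NA_real_, ci_lower = NA_real_,
                              ci_upper = NA_real_, branch = NA_character_,
                              method = NA_character_,
                              negative_fraction = mean(is.na(d$cq)),
                              n_replicates = nrow(d)))
      }
      tibble::tibble(n_hat = est$n_hat, ci_lower = est$ci[1],
                     ci_upper = est$ci[2], branch = est$branch,
                     method = est$method,
                     negative_fraction = est$negative_fraction,
                     n_replicates = est$n_replicates)
    }) |>
    dplyr::ungroup()
}

#' @export
print.varpcr_estimate <- function(x, ...) {
  cat("varPCR absolute quantification\n")
  cat(sprintf("  method: %s (branch: %s), %d replicates (%.0f%% negative)\n",
              x$method, x$branch, x$n_replicates,
              100 * x$negative_fraction))
  cat(sprintf("  N-hat: %.3g copies/reaction", x$n_hat))
  if (all(is.finite(x$ci))) {
    cat(sprintf("  [%.3g, %.3g]", x$ci[1], x$ci[2]))
  }
  cat("\n")
  invisible(x)
}

#' @export
tidy.varpcr_estimate <- function(x, ...) {
  tibble::tibble(estimate = x$n_hat, ci_lower = x$ci[1], ci_upper = x$ci[2],
                 branch = x$branch, method = x$method,
                 sd_cq = x$sd_cq, rsd = x$rsd,
                 negative_fraction = x$negative_fraction,
                 n_replicates = x$n_replicates)
}
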