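#' Poisson aliquoting probabilities
#'
#' When an aliquot is withdrawn from a homogeneous sample that holds on
#' average `n_expected` target molecules per aliquot volume, the actual number
#' of targets `x` in the aliquot is Poisson distributed.  These helpers give
#' the probability of observing exactly `x` targets and of the aliquot being
#' qPCR positive at all (`x > 0`).
#'
#' @param x Non-negative integer count(s) of target molecules in an aliquot.
#' @param n_expected Expected (mean) number of target molecules per aliquot,
#'   `N >= 0`.
#' @return `poisson_pmf()`: the probability `exp(-N) N^x / x!`;
#'   `prob_positive()`: `1 - exp(-N)`.
#' @examples
#' poisson_pmf(1, 1)       # ~0.37: one molecule when one is expected
#' prob_positive(3)        # ~0.95
#' @export
poisson_pmf <- function(x, n_expected) {
  if (any(!is.finite(x)) || any(x < 0) || any(x != floor(x))) {
    stop("`x` must be a non-negative integer.", call. = FALSE)
  }
  if (any(!is.finite(n_expected)) || any(n_expected < 0)) {
    stop("`n_expected` must be >= 0.", call. = FALSE)
  }
  stats::dpois(x, lambda = n_expected)
}

#' @rdname poisson_pmf
#' @export
prob_positive <- function(n_expected) {
  if (any(!is.finite(n_expected)) || any(n_expected < 0)) {
    stop("`n_expected` must be >= 0.", call. = FALSE)
  }
  -expm1(-n_expected)
}

#' Theoretical limit of detection under Poisson aliquoting
#'
#' The smallest expected copy number `N` at which an aliquot is positive with
#' the requested probability: the solution of `1 - exp(-N) = confidence`,
#' i.e. `-log(1 - confidence)`.  At 95% confidence this is about 3 molecules
#' per aliquot, a floor that no detection chemistry can beat because it stems
#' from the sampling of molecules into the reaction, not from the assay.
#'
#' @param confidence Required probability of a positive aliquot, in `(0, 1)`.
#' @return Expected copies per aliquot (molecules).
#' @examples
#' theoretical_lod()       # ~3 molecules
#' @export
theoretical_lod <- function(confidence = 0.95) {
  if (length(confidence) != 1 || !is.finite(confidence) ||
      confidence <= 0 || confidence >= 1) {
    stop("`confidence` must be in (0, 1).", call. = FALSE)
  }
  -log1p(-confidence)
}

#' Cq standard deviation from Poisson aliquoting alone
#'
#' For positive aliquots the target count follows a zero-truncated Poisson
#' distribution, and the log-linear response turns each count `x` into
#' `Cq(x) = m - log10(x) / log10(1 + E)`.  The standard deviation of Cq over
#' that distribution (the intercept `m` cancels) is the imprecision a
#' noise-free instrument would still show, purely from pipetting molecules.
#'
#' Moments are computed by direct enumeration of `x` from 1 to the point where
#' the Poisson tail mass drops below `1e-12`, renormalized by `1 - exp(-N)`;
#' this is exact to tolerance and free of sampling noise.
#'
#' @param n_expected Expected copies per aliquot, `N > 0` (all-negative
#'   aliquots carry no Cq).  Vectorized.
#' @param efficiency PCR efficiency in `(0, 1]`.
#' @return Standard deviation of Cq in cycles; tends to 0 as `N` grows.
#' @examples
#' truncated_cq_sd(16, efficiency = 1)
#' @export
truncated_cq_sd <- function(n_expected, efficiency = 1) {
  check_efficiency(efficiency)
  if (any(!is.finite(n_expected)) || any(n_expected <= 0)) {
    stop("`n_expected` must be > 0.", call. = FALSE)
  }
  vapply(n_expected, function(N) {
    # enumerate only where the Poisson mass lives (tail < 1e-12 each side)
    xmax <- max(30, stats::qpois(1e-12, N, lower.tail = FALSE) + 5)
    xmin <- max(1, stats::qpois(1e-12, N) - 5)
    x <- xmin:xmax
    w <- stats::dpois(x, N) / -expm1(-N)
    cq <- -log10(x) / log10(1 + efficiency)
    mu <- sum(w * cq)
    sqrt(sum(w * (cq - mu)^2))
  }, numeric(1))
}

#' Theoretical linear-scale RSD as a function of expected copy number
#'
#' Composes [truncated_cq_sd()] with [cq_sd_to_linear_rsd()]: the relative
#' standard deviation of concentration that Poisson aliquoting alone imposes
#' on replicate reactions holding `N` expected copies.  The curve is
#' hump-shaped: it rises while an increasing share of aliquots is positive,
#' peaks at a few molecules per aliquot, and then decays like
#' \eqn{1 / \sqrt{N \log(1+E)}}.
#'
#' @inheritParams truncated_cq_sd
#' @return Linear-scale relative standard deviation (fraction), vectorized
#'   over `n_expected`.
#' @seealso [theoretical_rsd_curve()] for a plotted-ready grid,
#'   [invert_theoretical_rsd()] for the varPCR inversion.
#' @examples
#' theoretical_rsd(c(1, 16, 64))
#' @export
theoretical_rsd <- function(n_expected, efficiency = 1) {
  cq_sd_to_linear_rsd(truncated_cq_sd(n_expected, efficiency), efficiency)
}

#' Evaluate the theoretical RSD curve on a grid
#'
#' @param n_min,n_max Range of expected copies (both `> 0`).
#' @param length_out Number of grid points (log-spaced).
#' @inheritParams truncated_cq_sd
#' @return A tibble with columns `n_expected` and `rsd`, and the efficiency
#'   recorded in attribute `"efficiency"`.
#' @export
theoretical_rsd_curve <- function(n_min = 0.1, n_max = 1000, length_out = 200,
                                  efficiency = 1) {
  if (n_min <= 0 || n_max <= n_min) {
    stop("need 0 < n_min < n_max.", call. = FALSE)
  }
  grid <- exp(seq(log(n_min), log(n_max), length.out = length_out))
  out <- tibble::tibble(
    n_expected = grid,
    rsd = theoretical_rsd(grid, efficiency)
  )
  attr(out, "efficiency") <- efficiency
  out
}

# locate the single interior maximum of the theoretical RSD curve
# (memoized per efficiency; called repeatedly by bootstrap inversions)
.rsd_peak_cache <- new.env(parent = emptyenv())
rsd_peak <- function(efficiency = 1) {
  key <- format(efficiency, digits = 15)
  hit <- .rsd_peak_cache[[key]]
  if (!is.null(hit)) return(hit)
  opt <- stats::optimize(function(n) theoretical_rsd(n, efficiency),
                         interval = c(0.1, 50), maximum = TRUE)
  out <- list(n_expected = opt$maximum, rsd = opt$objective)
  .rsd_peak_cache[[key]] <- out
  out
}

#' Invert the theoretical RSD curve
#'
#' Solves `theoretical_rsd(N, E) = rsd` for `N` by bisection to
#' `|dN| < 1e-6`.  Because the curve is hump-shaped the same RSD occurs at
#' two expected copy numbers; `branch = "high"` returns the solution on the
#' decreasing branch (all replicates positive), `branch = "low"` the one on
#' the increasing branch (some replicates negative).
#'
#' @param rsd Observed or target linear-scale RSD (fraction).
#' @inheritParams truncated_cq_sd
#' @param branch `"high"` (decreasing branch, default) or `"low"`.
#' @param n_max Upper search bound for the high branch.
#' @return Expected copies per aliquot.  Errors if `rsd` exceeds the curve
#'   maximum (inconsistent with Poisson-only variation) and returns `Inf`
#'   with a warning when `rsd` is 0 on the high branch (above the range that
#'   variance can quantify).
#' @export
invert_theoretical_rsd <- function(rsd, efficiency = 1,
                                   branch = c("high", "low"),
                                   n_max = 1e7) {
  branch <- match.arg(branch)
  check_efficiency(efficiency)
  if (length(rsd) != 1 || !is.finite(rsd) || rsd < 0) {
    stop("`rsd` must be a single finite value >= 0.", call. = FALSE)
  }
  peak <- rsd_peak(efficiency)
  if (rsd > peak$rsd) {
    stop(sprintf(
      paste0("observed RSD (%.3f) exceeds the Poisson-only maximum (%.3f); ",
             "variation is inconsistent with aliquoting uncertainty alone."),
      rsd, peak$rsd), call. = FALSE)
  }
  if (rsd == 0) {
    if (branch == "high") {
      warning("RSD of 0 has no finite solution; ",
              "concentration is above the quantifiable-by-variance range.",
              call. = FALSE)
      return(Inf)
    }
    return(0)
  }
  f <- function(n) theoretical_rsd(n, efficiency) - rsd
  interval <- if (branch == "high") {
    c(peak$n_expected, n_max)
  } else {
    c(1e-8, peak$n_expected)
  }
  if (branch == "high" && f(n_max) > 0) {
    stop("no high-branch solution below `n_max`; increase `n_max`.",
         call. = FALSE)
  }
  stats::uniroot(f, interval, tol = 1e-9)$root
}

#' Theoretical limit of quantification under Poisson aliquoting
#'
#' The expected copy number at which the theoretical linear-scale RSD falls
#' to a precision criterion (by convention 25%) on the decreasing branch of
#' the curve.  With perfect efficiency the criterion is met from about 26
#' molecules per aliquot; below that, aliquoting alone makes quantification
#' less precise than the criterion regardless of instrument quality.
#'
#' @param rsd_threshold Precision criterion as a fraction, default `0.25`.
#' @inheritParams truncated_cq_sd
#' @return A list with `loq` (the real-valued crossing, found by bracketing
#'   and bisection to `|dN| < 1e-6`), `loq_integer` (the smallest integer `N`
#'   on the decreasing branch whose RSD meets the criterion),
#'   `rsd_threshold`, and `efficiency`.  Errors with "no crossing" when the
#'   threshold is at or above the curve maximum.
#' @examples
#' theoretical_loq()$loq_integer   # 26 at E = 1
#' @export
theoretical_loq <- function(rsd_threshold = 0.25, efficiency = 1) {
  check_efficiency(efficiency)
  if (length(rsd_threshold) != 1 || !is.finite(rsd_threshold) ||
      rsd_threshold <= 0) {
    stop("`rsd_threshold` must be a single value > 0.", call. = FALSE)
  }
  peak <- rsd_peak(efficiency)
  if (rsd_threshold >= peak$rsd) {
    stop(sprintf(
      "no crossing: threshold %.3f is not below the curve maximum %.3f.",
      rsd_threshold, peak$rsd), call. = FALSE)
  }
  root <- invert_theoretical_rsd(rsd_threshold, efficiency, branch = "high")
  loq_int <- ceiling(root - 1e-9)
  # guard against the crossing landing within rounding of an integer
  while (theoretical_rsd(loq_int, efficiency) > rsd_threshold) {
    loq_int <- loq_int + 1
  }
  list(loq = root, loq_integer = loq_int,
       rsd_threshold = rsd_threshold, efficiency = efficiency)
}
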