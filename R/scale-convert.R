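#' Convert Cq-scale imprecision to linear-scale relative standard deviation
#'
#' A standard deviation of quantification-cycle (Cq) values maps onto a
#' relative standard deviation (coefficient of variation) of the underlying
#' starting-copy concentration through the PCR efficiency `E`:
#'
#' \deqn{RSD = \sqrt{(1+E)^{SD(Cq)^2} - 1}}
#'
#' One cycle corresponds to a fold-change of `1 + E` in concentration, so the
#' same Cq spread translates into a larger linear-scale spread when the
#' efficiency is higher.  The RSD is returned as a fraction (0.25, not 25%);
#' formatting as percent is left to the reporting layer.
#'
#' @param sd_cq Non-negative standard deviation of Cq values, in cycles.
#' @param efficiency PCR efficiency `E`, the fraction of molecules duplicated
#'   per cycle, in `(0, 1]`.
#' @return Linear-scale relative standard deviation as a fraction, same length
#'   as `sd_cq`.
#' @seealso [linear_rsd_to_cq_sd()] for the exact inverse,
#'   [theoretical_rsd()] which composes this conversion with the Poisson
#'   aliquoting model.
#' @examples
#' cq_sd_to_linear_rsd(0.25, efficiency = 1)
#' @export
cq_sd_to_linear_rsd <- function(sd_cq, efficiency = 1) {
  check_efficiency(efficiency)
  if (any(!is.finite(sd_cq)) || any(sd_cq < 0)) {
    stop("`sd_cq` must be finite and >= 0.", call. = FALSE)
  }
  sqrt((1 + efficiency)^(sd_cq^2) - 1)
}

#' Convert a linear-scale relative standard deviation to a Cq standard
#' deviation
#'
#' Exact algebraic inverse of [cq_sd_to_linear_rsd()]:
#' \deqn{SD(Cq) = \sqrt{\log_{1+E}(1 + RSD^2)}}
#'
#' @param rsd Non-negative relative standard deviation (fraction).
#' @inheritParams cq_sd_to_linear_rsd
#' @return Standard deviation on the Cq scale, in cycles.
#' @examples
#' linear_rsd_to_cq_sd(cq_sd_to_linear_rsd(0.5), efficiency = 1)
#' @export
linear_rsd_to_cq_sd <- function(rsd, efficiency = 1) {
  check_efficiency(efficiency)
  if (any(!is.finite(rsd)) || any(rsd < 0)) {
    stop("`rsd` must be finite and >= 0.", call. = FALSE)
  }
  sqrt(log1p(rsd^2) / log1p(efficiency))
}

# shared argument check: E must lie in (0, 1]
check_efficiency <- function(efficiency) {
  if (length(efficiency) != 1 || !is.finite(efficiency) ||
      efficiency <= 0 || efficiency > 1) {
    stop("`efficiency` must be a single value in (0, 1].", call. = FALSE)
  }
  invisible(efficiency)
}
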