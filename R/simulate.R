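#' Simulate a replicate-level qPCR dilution series
#'
#' Monte Carlo generator with the two variance sources that dominate
#' replicate spread in dilution series: Poisson aliquoting of target
#' molecules into reactions, and Gaussian technical noise on the measured
#' Cq.  Each reaction draws `x ~ Poisson(N)`; a draw of zero yields a
#' negative reaction (missing Cq), otherwise
#' `Cq = m - log10(x) / log10(1 + E) + Normal(0, sigma_tech)`.
#' Early-cycle amplification stochasticity is not modeled.
#'
#' @param levels Expected copies per reaction at each dilution level
#'   (strictly positive).
#' @param replicates Replicate count per level; recycled to `length(levels)`.
#' @param efficiency PCR efficiency in `(0, 1]`.
#' @param intercept Cq of a single target molecule (cycles).
#' @param sigma_tech Standard deviation of Gaussian Cq measurement noise
#'   (cycles).
#' @param seed Optional integer seed; a fixed seed makes the output fully
#'   reproducible.
#' @param outliers Optional data frame with columns `copies`, `replicate`,
#'   `offset` adding a Cq offset to specific reactions (applied last;
#'   negative reactions stay negative).
#' @return A tibble with columns `level_id`, `copies`, `replicate`, `cq`
#'   (`NA` for negative reactions), one row per reaction.
#' @examples
#' sim <- simulate_dilution_series(levels = 10^(1:5), replicates = 3, seed = 1)
#' @export
simulate_dilution_series <- function(levels,
                                     replicates = 3,
                                     efficiency = 1,
                                     intercept = 34,
                                     sigma_tech = 0.15,
                                     seed = NULL,
                                     outliers = NULL) {
  check_efficiency(efficiency)
  if (length(levels) < 1 || any(!is.finite(levels)) || any(levels <= 0)) {
    stop("`levels` must be strictly positive expected copy numbers.",
         call. = FALSE)
  }
  if (any(!is.finite(replicates)) || any(replicates < 1) ||
      any(replicates != floor(replicates))) {
    stop("`replicates` must be positive integers.", call. = FALSE)
  }
  if (length(sigma_tech) != 1 || !is.finite(sigma_tech) || sigma_tech < 0) {
    stop("`sigma_tech` must be a single value >= 0.", call. = FALSE)
  }
  if (length(intercept) != 1 || !is.finite(intercept)) {
    stop("`intercept` must be a single finite Cq value.", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  replicates <- rep_len(replicates, length(levels))

  slope_scale <- log10(1 + efficiency)
  tab <- tibble::tibble(
    copies = rep(levels, replicates),
    replicate = unlist(lapply(replicates, seq_len), use.names = FALSE)
  )
  x <- stats::rpois(nrow(tab), tab$copies)
  cq <- ifelse(x > 0,
               intercept - log10(pmax(x, 1)) / slope_scale +
                 stats::rnorm(nrow(tab), 0, sigma_tech),
               NA_real_)
  tab$cq <- cq
  tab$level_id <- format_level_id(tab$copies)
  tab <- tab[, c("level_id", "copies", "replicate", "cq")]

  if (!is.null(outliers)) {
    need <- c("copies", "replicate", "offset")
    if (!all(need %in% names(outliers))) {
      stop("`outliers` needs columns copies, replicate, offset.",
           call. = FALSE)
    }
    for (i in seq_len(nrow(outliers))) {
      hit <- tab$copies == outliers$copies[i] &
        tab$replicate == outliers$replicate[i]
      tab$cq[hit] <- tab$cq[hit] + outliers$offset[i]
    }
  }
  tab
}

format_level_id <- function(copies) {
  paste0("N", format(copies, trim = TRUE, scientific = FALSE, digits = 15))
}

#' Simulate an extreme validation dilution series
#'
#' Convenience preset emulating a method-validation experiment with very
#' heavy replication: two-fold dilutions from 2048 down to 1 expected copy
#' per reaction, with 128 replicates at the lowest level, 64 at intermediate
#' levels (2--512) and 32 at the two highest (1024, 2048); perfect doubling
#' (`E = 1`) and an intercept of 34 cycles.
#'
#' @inheritParams simulate_dilution_series
#' @return A reaction tibble as from [simulate_dilution_series()].
#' @examples
#' ext <- simulate_extreme_series(seed = 7)
#' @export
simulate_extreme_series <- function(seed = NULL, sigma_tech = 0.15,
                                    efficiency = 1, intercept = 34) {
  levels <- 2^(0:11)
  reps <- c(128, rep(64, 9), 32, 32)
  simulate_dilution_series(levels, reps,
                           efficiency = efficiency, intercept = intercept,
                           sigma_tech = sigma_tech, seed = seed)
}

#' Inject curvature at the top of a dilution series
#'
#' Adds a fixed Cq offset to every reaction at the highest concentration
#' level, reproducing the high-end curvature failure mode in which all
#' replicates at the top level sit above the fitted line.  Used to exercise
#' [linearity_test()].
#'
#' @param reactions Reaction tibble (`level_id`, `copies`, `replicate`,
#'   `cq`).
#' @param top_level_offset Cq offset in cycles added at the highest level.
#' @return The reaction tibble with offsets applied; row count unchanged.
#' @export
inject_curvature <- function(reactions, top_level_offset) {
  reactions <- validate_reactions(reactions)
  if (nrow(reactions) == 0) {
    stop("`reactions` is empty.", call. = FALSE)
  }
  if (length(unique(reactions$copies)) < 2) {
    stop("need at least 2 levels to inject curvature.", call. = FALSE)
  }
  top <- max(reactions$copies)
  reactions$cq[reactions$copies == top] <-
    reactions$cq[reactions$copies == top] + top_level_offset
  reactions
}
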