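# fixtures built in code, shared across test files

# exact calibration points on Cq = slope * log10(N) + intercept
exact_line_reactions <- function(levels = 10^(1:6), replicates = 3,
                                 slope = -1 / log10(2), intercept = 34) {
  tibble::tibble(
    level_id = rep(paste0("L", seq_along(levels)), each = replicates),
    copies = rep(levels, each = replicates),
    replicate = rep(seq_len(replicates), length(levels)),
    cq = intercept + slope * log10(rep(levels, each = replicates))
  )
}

# independent zero-truncated Poisson moment oracle: plain renormalized sum,
# written without reusing any package internals
oracle_truncated_sd <- function(n_expected, efficiency = 1, xmax = 200) {
  x <- seq_len(max(xmax, ceiling(n_expected + 20 * sqrt(n_expected))))
  # e^-N N^x / x! evaluated in log space to dodge overflow
  w <- exp(x * log(n_expected) - n_expected - lgamma(x + 1))
  w <- w / (1 - exp(-n_expected))
  cq <- -log10(x) / log10(1 + efficiency)
  mu <- sum(w * cq)
  sqrt(sum(w * (cq - mu)^2))
}

# moment-based standard error of a sample SD (accounts for kurtosis)
se_of_sd <- function(x) {
  n <- length(x)
  m <- mean(x)
  s2 <- stats::var(x)
  m4 <- mean((x - m)^4)
  sqrt(max(m4 - (n - 3) / (n - 1) * s2^2, 0) / n) / (2 * sqrt(s2))
}
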