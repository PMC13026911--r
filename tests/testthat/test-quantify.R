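noisy_fit <- function(seed = 17, sigma = 0.2) {
  suppressWarnings(fit_standard_curve(
    simulate_dilution_series(10^(2:7), 3, sigma_tech = sigma, seed = seed)))
}

test_that("inverse prediction inverts the calibration line", {
  fit <- noisy_fit()
  # the intercept is the Cq of a single copy
  expect_equal(suppressWarnings(predict_log_n(fit, fit$intercept)), 0,
               tolerance = 1e-12)
  # OLS passes through the centroid
  expect_equal(predict_log_n(fit, fit$mean_cq), fit$mean_log10,
               tolerance = 1e-12)
  # algebraic round trip through the response
  set.seed(3)
  cqs <- runif(100, fit$intercept + fit$slope * 7, fit$intercept)
  x <- suppressWarnings(predict_log_n(fit, cqs))
  expect_equal(fit$intercept + fit$slope * x, cqs, tolerance = 1e-12)
  expect_warning(predict_log_n(fit, fit$intercept + 1), "extrapolation")
})

test_that("prediction SE has the inverse-prediction structure", {
  fit <- noisy_fit()
  cq <- fit$intercept + fit$slope * 4
  # minimized at the calibration centroid
  grid <- seq(fit$intercept + fit$slope * 7, fit$intercept, length.out = 41)
  ses <- prediction_se(fit, grid, b = 1)
  expect_lte(prediction_se(fit, fit$mean_cq, 1), min(ses) + 1e-12)
  # decreasing in the number of averaged replicates
  expect_lt(prediction_se(fit, cq, 4), prediction_se(fit, cq, 1))
  # direct formula recomputation
  manual <- fit$fit_se / abs(fit$slope) *
    sqrt(1 + 1 / fit$n + (cq - fit$mean_cq)^2 / (fit$slope^2 * fit$sxx))
  expect_equal(prediction_se(fit, cq, 1), manual, tolerance = 1e-12)
  expect_error(prediction_se(fit, cq, 0), "positive integer")
  # exact fit: zero SE, zero-width CI
  fit0 <- suppressWarnings(fit_standard_curve(exact_line_reactions()))
  expect_equal(prediction_se(fit0, 25, 1), 0, tolerance = 1e-12)
  p0 <- suppressWarnings(prediction_ci(fit0, 25, 1))
  expect_equal(p0$re_log_pct, 0, tolerance = 1e-9)
})

test_that("prediction SE matches a Monte Carlo refit-and-measure oracle", {
  true_slope <- slope_from_efficiency(0.95)
  true_int <- 34
  cq_test <- true_int + true_slope * 4.5
  set.seed(99)
  preds <- replicate(3000, {
    x <- rep(2:7, each = 3)
    cq <- true_int + true_slope * x + rnorm(18, 0, 0.2)
    m <- lm.fit(cbind(1, x), cq)
    (cq_test + rnorm(1, 0, 0.2) - m$coefficients[1]) / m$coefficients[2]
  })
  # analytic SE with the true noise SD plugged in as the fit SE
  fit <- suppressWarnings(fit_standard_curve(
    exact_line_reactions(levels = 10^(2:7), replicates = 3,
                         slope = true_slope, intercept = true_int)))
  fit$fit_se <- 0.2
  se <- prediction_se(fit, cq_test, 1)
  expect_equal(sd(preds), se, tolerance = 0.05)
})

test_that("intervals are symmetric in log and upward-skewed in linear scale", {
  fit <- noisy_fit()
  p <- prediction_ci(fit, fit$intercept + fit$slope * 4.2, b = 2)
  expect_equal(p$log10_n - p$ci_log10_lower, p$ci_log10_upper - p$log10_n,
               tolerance = 1e-12)
  expect_equal(p$ci_linear_lower, 10^p$ci_log10_lower, tolerance = 1e-12)
  expect_equal(p$ci_linear_upper, 10^p$ci_log10_upper, tolerance = 1e-12)
  expect_gt(p$ci_linear_upper - p$n_linear, p$n_linear - p$ci_linear_lower)
})

test_that("relative errors reproduce the worked reference arithmetic", {
  expect_equal(relative_error(4.91, 4.73, 5.09), 7.3, tolerance = 0.05)
  expect_equal(relative_error(81200, 54100, 121900), 83.5, tolerance = 0.05)
})

test_that("replicate handling matches the b entering the standard error", {
  fit <- noisy_fit()
  cqs <- fit$intercept + fit$slope * 4 + c(-0.1, 0, 0.1)
  samples <- tibble::tibble(sample_id = "s1", cq = cqs)
  avg <- suppressWarnings(predict_samples(fit, samples))
  expect_identical(avg$b, 3L)
  expect_equal(avg$cq_mean, mean(cqs))
  expect_equal(avg$se_log10, prediction_se(fit, mean(cqs), 3))

  sep <- suppressWarnings(predict_samples(fit, samples, mode = "separate"))
  expect_identical(nrow(sep), 3L)
  expect_true(all(sep$b == 1L))
  # averaging improves precision over any single replicate
  expect_lt(avg$se_log10, min(sep$se_log10))
  # mismatched replicate handling triggers the consistency warning
  expect_warning(predict_samples(fit, samples[1:2, ]), "same way")
})

test_that("prediction CI coverage is near nominal in simulation", {
  true_slope <- slope_from_efficiency(0.95)
  hits <- 0
  n_sims <- 200
  for (i in seq_len(n_sims)) {
    sim <- simulate_dilution_series(10^(2:7), 3, efficiency = 0.95,
                                    sigma_tech = 0.2, seed = 40000 + i)
    fit <- suppressWarnings(fit_standard_curve(sim))
    true_log <- 4.3
    cq_obs <- 34 + true_slope * true_log + rnorm(1, 0, 0.2)
    p <- suppressWarnings(prediction_ci(fit, cq_obs, b = 1))
    if (p$ci_log10_lower <= true_log && true_log <= p$ci_log10_upper) {
      hits <- hits + 1
    }
  }
  expect_gte(hits / n_sims, 0.90)
  expect_lte(hits / n_sims, 0.99)
})

test_that("QC rule passes on-curve samples and fails cycle-sized offsets", {
  fit <- noisy_fit()
  on_curve <- tibble::tibble(
    sample_id = c("qc_low", "qc_high"), copies = c(1e3, 1e6),
    cq = fit$intercept + fit$slope * c(3, 6))
  chk <- qc_check(fit, on_curve)
  expect_true(chk$run_pass)
  expect_equal(chk$samples$delta_cq, c(0, 0), tolerance = 1e-12)

  off <- on_curve
  off$cq[2] <- off$cq[2] + 1.2
  chk2 <- qc_check(fit, off)
  expect_false(chk2$run_pass)
  expect_false(chk2$samples$pass[2])
  expect_true(chk2$samples$pass[1])

  expect_warning(qc_check(fit, on_curve[1, ]), "fewer than 2 QC")
  out_of_range <- tibble::tibble(sample_id = c("a", "b"),
                                 copies = c(1, 1e9),
                                 cq = fit$intercept + fit$slope * c(0, 9))
  expect_warning(chk3 <- qc_check(fit, out_of_range), "outside")
  expect_false(any(chk3$samples$in_range))
  expect_true(all(chk3$samples$pass))
})

test_that("run-level QC pass rate tracks the Gaussian prediction", {
  fit0 <- suppressWarnings(fit_standard_curve(
    exact_line_reactions(levels = 10^(2:7), replicates = 3)))
  sigma <- 0.3
  set.seed(55)
  passes <- replicate(400, {
    qc <- tibble::tibble(
      sample_id = c("lo", "hi"), copies = c(1e3, 1e6),
      cq = fit0$intercept + fit0$slope * c(3, 6) + rnorm(2, 0, sigma))
    qc_check(fit0, qc)$run_pass
  })
  expected <- (2 * pnorm(1 / sigma) - 1)^2
  se <- sqrt(expected * (1 - expected) / 400)
  expect_lt(abs(mean(passes) - expected), 4 * se)
})
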