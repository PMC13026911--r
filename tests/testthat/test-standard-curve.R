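test_that("exact line input is recovered exactly", {
  pts <- exact_line_reactions(slope = -3.3219, intercept = 34)
  fit <- suppressWarnings(fit_standard_curve(pts))
  expect_equal(fit$slope, -3.3219, tolerance = 1e-10)
  expect_equal(fit$intercept, 34, tolerance = 1e-10)
  expect_equal(fit$fit_se, 0, tolerance = 1e-10)
  expect_equal(sum(fit$residuals), 0, tolerance = 1e-8 * fit$n)
  expect_identical(fit$df, fit$n - 2L)
  res <- standardized_residuals(fit)
  expect_true(all(res$std_residual == 0))
  expect_false(any(res$flagged))
})

test_that("OLS matches an independent normal-equations solve", {
  sim <- simulate_dilution_series(10^(2:7), 3, sigma_tech = 0.3, seed = 21)
  fit <- suppressWarnings(fit_standard_curve(sim))
  x <- log10(sim$copies)
  y <- sim$cq
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept <- mean(y) - slope * mean(x)
  expect_equal(fit$slope, slope, tolerance = 1e-10)
  expect_equal(fit$intercept, intercept, tolerance = 1e-10)
  expect_equal(fit$sxx, sum((x - mean(x))^2), tolerance = 1e-10)
})

test_that("degenerate designs are rejected", {
  one_level <- exact_line_reactions(levels = 100, replicates = 4)
  expect_error(fit_standard_curve(one_level), "2 distinct")
  two_points <- exact_line_reactions(levels = c(10, 100), replicates = 1)
  expect_error(fit_standard_curve(two_points), ">= 3")
  expect_warning(fit_standard_curve(exact_line_reactions()),
                 "9 levels")
})

test_that("slope-to-efficiency conversion matches published values", {
  expect_equal(efficiency_from_slope(-3.33), 0.997, tolerance = 5e-4)
  expect_equal(efficiency_from_slope(-3.50), 0.930, tolerance = 1e-3)
  expect_equal(efficiency_from_slope(-1 / log10(2)), 1, tolerance = 1e-12)
  expect_error(efficiency_from_slope(3.3), "negative")
  # exact round trip
  for (e in c(0.7, 0.9, 0.997, 1)) {
    expect_equal(efficiency_from_slope(slope_from_efficiency(e)), e,
                 tolerance = 1e-12)
  }
})

test_that("efficiency interval follows the delta method", {
  sim <- simulate_dilution_series(10^(1:6), 3, sigma_tech = 0.2, seed = 5)
  fit <- suppressWarnings(fit_standard_curve(sim))
  eff <- fit$efficiency
  # independent delta-method check via numerical derivative
  h <- 1e-6
  dEdk <- (efficiency_from_slope(fit$slope + h) -
             efficiency_from_slope(fit$slope - h)) / (2 * h)
  expect_equal(eff$se, abs(dEdk) * fit$se_slope, tolerance = 1e-6)
  tq <- qt(0.975, fit$df)
  expect_equal(eff$upper - eff$lower, 2 * tq * eff$se, tolerance = 1e-10)
  # zero-noise fit gives a zero-width interval
  fit0 <- suppressWarnings(fit_standard_curve(exact_line_reactions()))
  expect_equal(fit0$efficiency$lower, fit0$efficiency$upper,
               tolerance = 1e-9)
})

test_that("slope recovery and efficiency CI coverage hold in simulation", {
  true_e <- 0.95
  hits_slope <- 0
  hits_eff <- 0
  n_sims <- 120
  for (i in seq_len(n_sims)) {
    sim <- simulate_dilution_series(10^(2:7), 3, efficiency = true_e,
                                    sigma_tech = 0.2, seed = 1000 + i)
    fit <- suppressWarnings(fit_standard_curve(sim))
    tq <- qt(0.975, fit$df)
    if (abs(fit$slope - slope_from_efficiency(true_e)) <=
          tq * fit$se_slope) hits_slope <- hits_slope + 1
    if (fit$efficiency$lower <= true_e && true_e <= fit$efficiency$upper)
      hits_eff <- hits_eff + 1
  }
  expect_gte(hits_slope, 0.90 * n_sims)
  expect_gte(hits_eff, 0.88 * n_sims)
  expect_lte(hits_eff, n_sims)
})

test_that("standardized residuals flag an injected outlier", {
  flagged <- 0
  for (i in 1:50) {
    # +5 sigma offset; enough points that the outlier cannot mask itself
    sim <- simulate_dilution_series(
      10^(3:8), 16, sigma_tech = 0.2, seed = 3000 + i,
      outliers = data.frame(copies = 1e4, replicate = 2, offset = 1.0))
    fit <- suppressWarnings(fit_standard_curve(sim))
    res <- standardized_residuals(fit)
    hit <- which(res$flagged)
    if (length(hit) >= 1 &&
          all(res$copies[hit] == 1e4 & res$replicate[hit] == 2)) {
      flagged <- flagged + 1
    }
  }
  expect_gte(flagged, 45)
})

test_that("Grubbs test flags a single gross outlier and respects edge cases", {
  gr <- grubbs_test(c(0.1, -0.2, 0.05, -0.1, 4.0))
  expect_true(gr$outlier)
  expect_identical(gr$index, 5L)
  expect_equal(gr$statistic, 1.7851, tolerance = 1e-4)
  expect_equal(gr$critical, 1.715, tolerance = 1e-3)  # published n=5 value

  none <- grubbs_test(c(-1, -0.5, 0, 0.5, 1))
  expect_false(none$outlier)
  expect_true(is.na(none$index))

  const <- grubbs_test(rep(0.3, 6))
  expect_false(const$outlier)
  expect_true(is.na(const$statistic))
  expect_error(grubbs_test(c(1, 2)), "at least 3")
})

test_that("linearity test passes straight data and detects top-level curvature", {
  sim <- simulate_dilution_series(10^(3:8), 3, sigma_tech = 0.1, seed = 9)
  rep_ok <- linearity_test(sim)
  expect_true(rep_ok$p_quadratic >= 0 && rep_ok$p_quadratic <= 1)

  hits <- 0
  for (i in 1:50) {
    # high-copy levels so technical noise dominates aliquoting
    sim <- simulate_dilution_series(10^(3:8), 3, sigma_tech = 0.1,
                                    seed = 5000 + i)
    bent <- inject_curvature(sim, 0.5)
    if (!linearity_test(bent)$passes_linear) hits <- hits + 1
  }
  expect_gte(hits, 45)

  # quadratic term estimate is ~0 on quadratic-free data
  sim <- simulate_dilution_series(10^(3:8), 4, sigma_tech = 0.05, seed = 31)
  quad <- lm(cq ~ log10(copies) + I(log10(copies)^2), data = sim)
  expect_lt(abs(coef(quad)[["I(log10(copies)^2)"]]), 0.05)

  expect_error(linearity_test(exact_line_reactions(levels = c(10, 100))),
               "4 distinct")
})

test_that("Working-Hotelling bands have the textbook geometry", {
  sim <- simulate_dilution_series(10^(1:6), 3, sigma_tech = 0.25, seed = 13)
  fit <- suppressWarnings(fit_standard_curve(sim))
  grid <- seq(0, 7, by = 0.1)
  conf <- working_hotelling_band(fit, grid, "confidence")
  pred <- working_hotelling_band(fit, grid, "prediction", b = 2)

  # narrowest at the calibration centroid
  at_centroid <- working_hotelling_band(fit, fit$mean_log10, "confidence")
  expect_lte(at_centroid$half_width, min(conf$half_width) + 1e-12)
  # prediction band strictly wider everywhere
  expect_true(all(pred$half_width > conf$half_width))
  # direct recomputation from sufficient statistics
  h <- 1 / fit$n + (grid - fit$mean_log10)^2 / fit$sxx
  manual <- sqrt(2 * qf(0.95, 2, fit$df)) * fit$fit_se * sqrt(h)
  expect_equal(conf$half_width, manual, tolerance = 1e-12)
  # empty grid, empty band
  expect_identical(nrow(working_hotelling_band(fit, numeric(0))), 0L)
  # pointwise band is narrower than the simultaneous one
  pw <- working_hotelling_band(fit, grid, "confidence",
                               simultaneous = FALSE)
  expect_true(all(pw$half_width < conf$half_width))
})

test_that("acceptance rules fire on the efficiency interval", {
  make_fit <- function(slope, se_slope = 0.02, n = 18) {
    f <- suppressWarnings(fit_standard_curve(
      exact_line_reactions(slope = slope)))
    f$se_slope <- se_slope
    f$efficiency <- efficiency_ci(f)
    f
  }
  ok <- make_fit(-3.33)
  expect_true(acceptance_check(ok)$pass)

  # lower CI bound above 100% -> hard failure
  hot <- make_fit(-3.1, se_slope = 0.01)
  expect_gt(hot$efficiency$lower, 1)
  expect_false(acceptance_check(hot)$pass)

  # estimate above 100% but CI spans it -> pass with warning
  warm <- make_fit(-3.25, se_slope = 0.05)
  chk <- acceptance_check(warm)
  expect_true(chk$pass)
  expect_true(any(grepl("spans 100", chk$warnings)))

  # low efficiency with wide CI -> pass with warnings
  low <- make_fit(-3.61, se_slope = 0.12)
  chk_low <- acceptance_check(low)
  expect_true(chk_low$pass)
  expect_true(any(grepl("below the common 90", chk_low$warnings)))
})

test_that("removing a flagged extreme outlier tightens the efficiency CI", {
  wider <- 0L
  for (i in 1:20) {
    sim <- simulate_dilution_series(
      10^(1:6), 3, sigma_tech = 0.15, seed = 7000 + i,
      outliers = data.frame(copies = 10, replicate = 1, offset = 2.5))
    fit <- suppressWarnings(fit_standard_curve(sim))
    res <- standardized_residuals(fit)
    drop_idx <- which.max(abs(res$std_residual))
    clean <- sim[!(sim$copies == res$copies[drop_idx] &
                     sim$replicate == res$replicate[drop_idx]), ]
    fit2 <- suppressWarnings(fit_standard_curve(clean))
    w1 <- fit$efficiency$upper - fit$efficiency$lower
    w2 <- fit2$efficiency$upper - fit2$efficiency$lower
    if (w2 > w1) wider <- wider + 1L
  }
  expect_identical(wider, 0L)
})

test_that("tidy and glance summarize the fit", {
  fit <- suppressWarnings(fit_standard_curve(
    simulate_dilution_series(10^(1:6), 3, seed = 2)))
  td <- tidy(fit)
  expect_setequal(td$term, c("slope", "intercept", "efficiency"))
  expect_true(all(td$conf_low < td$conf_high))
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_equal(gl$slope, fit$slope)
  expect_gt(gl$r_squared, 0.99)
})
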