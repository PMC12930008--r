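test_that("trapezoidal AUC matches analytic integrals", {
  expect_equal(compute_auc(0:24, rep(1, 25)), 24)
  t <- seq(0, 24, by = 0.1)
  analytic <- (1 - exp(-2.4)) / 0.1  # integral of exp(-0.1 t) over 0-24
  expect_equal(compute_auc(t, exp(-0.1 * t), method = "linear"), analytic,
               tolerance = 5e-3)
  # log-down trapezoid is exact on a mono-exponential decline
  expect_equal(compute_auc(t, exp(-0.1 * t), method = "lin_up_log_down"),
               analytic, tolerance = 1e-10)
  expect_equal(compute_auc(0:24, rep(0, 25)), 0)
  expect_error(compute_auc(c(0, 1), c(1, 1), t_end = 0.5), "two observations")
  expect_error(compute_auc(c(0, 1, 1), c(1, 1, 1)), "increasing")
})

test_that("AUC is additive over adjacent intervals", {
  t <- c(0, 0.5, 1, 2, 4, 8, 12, 18, 24)
  set.seed(3)
  for (i in 1:5) {
    conc <- exp(rnorm(length(t), 0, 0.5)) * exp(-0.1 * t)
    total <- compute_auc(t, conc)
    parts <- compute_auc(t, conc, t_end = 8) +
      compute_auc(t[t >= 8], conc[t >= 8])
    expect_equal(parts, total, tolerance = 1e-12)
  }
  # interpolated cut point between samples is consistent too (linear rule)
  conc <- 2 * exp(-0.2 * t)
  expect_equal(compute_auc(t, conc, t_end = 5, method = "linear") +
                 compute_auc(c(5, t[t > 5]),
                             c(approx(t, conc, 5)$y, conc[t > 5]),
                             method = "linear"),
               compute_auc(t, conc, method = "linear"), tolerance = 1e-12)
})

test_that("terminal slope regression recovers exact and model rates", {
  t <- c(1, 2, 4, 8, 12, 24)
  fit <- fit_lambda_z(t, 2 * exp(-0.05 * t))
  expect_equal(fit$lambda_z, 0.05, tolerance = 1e-10)
  expect_equal(log(2) / fit$lambda_z, 13.86, tolerance = 1e-3)
  expect_equal(fit$adj_r2, 1, tolerance = 1e-10)

  # profile with an absorption phase: terminal points recover ke
  prof <- simulate_profile(ref_compound(), dosing_regimen(100),
                           times = plasma_grid)
  fit2 <- fit_lambda_z(prof$time_h, prof$conc_mg_L)
  expect_equal(fit2$lambda_z, ref_ke, tolerance = 0.02)
  expect_equal(log(2) / fit2$lambda_z, 13.05, tolerance = 0.3)

  # rising terminal concentrations cannot give a negative slope
  bad <- fit_lambda_z(c(1, 2, 4, 8, 12), c(1, 0.9, 1.0, 1.2, 1.5))
  expect_false(bad$ok)
  expect_true(is.na(bad$lambda_z))
})

test_that("NCA on the clinical sampling grid recovers clearance", {
  prof <- simulate_profile(ref_compound(), dosing_regimen(100),
                           times = plasma_grid)
  res <- run_nca(prof)
  expect_equal(res$auc_inf, ref_auc_inf, tolerance = 0.05)
  expect_equal(100 / res$auc_inf, 5.151, tolerance = 0.05)
  expect_true(res$pct_extrapolated > 0 && res$pct_extrapolated < 100)
  expect_true(res$auc_inf >= res$auc_0_24)

  # dense grid: within 0.5%
  dense <- simulate_profile(ref_compound(), dosing_regimen(100))
  expect_equal(run_nca(dense)$auc_inf, ref_auc_inf, tolerance = 5e-3)
})

test_that("NCA scales linearly from plasma into milk", {
  prof <- simulate_profile(ref_compound(), dosing_regimen(100),
                           times = plasma_grid)
  both <- dplyr::bind_rows(prof, milk_profile(prof, 0.26))
  res <- run_nca(both)
  p <- res[res$matrix == "plasma", ]
  m <- res[res$matrix == "milk", ]
  for (col in c("cmax", "auc_0_24", "auc_last", "auc_inf")) {
    expect_equal(m[[col]], 0.26 * p[[col]], tolerance = 1e-9)
  }
  expect_equal(m$t_half, p$t_half, tolerance = 1e-9)
  expect_error(nca_summary(0, 1), "two quantifiable")
})

test_that("BLQ handling zeroes the pre-dose sample and drops trailing BLQ", {
  t <- c(0, 1, 2, 4, 8, 12, 24)
  conc <- c(NA, 0.5, 0.8, 0.6, 0.3, 0.15, NA)
  blq <- c(TRUE, rep(FALSE, 5), TRUE)
  res <- nca_summary(t, conc, blq)
  # leading BLQ counted as zero: AUC includes the 0-1 h triangle
  expect_equal(res$cmax, 0.8)
  expect_equal(res$auc_last,
               compute_auc(t[1:6], c(0, conc[2:6])), tolerance = 1e-12)
})

test_that("geometric and quantile summaries match their definitions", {
  expect_equal(geomean_cv(c(4, 4, 4))$geo_mean, 4)
  expect_equal(geomean_cv(c(4, 4, 4))$cv_pct, 0)
  g <- geomean_cv(c(2, 8))
  expect_equal(g$geo_mean, 4)
  expect_equal(g$cv_pct, 127.0458, tolerance = 1e-4)
  expect_error(geomean_cv(c(1, -1)), "positive")

  m <- median_iqr(c(1, 2, 3, 4))
  expect_equal(m$median, 2.5)
  expect_equal(m$iqr_low, 1.75)
  expect_equal(m$iqr_high, 3.25)
  expect_equal(median_iqr(c(1, 2, 3))$median, 2)

  # brute-force agreement and invariances on random inputs
  set.seed(9)
  for (i in 1:10) {
    x <- exp(rnorm(25, 0, 0.7))
    expect_equal(geomean_cv(x)$geo_mean, prod(x)^(1 / length(x)),
                 tolerance = 1e-9)
    expect_equal(geomean_cv(x)$cv_pct,
                 100 * sqrt(exp(var(log(x))) - 1), tolerance = 1e-9)
    expect_equal(geomean_cv(3 * x)$geo_mean, 3 * geomean_cv(x)$geo_mean,
                 tolerance = 1e-9)
    shuffled <- sample(x)
    expect_equal(median_iqr(shuffled), median_iqr(x))
    q <- sort(x)[c(7, 13, 19)]  # order-statistic sanity: quartiles inside
    expect_true(median_iqr(x)$iqr_low <= median_iqr(x)$median)
    expect_true(median_iqr(x)$median <= median_iqr(x)$iqr_high)
  }
})
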