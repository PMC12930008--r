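test_that("closed-form concentration matches hand evaluation of the model", {
  dor <- ref_compound()
  reg <- dosing_regimen(100)
  # hand-evaluated: F*D*ka/(V*(ka-ke)) * (exp(-ke t) - exp(-ka t)) at t = 2.72
  expect_equal(conc_onecomp(dor, reg, 2.72), 0.8923456, tolerance = 1e-6)
  # model Cmax sits near the back-calculated 0.89 mg/L at tmax ~ 2.72 h
  expect_equal(conc_onecomp(dor, reg, 2.72), 0.89, tolerance = 0.01)
  expect_identical(conc_onecomp(dor, reg, 0), 0)
  expect_error(conc_onecomp(dor, reg, -1), "Times")
})

test_that("dose linearity holds to analytic precision", {
  dor <- ref_compound()
  t <- c(0.5, 1, 2, 5, 12, 24)
  c1 <- conc_onecomp(dor, dosing_regimen(100), t)
  c2 <- conc_onecomp(dor, dosing_regimen(200), t)
  expect_equal(c2, 2 * c1, tolerance = 1e-12)
  # AUC_inf scales with dose too
  a1 <- run_nca(simulate_profile(dor, dosing_regimen(100)))$auc_inf
  a2 <- run_nca(simulate_profile(dor, dosing_regimen(200)))$auc_inf
  expect_lt(abs(a2 / a1 - 2), 1e-9)
})

test_that("multiple dosing equals superposition of shifted single doses", {
  dor <- ref_compound()
  t <- seq(0, 120, by = 0.5)
  multi <- conc_onecomp(dor, dosing_regimen(100, 24, n_doses = 5), t)
  single <- rowSums(sapply(0:4 * 24, function(td) {
    ifelse(t > td, conc_onecomp(dor, dosing_regimen(100), pmax(t - td, 0)), 0)
  }))
  expect_lt(max(abs(multi - single)), 1e-9)
})

test_that("once-daily steady-state trough shows the analytic accumulation", {
  dor <- ref_compound()
  ke <- dor$cl_f / dor$v_f
  n <- 200  # far beyond 5 half-lives of daily dosing
  trough_ss <- conc_onecomp(dor, dosing_regimen(100, 24, n_doses = n), n * 24)
  trough_1 <- conc_onecomp(dor, dosing_regimen(100), 24)
  expect_equal(trough_ss / trough_1, 1 / (1 - exp(-ke * 24)),
               tolerance = 1e-6)
})

test_that("absorption and elimination rate coincidence uses the limiting form", {
  flip <- compound_profile("flip", 300, 2, 8, "monoprotic_base", 0.5,
                           cl_f = 5, v_f = 100, ka = 0.05)
  t <- c(1, 5, 20, 60)
  exact <- flip$f_abs * 100 * flip$ka * t * exp(-flip$ka * t) / flip$v_f
  expect_equal(conc_onecomp(flip, dosing_regimen(100), t), exact,
               tolerance = 1e-12)
  # approaches the limit continuously
  near <- flip; near$ka <- 0.05 * (1 + 1e-9)
  expect_equal(conc_onecomp(near, dosing_regimen(100), t), exact,
               tolerance = 1e-6)
})

test_that("ODE backend agrees with the closed form to better than 0.1%", {
  skip_if_not_installed("deSolve")
  dor <- ref_compound()
  reg <- dosing_regimen(100, 24, n_doses = 3)
  t <- seq(1, 72, by = 1)
  a <- conc_onecomp(dor, reg, t)
  b <- conc_onecomp_ode(dor, reg, t)
  expect_lt(max(abs(a - b) / a), 1e-3)
})

test_that("simulated single-dose profile carries the analytic AUC_inf", {
  prof <- simulate_profile(ref_compound(), dosing_regimen(100))
  expect_equal(run_nca(prof)$auc_inf, ref_auc_inf, tolerance = 1e-3)
  expect_error(simulate_profile(ref_compound(), dosing_regimen(100),
                                times = numeric(0)), "nonempty")
  # day-5 AUC over the dosing interval equals single-dose AUC_inf (linear PK)
  reg5 <- dosing_regimen(100, 24, n_doses = 5)
  day5 <- simulate_profile(ref_compound(), reg5,
                           times = seq(96, 120, by = 0.05))
  auc_tau <- compute_auc(day5$time_h, day5$conc_mg_L)
  expect_equal(auc_tau, ref_auc_inf, tolerance = 0.01)
})

test_that("population simulation is reproducible and GM-preserving", {
  dor <- ref_compound(iiv = list(cl_f = 0.3, v_f = 0.25, ka = 0.3))
  subj <- sample_subjects(demographic_spec(), n = 10, seed = 5)
  e1 <- simulate_population(dor, dosing_regimen(100), subj, n_trials = 3,
                            seed = 11, times = plasma_grid)
  e2 <- simulate_population(dor, dosing_regimen(100), subj, n_trials = 3,
                            seed = 11, times = plasma_grid)
  expect_identical(e1$profiles, e2$profiles)
  expect_identical(e1$params, e2$params)

  # zero variability collapses every subject onto the typical profile
  e0 <- simulate_population(ref_compound(), dosing_regimen(100), subj,
                            n_trials = 2, seed = 1, times = plasma_grid)
  typical <- simulate_profile(ref_compound(), dosing_regimen(100),
                              plasma_grid)
  for (prof in split(e0$profiles, interaction(e0$profiles$trial,
                                              e0$profiles$subject_id))) {
    expect_equal(prof$conc_mg_L, typical$conc_mg_L, tolerance = 1e-12)
  }

  # log-normal IIV preserves the geometric mean of AUC = D/CL
  big <- simulate_population(dor, dosing_regimen(100),
                             sample_subjects(demographic_spec(), 100,
                                             seed = 2),
                             n_trials = 10, seed = 3, times = c(0, 24))
  gm_auc <- exp(mean(log(100 / big$params$cl_f)))
  expect_equal(gm_auc, ref_auc_inf, tolerance = 0.05)
})

test_that("VPC bands behave as order statistics of the ensemble", {
  dor <- ref_compound(iiv = list(cl_f = 0.3, v_f = 0.25, ka = 0.3))
  subj <- sample_subjects(demographic_spec(), n = 10, seed = 5)
  ens <- simulate_population(dor, dosing_regimen(100), subj, n_trials = 10,
                             seed = 7, times = plasma_grid)
  vpc <- summarize_vpc(ens)
  after_dose <- vpc[vpc$time_h > 0, ]
  expect_true(all(after_dose$conc_lo < after_dose$conc_mean))
  expect_true(all(after_dose$conc_hi > after_dose$conc_mean))

  # degenerate ensemble: all bands coincide with the single profile
  e0 <- simulate_population(ref_compound(), dosing_regimen(100),
                            subj[1, ], n_trials = 1, seed = 1,
                            times = plasma_grid)
  v0 <- summarize_vpc(e0)
  expect_equal(v0$conc_lo, v0$conc_hi, tolerance = 1e-12)
  expect_equal(v0$conc_mean, e0$profiles$conc_mg_L, tolerance = 1e-12)

  # ragged grids are rejected
  ragged <- ens
  ragged$profiles <- ragged$profiles[-2, ]
  expect_error(summarize_vpc(ragged), "time grid")
})
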