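test_that("Henderson-Hasselbalch ionized fractions are correct", {
  expect_equal(fraction_unionized(7.4, 7.4, "monoprotic_base"), 0.5)
  expect_equal(fraction_unionized(5, 7, "monoprotic_base"),
               1 / (1 + 1e-2), tolerance = 1e-10)
  expect_equal(fraction_unionized(5, 7, "monoprotic_base"), 0.9901,
               tolerance = 1e-4)
  expect_equal(fraction_unionized(5, 7, "monoprotic_acid"),
               1 / (1 + 1e2), tolerance = 1e-10)
  expect_equal(fraction_unionized(3, 10, "neutral"), 1)
  expect_error(fraction_unionized(7, 7, "diprotic"), "Unknown")
  expect_error(fraction_unionized(7, 15, "neutral"), "pH")
})

test_that("dynamic milk pH interpolates its anchors and clamps at 12 months", {
  anchors <- milk_ph_anchors()
  expect_equal(milk_ph(anchors$months[1]), anchors$ph[1])
  expect_equal(milk_ph(12), anchors$ph[2])
  mid <- mean(anchors$months)
  expect_equal(milk_ph(mid), mean(anchors$ph))
  # monotone non-decreasing across the supported range
  ages <- seq(0, 12, by = 0.25)
  expect_true(all(diff(milk_ph(ages)) >= 0))
  expect_warning(ph38 <- milk_ph(38), "clamped")
  expect_equal(ph38, milk_ph(12))
})

test_that("creamatocrit converts monotonically to fat fraction", {
  expect_equal(fat_fraction_from_creamatocrit(0), 0)
  expect_equal(fat_fraction_from_creamatocrit(5), 0.05)
  cr <- seq(0, 15, by = 0.5)
  expect_true(all(diff(fat_fraction_from_creamatocrit(cr)) > 0))
  expect_error(fat_fraction_from_creamatocrit(20), "creamatocrit")
})

test_that("phase-distribution model collapses to its symmetric limits", {
  cmp <- base_compound(pKa = 8)
  # full symmetry: equal pH, equal binding, no fat -> M/P = 1 for any pKa
  for (pka in c(2, 6, 8, 10)) {
    sym <- milk_plasma_ratio(
      base_compound(pKa = pka),
      milk_composition(ph_milk = 7.4, ph_plasma = 7.4, creamatocrit = 0,
                       fu_milk = 0.5))
    expect_lt(abs(sym$mp_ratio - 1), 1e-9)
  }
  # fu-ratio limit: no fat, equal pH, free milk -> M/P = fu_plasma/fu_milk
  lim <- milk_plasma_ratio(
    compound_profile("x", 300, 2, 8, "monoprotic_base", 0.24,
                     cl_f = 5, v_f = 100, ka = 1),
    milk_composition(ph_milk = 7.4, ph_plasma = 7.4, creamatocrit = 0,
                     fu_milk = 1))
  expect_lt(abs(lim$mp_ratio - 0.24), 1e-9)
  # decomposition invariant
  mp <- milk_plasma_ratio(cmp, milk_composition(6.5))
  expect_equal(mp$mp_ratio,
               mp$phi_plasma * cmp$fu_plasma * (mp$skim_term + mp$fat_term),
               tolerance = 1e-12)
})

test_that("ion trapping makes M/P strictly decreasing in milk pH for a base", {
  cmp <- base_compound(pKa = 8)
  phs <- seq(6.5, 7.6, by = 0.05)
  mps <- vapply(phs, function(ph) {
    milk_plasma_ratio(cmp, milk_composition(ph_milk = ph))$mp_ratio
  }, numeric(1))
  expect_true(all(diff(mps) < 0))
  # holds for the reference weak base too, if only marginally
  dor_mps <- vapply(phs, function(ph) {
    milk_plasma_ratio(ref_compound(), milk_composition(ph_milk = ph))$mp_ratio
  }, numeric(1))
  expect_true(all(diff(dor_mps) < 0))
})

test_that("M/P is a pure partition coefficient, invariant to concentration", {
  cmp <- ref_compound()
  prof <- simulate_profile(cmp, dosing_regimen(100), times = plasma_grid)
  mp <- milk_plasma_ratio(cmp, milk_composition(6.5))
  milk <- milk_profile(prof, mp)
  # AUC ratio equals mp for any plasma scale
  expect_equal(compute_auc(milk$time_h, milk$conc_mg_L) /
                 compute_auc(prof$time_h, prof$conc_mg_L),
               mp$mp_ratio, tolerance = 1e-12)
  prof2 <- dplyr::mutate(prof, conc_mg_L = conc_mg_L * 7)
  milk2 <- milk_profile(prof2, mp)
  expect_equal(milk2$conc_mg_L, 7 * milk$conc_mg_L, tolerance = 1e-12)
})

test_that("milk profile preserves Tmax and terminal half-life", {
  prof <- simulate_profile(ref_compound(), dosing_regimen(100),
                           times = plasma_grid)
  milk <- milk_profile(prof, 0.26)
  expect_identical(milk$matrix, rep("milk", nrow(milk)))
  expect_equal(milk$time_h[which.max(milk$conc_mg_L)],
               prof$time_h[which.max(prof$conc_mg_L)])
  lam_p <- fit_lambda_z(prof$time_h, prof$conc_mg_L)$lambda_z
  lam_m <- fit_lambda_z(milk$time_h, milk$conc_mg_L)$lambda_z
  expect_lt(abs(lam_m / lam_p - 1), 1e-9)
  expect_error(milk_profile(prof, -1), "mp")
})

test_that("doravirine reference configuration reproduces its calibrated M/P", {
  mp <- milk_plasma_ratio(doravirine(), milk_composition(6.5))
  expect_equal(mp$mp_ratio, 0.39, tolerance = 1e-3)
  # the calibration is in the fat term: removing fat drops M/P to ~fu ratio
  nofat <- milk_plasma_ratio(doravirine(),
                             milk_composition(6.5, creamatocrit = 0))
  expect_lt(nofat$mp_ratio, mp$mp_ratio)
})

test_that("default fu_milk scaling behaves at its ends", {
  expect_equal(default_fu_milk(1), 1)
  expect_lt(default_fu_milk(0.1), 1)
  expect_gt(default_fu_milk(0.1), 0.1)  # less binding protein in milk
})
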