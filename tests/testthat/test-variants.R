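test_that("the RA row is the identity and inputs are never mutated", {
  base <- channel_params()
  snap <- unclass(base)
  out <- apply_region(base, "RA")
  expect_identical(unclass(out), snap)
  af <- apply_af(base, "AF4")
  expect_identical(unclass(base), snap)   # purity
  expect_false(identical(unclass(af), snap))
  expect_error(apply_region(base, "XX"), "unknown region")
})

test_that("AF scenario transforms encode the documented percentage changes", {
  base <- channel_params()
  ctl <- apply_af(base, "CONTROL")
  expect_identical(unclass(ctl), unclass(base))
  af4 <- apply_af(base, "AF4")
  expect_equal(af4[["g_CaL"]] / base[["g_CaL"]], 0.30)
  expect_equal(af4[["g_Kur"]] / base[["g_Kur"]], 0.50)
  expect_equal(af4[["g_to"]] / base[["g_to"]], 0.35)
  expect_equal(af4[["g_K1"]] / base[["g_K1"]], 2.0)
  expect_equal(af4[["g_Ks"]] / base[["g_Ks"]], 2.0)
  expect_equal(af4[["k_NaCa"]] / base[["k_NaCa"]], 1.55)
  expect_equal(af4[["serca_vmax"]], 1.5)
  expect_equal(af4[["ryr_scale"]], 4.0)
  expect_equal(af4[["sr_leak_scale"]], 1.25)
  expect_equal(af4[["g_Kr"]], base[["g_Kr"]])   # unchanged
  af1 <- apply_af(base, "AF1")
  expect_equal(af1[["g_CaL"]] / base[["g_CaL"]], 0.30)
  expect_equal(af1[["tau_CaL_mult"]], 1.6)
  expect_equal(af1[["g_to"]] / base[["g_to"]], 0.30)
  expect_equal(af1[["shift_to_inact"]], 16)
  expect_equal(af1[["g_K1"]] / base[["g_K1"]], 2.0)
  expect_equal(af1[["g_Kur"]], base[["g_Kur"]])
  # diffusion reductions
  expect_equal(af_scenario("AF0")$d_reduction, 0.60)
  expect_equal(af_scenario("AF1")$d_reduction, 0.40)
  expect_equal(af_scenario("CONTROL")$d_reduction, 0)
})

test_that("region and AF transforms commute for multiplicative entries", {
  base <- channel_params()
  a <- apply_af(apply_region(base, "RAA"), "AF4")
  b <- apply_region(apply_af(base, "AF4"), "RAA")
  expect_equal(unclass(a), unclass(b), tolerance = 1e-12)
})

test_that("calibrated regional family reproduces the published APD ratios", {
  raa <- paced_apd("RAA")
  expect_equal(raa, 230, tolerance = 5)
  expect_equal(paced_apd("BB"), 297, tolerance = 5)
  expect_equal(paced_apd("AS"), 152, tolerance = 5)
  expect_equal(paced_apd("CT") / raa, 1.21, tolerance = 0.02)
  expect_equal(paced_apd("AS") / raa, 0.66, tolerance = 0.02)
  expect_equal(paced_apd("PM") / raa, 1.03, tolerance = 0.02)
  expect_equal(paced_apd("AVR") / raa, 0.71, tolerance = 0.02)
  expect_equal(paced_apd("LA") / raa, 0.86, tolerance = 0.02)
})

test_that("every regional model is abbreviated by every AF scenario", {
  regions <- c("RA", "CT", "PM", "RAA", "AVR", "AS", "LA", "LAA", "PV", "BB")
  for (rg in regions) {
    ctrl <- paced_apd(rg)
    for (sc in c("AF1", "AF2", "AF3", "AF4")) {
      expect_lt(paced_apd(rg, sc), ctrl,
                label = sprintf("APD90(%s, %s)", rg, sc))
    }
  }
})

test_that("AF-1/AF-2 shorten the base AP more than AF-3/AF-4", {
  ctrl <- paced_apd("RA")
  red <- vapply(c("AF1", "AF2", "AF3", "AF4"),
                function(sc) 1 - paced_apd("RA", sc) / ctrl, numeric(1))
  expect_gt(min(red[c("AF1", "AF2")]), max(red[c("AF3", "AF4")]))
})

test_that("LA-PV dispersion is preserved but reduced under AF-4", {
  gap_ctrl <- paced_apd("LA") - paced_apd("PV")
  gap_af4 <- paced_apd("LA", "AF4") - paced_apd("PV", "AF4")
  expect_gt(gap_ctrl, 0)
  expect_gt(gap_af4, 0)
  expect_lt(gap_af4, gap_ctrl)
})

test_that("regional table construction enforces the per-region channel sets", {
  expect_error(regional_table(list(PM = c(g_Kr = 2))), "may not scale")
  expect_error(regional_table(list(RA = c(g_CaL = 2))), "may not scale")
  tb <- regional_table(list(CT = c(g_CaL = 1.1)))
  expect_s3_class(tb, "regional_table")
})

test_that("regional calibration reproduces a stored region from scratch", {
  # empty target set: identity table
  tb0 <- calibrate_regional_table(targets = list())
  expect_identical(tb0$RA, numeric(0))
  # one-region re-derivation lands on the stored factors
  tb <- calibrate_regional_table(targets = list(AS = 152))
  stored <- default_regional_table()$AS
  expect_equal(tb$AS[names(stored)], stored, tolerance = 0.02)
  expect_lt(abs(attr(tb, "residuals")[["AS"]]), 1)
})
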