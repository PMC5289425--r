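test_that("the one-compartment collapse matches the closed-form solution", {
  m <- one_compartment_model(volume_l = 10, clearance_l_h = 1,
                             molecular_weight = 100)
  sim <- simulate_pk(m, dosing_regimen("iv_bolus", dose = 10), t_end = 24)
  prof <- get_profile(sim)
  grid <- seq(0, 24, length.out = 100)
  mg_l <- approx(prof$times, prof$values, xout = grid)$y * 100 / 1000
  expect_lt(max(abs(mg_l - exp(-0.1 * grid)) / exp(-0.1 * grid)), 1e-3)
  auc <- compute_auc(prof, c(0, 24)) * 100 / 1000
  expect_equal(auc, 10 * (1 - exp(-2.4)), tolerance = 5e-3)
})

test_that("with no elimination the body amount stays equal to the dose", {
  cmp <- compound_properties("inert", 250, 1, 0.5, "neutral")
  m <- pbpk_model(list(cmp), reduced_physiology("human"))
  sim <- simulate_pk(m, dosing_regimen("iv_bolus", 100), t_end = 24)
  mb <- mass_balance(sim)
  expect_lt(mb$max_relative_error, 1e-4)
  # urine/bile stay empty
  expect_equal(max(get_profile(sim, compartment = "urine")$values), 0)
  expect_equal(max(get_profile(sim, compartment = "bile")$values), 0)
})

test_that("all-linear models are exactly dose-proportional", {
  m <- toy_linear_model()
  s1 <- simulate_pk(m, dosing_regimen("iv_bolus", 50), t_end = 24)
  s2 <- simulate_pk(m, dosing_regimen("iv_bolus", 100), t_end = 24)
  p1 <- get_profile(s1)$values
  p2 <- get_profile(s2)$values
  expect_equal(p2, 2 * p1, tolerance = 1e-6)
  for (organ in c("liver", "kidney", "adipose")) {
    q1 <- get_profile(s1, compartment = organ,
                      subcompartment = "interstitial")$values
    q2 <- get_profile(s2, compartment = organ,
                      subcompartment = "interstitial")$values
    expect_equal(q2, 2 * q1, tolerance = 1e-6)
  }
})

test_that("saturable metabolism makes dose-normalized AUC non-decreasing in dose", {
  m <- toy_mm_model(vmax = 3000, Km = 5)
  aucs <- vapply(c(10, 100, 1000), function(d) {
    sim <- simulate_pk(m, dosing_regimen("iv_bolus", d), t_end = 48)
    compute_auc(get_profile(sim), c(0, 48)) / d
  }, 0)
  expect_true(all(diff(aucs) > 0))
})

test_that("mass balance holds through a metabolite chain with saturable metabolism", {
  m <- toy_mm_model()
  sim <- simulate_pk(m, dosing_regimen("iv_bolus", 200), t_end = 48)
  expect_lt(mass_balance(sim)$max_relative_error, 1e-4)
  # metabolite is actually formed and excreted
  met_urine <- get_profile(sim, "met", "urine")
  expect_gt(max(met_urine$values), 0)
})

test_that("oral dosing passes the lumen and respects the solubility cap", {
  cmp <- compound_properties("po_drug", 200, 1, 0.5, "neutral",
                             water_solubility = 1e6)
  m <- pbpk_model(list(cmp), reduced_physiology("human"),
                  clearances = list(po_drug = clearance_spec(
                    renal_plasma_clearance = 100)))
  reg <- dosing_regimen("oral", 100, intestinal_permeability = 1e-4)
  sim <- simulate_pk(m, reg, t_end = 24)
  expect_lt(mass_balance(sim)$max_relative_error, 1e-4)
  lumen <- get_profile(sim, compartment = "gut_lumen")
  expect_equal(lumen$values[1], 100 / 200 * 1000, tolerance = 1e-6)
  expect_lt(lumen$values[length(lumen$values)], lumen$values[1] * 0.01)
  # a poorly soluble compound absorbs strictly slower
  cmp2 <- compound_properties("po_drug", 200, 1, 0.5, "neutral",
                              water_solubility = 2)
  m2 <- pbpk_model(list(cmp2), reduced_physiology("human"),
                   clearances = list(po_drug = clearance_spec(
                     renal_plasma_clearance = 100)))
  sim2 <- simulate_pk(m2, reg, t_end = 24)
  lumen2 <- get_profile(sim2, compartment = "gut_lumen")
  expect_gt(lumen2$values[length(lumen2$values)],
            lumen$values[length(lumen$values)])
})

test_that("infusion delivers the dose over the stated duration", {
  m <- one_compartment_model(10, 0, molecular_weight = 100)
  reg <- dosing_regimen("iv_infusion", dose = 10, dose_times = 0,
                        infusion_duration = 4)
  sim <- simulate_pk(m, reg, t_end = 12)
  prof <- get_profile(sim)
  # no clearance: plateau = dose/V = 100 µmol / 10 L after the infusion
  end_conc <- prof$values[prof$times >= 4]
  expect_equal(end_conc, rep(10, length(end_conc)), tolerance = 1e-6)
  half <- approx(prof$times, prof$values, xout = 2)$y
  expect_equal(half, end_conc[1] / 2, tolerance = 1e-6)
  expect_lt(mass_balance(sim)$max_relative_error, 1e-4)
})

test_that("endothelial permeability overrides slow tissue equilibration", {
  cmp <- compound_properties("dfn_like", 296, 2, 0.1, "neutral")
  base <- pbpk_model(list(cmp), reduced_physiology("human"),
                     clearances = list(dfn_like = clearance_spec(
                       renal_plasma_clearance = 50)))
  limited <- pbpk_model(list(cmp), reduced_physiology("human"),
                        clearances = list(dfn_like = clearance_spec(
                          renal_plasma_clearance = 50)),
                        endothelial_permeability_overrides = list(
                          dfn_like = c(adipose = 1e-7)))
  reg <- dosing_regimen("iv_bolus", 100)
  s0 <- simulate_pk(base, reg, t_end = 6)
  s1 <- simulate_pk(limited, reg, t_end = 6)
  a0 <- compute_auc(get_profile(s0, compartment = "adipose",
                                subcompartment = "intracellular"), c(0, 6))
  a1 <- compute_auc(get_profile(s1, compartment = "adipose",
                                subcompartment = "intracellular"), c(0, 6))
  expect_lt(a1, a0 * 0.5)
  expect_lt(mass_balance(s1)$max_relative_error, 1e-4)
})

test_that("compute_auc handles the documented shapes", {
  tri <- list(times = c(0, 1, 2), values = c(0, 1, 0))
  expect_equal(compute_auc(tri, c(0, 2)), 1)
  const <- list(times = c(0, 24), values = c(10, 10))
  expect_equal(compute_auc(const, c(0, 24)), 240)
  tt <- seq(0, 200, by = 0.05)
  expdec <- list(times = tt, values = exp(-0.1 * tt))
  expect_equal(compute_auc(expdec, c(0, 200)), 10, tolerance = 5e-3)
  expect_error(compute_auc(tri, c(2, 1)), "exceed")
  expect_error(compute_auc(tri, c(0, 5)), "outside")
})

test_that("multiple bolus doses accumulate and balance", {
  m <- toy_linear_model()
  reg <- dosing_regimen("iv_bolus", dose = 50, dose_times = c(0, 8, 16))
  sim <- simulate_pk(m, reg, t_end = 24)
  expect_lt(mass_balance(sim)$max_relative_error, 1e-4)
  prof <- get_profile(sim)
  c_8minus <- approx(prof$times, prof$values, xout = 7.99)$y
  c_8plus <- approx(prof$times, prof$values, xout = 8.02)$y
  expect_gt(c_8plus, c_8minus)
})
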