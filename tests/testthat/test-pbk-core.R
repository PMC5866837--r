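test_that("zero dose gives identically zero concentrations", {
  sim <- pbk_simulate(e2_params(), scenario = fast_scenario("oral", 0))
  expect_equal(sim$cmax, 0)
  expect_equal(max(abs(sim$timecourse$conc_blood_uM)), 0)
  expect_equal(sim$mass_balance_error, 0)
})

test_that("IV bolus without clearance conserves the dose in the body", {
  chem <- chemical_params("X", mw = 200, log_pow = 2, papp_caco2 = 10,
                          clint_invitro = 0, fub_serum = 0.5)
  sim <- pbk_simulate(chem, scenario = fast_scenario("iv", 1, 6))
  body <- sim$timecourse |>
    dplyr::select(dplyr::all_of(c("blood", "liver", "fat", "rich", "slow"))) |>
    rowSums()
  expect_equal(max(abs(body - sim$dose_umol)) / sim$dose_umol, 0,
               tolerance = 1e-7)
  expect_equal(max(sim$timecourse$metabolized), 0)
})

test_that("mass balance closes to < 1e-6 on all scenarios", {
  grid <- list(
    list(chem = e2_params(), route = "oral", dose = 0.02),
    list(chem = e2_params(), route = "iv", dose = 0.08),
    list(chem = bpa_params(), route = "oral", dose = 10),
    list(chem = bpa_params(), route = "iv", dose = 100)
  )
  for (g in grid) {
    sim <- pbk_simulate(g$chem, scenario = fast_scenario(g$route, g$dose))
    expect_lt(sim$mass_balance_error, 1e-6)
    amounts <- sim$timecourse |>
      dplyr::select(-dplyr::all_of(c("time_h", "conc_blood_uM")))
    expect_true(all(amounts >= -1e-9 * sim$dose_umol))
  }
})

test_that("Cmax is strictly dose-proportional (all-first-order model)", {
  base <- pbk_simulate(bpa_params(), scenario = fast_scenario("oral", 10))
  for (alpha in c(0.1, 3, 10)) {
    scaled <- pbk_simulate(bpa_params(),
                           scenario = fast_scenario("oral", 10 * alpha))
    expect_equal(scaled$cmax / base$cmax, alpha, tolerance = 1e-6)
    expect_equal(scaled$auc / base$auc, alpha, tolerance = 1e-6)
  }
})

test_that("with absorption and clearance both zero, oral dose stays luminal", {
  chem <- chemical_params("X", mw = 200, log_pow = 2, papp_caco2 = 10,
                          clint_invitro = 0, fub_serum = 0.5)
  phys <- physiology_params(SAin = 0)
  sim <- pbk_simulate(chem, phys = phys, scenario = fast_scenario("oral", 5))
  expect_equal(max(sim$timecourse$conc_blood_uM), 0)
  luminal <- sim$timecourse$stomach +
    rowSums(sim$timecourse[, paste0("lumen_", 1:7)]) +
    sim$timecourse$unabsorbed
  expect_equal(max(abs(luminal - sim$dose_umol)) / sim$dose_umol, 0,
               tolerance = 1e-7)
})

test_that("halving solver tolerances moves Cmax by < 0.1%", {
  s1 <- pbk_simulate(e2_params(), scenario = fast_scenario("oral", 0.02),
                     rtol = 1e-8, atol = 1e-12)
  s2 <- pbk_simulate(e2_params(), scenario = fast_scenario("oral", 0.02),
                     rtol = 5e-9, atol = 5e-13)
  expect_lt(abs(s1$cmax - s2$cmax) / s1$cmax, 1e-3)
})

test_that("summary metrics come from the simulated course", {
  sim <- pbk_simulate(bpa_params(), scenario = fast_scenario("oral", 10))
  m <- cmax_auc(sim)
  expect_s3_class(m, "tbl_df")
  expect_equal(m$cmax, sim$cmax)
  # peak refinement can only raise Cmax relative to the coarse grid
  expect_gte(sim$cmax, max(sim$timecourse$conc_blood_uM) * (1 - 1e-9))
  # AUC equals the trapezoid of the output grid
  tc <- sim$timecourse
  expect_equal(m$auc,
               sum(diff(tc$time_h) *
                     (head(tc$conc_blood_uM, -1) + tail(tc$conc_blood_uM, -1)) / 2))
})

test_that("oral and IV routes differ by first-pass extraction", {
  oral <- pbk_simulate(bpa_params(), scenario = fast_scenario("oral", 10))
  iv <- pbk_simulate(bpa_params(), scenario = fast_scenario("iv", 10))
  expect_gt(iv$cmax, oral$cmax)
  expect_gt(iv$auc, oral$auc)
})

test_that("long-format tidier exposes the delimited-table schema", {
  sim <- pbk_simulate(e2_params(), scenario = fast_scenario("oral", 0.02, 2))
  long <- tidy(sim)
  expect_named(long, c("time_h", "compartment", "amount_umol", "conc_uM"))
  expect_setequal(unique(long$compartment),
                  c("stomach", paste0("lumen_", 1:7), "blood", "liver", "fat",
                    "rich", "slow", "metabolized", "unabsorbed"))
})
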