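test_that("Caco-2 to in vivo permeability regression evaluates correctly", {
  # unit case: at Papp,Caco-2 = 1 the regression collapses to its intercept,
  # 10^-0.5579 in the output scale (1e-4 cm/s), before cm/h conversion
  expect_equal(papp_invivo_from_caco2(1) / (1e-4 * 3600), 10^(-0.5579),
               tolerance = 1e-12)
  # direct evaluation of the published regression for the E2 Caco-2 value
  expect_equal(papp_invivo_from_caco2(17),
               10^(0.6836 * log10(17) - 0.5579) * 1e-4 * 3600,
               tolerance = 1e-12)
  # strictly increasing
  expect_gt(papp_invivo_from_caco2(20), papp_invivo_from_caco2(17))
  p <- sort(runif(20, 0.1, 100))
  expect_true(all(diff(papp_invivo_from_caco2(p)) > 0))
  expect_error(papp_invivo_from_caco2(0), "positive")
  expect_error(papp_invivo_from_caco2(-3), "positive")
})

test_that("alternative regression unit convention is exposed", {
  raw <- papp_invivo_from_caco2(17, unit_convention = "raw_cm_s")
  expect_equal(raw, 10^(0.6836 * log10(17e-6) - 0.5579) * 3600,
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(raw, papp_invivo_from_caco2(17))))
})

test_that("QPPR partition coefficients behave physically", {
  # a hypothetical tissue with blood's own composition partitions at exactly 1
  comp <- qppr_tissue_composition()
  blood_row <- comp[comp$tissue == "blood", ]
  same <- comp
  same$lipid <- blood_row$lipid
  same$water <- blood_row$water
  for (lp in c(-1, 0, 2.5, 4.01)) {
    pc <- partition_coefficients_qppr(lp, composition = same)
    expect_equal(pc$liver, 1, tolerance = 1e-12)
    expect_equal(pc$slowly_perfused, 1, tolerance = 1e-12)
  }
  # fat partitioning grows with lipophilicity
  expect_gt(partition_coefficients_qppr(4.01)$fat,
            partition_coefficients_qppr(3.32)$fat)
  # deterministic: identical inputs give identical outputs
  expect_identical(partition_coefficients_qppr(3.32),
                   partition_coefficients_qppr(3.32))
  # missing tissue is a configuration error
  expect_error(
    partition_coefficients_qppr(3, composition = comp[comp$tissue != "fat", ]),
    "missing tissue")
})

test_that("explicit partition coefficients bypass the QPPR", {
  pc <- partition_coefficients(liver = 2, fat = 50, richly_perfused = 2,
                               slowly_perfused = 1.5)
  chem <- chemical_params("X", mw = 200, log_pow = 3, papp_caco2 = 10,
                          clint_invitro = 100, fub_serum = 0.1,
                          partition_coefficients = pc)
  sim <- pbk_simulate(chem, scenario = fast_scenario("iv", 1, 2))
  expect_identical(sim$pc, pc)
  expect_error(partition_coefficients(liver = -1, fat = 1,
                                      richly_perfused = 1,
                                      slowly_perfused = 1), "> 0")
})

test_that("absorption rate is the bilinear product with closed units", {
  # 0.1 cm/h * 10 cm^2 * 1 mM (= 1 umol/cm^3) = 1 umol/h
  expect_equal(absorption_rate(0.1, 10, 1), 1)
  expect_equal(absorption_rate(0.1, 10, 0), 0)
  expect_equal(absorption_rate(0, 10, 5), 0)
  expect_equal(absorption_rate(0.1, 10, 2), 2 * absorption_rate(0.1, 10, 1))
  expect_equal(absorption_rate(0.2, 10, 1), 2 * absorption_rate(0.1, 10, 1))
  expect_error(absorption_rate(-0.1, 10, 1), ">= 0")
})

test_that("chemical parameter validation rejects bad inputs", {
  expect_error(e2_params(clint = -1), ">= 0")
  expect_error(chemical_params("X", mw = -1, log_pow = 3, papp_caco2 = 10,
                               clint_invitro = 1, fub_serum = 0.1), "positive")
  expect_error(chemical_params("X", mw = 200, log_pow = 3, papp_caco2 = 10,
                               clint_invitro = 1, fub_serum = 1.2), "fraction")
})
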