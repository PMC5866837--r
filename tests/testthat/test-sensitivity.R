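test_that("SC is exact for analytic maps", {
  expect_equal(normalized_sc(function(p) 3 * p, p = 2), 1, tolerance = 1e-12)
  expect_equal(normalized_sc(function(p) 10, p = 2), 0, tolerance = 1e-12)
  expect_equal(normalized_sc(function(p) 5 / p, p = 2), -1 / 1.05,
               tolerance = 1e-9) # forward difference of 1/p at +5%
  expect_error(normalized_sc(function(p) 0, p = 2), "zero")
  expect_error(normalized_sc(function(p) p, p = 2, delta = 0), "> 0")
})

test_that("empty parameter list yields an empty screen", {
  out <- sensitivity_screen(e2_params(), scenario = fast_scenario("oral", 0.02),
                            parameters = character(0))
  expect_equal(nrow(out), 0)
  expect_named(out, c("parameter", "sc", "abs_sc", "above_threshold"))
})

test_that("screen is deterministic and ranked by |SC|", {
  sc1 <- sensitivity_screen(e2_params(),
                            scenario = fast_scenario("oral", 0.02),
                            parameters = c("CLint", "S9P", "VLc", "kin"))
  sc2 <- sensitivity_screen(e2_params(),
                            scenario = fast_scenario("oral", 0.02),
                            parameters = c("CLint", "S9P", "VLc", "kin"))
  expect_identical(sc1, sc2)
  expect_true(all(diff(sc1$abs_sc) <= 0))
})

test_that("liver and absorption parameters dominate the oral Cmax", {
  for (case in list(list(chem = e2_params(), dose = 0.02),
                    list(chem = bpa_params(), dose = 10))) {
    sc <- sensitivity_screen(case$chem,
                             scenario = fast_scenario("oral", case$dose),
                             parameters = c("CLint", "S9P", "VLc", "Papp",
                                            "kin", "VFc"))
    get <- function(p) sc$sc[sc$parameter == p]
    expect_lt(get("CLint"), 0)                # clearance lowers Cmax
    expect_gt(abs(get("CLint")), 0.1)
    expect_gt(abs(get("S9P")), 0.1)
    expect_gt(abs(get("VLc")), 0.1)
    expect_gt(abs(get("Papp")), 0.1)
    expect_lt(abs(get("VFc")), 0.1)           # fat volume is immaterial
  }
})

test_that("CLint and S9P act through the same product", {
  sc <- sensitivity_screen(bpa_params(), scenario = fast_scenario("oral", 10),
                           parameters = c("CLint", "S9P"))
  expect_equal(sc$sc[1], sc$sc[2], tolerance = 1e-6)
})

test_that("SC of dose on Cmax is exactly 1 for the all-linear model", {
  f <- function(dose) {
    pbk_simulate(bpa_params(), scenario = fast_scenario("oral", dose))$cmax
  }
  expect_equal(normalized_sc(f, p = 10), 1, tolerance = 1e-6)
})

test_that("doubling the perturbation barely moves smooth SCs", {
  sc5 <- sensitivity_screen(e2_params(), scenario = fast_scenario("oral", 0.02),
                            parameters = c("CLint", "Papp"), delta = 0.05)
  sc10 <- sensitivity_screen(e2_params(), scenario = fast_scenario("oral", 0.02),
                             parameters = c("CLint", "Papp"), delta = 0.10)
  rel <- abs(sc10$sc - sc5$sc) / abs(sc5$sc)
  expect_true(all(rel < 0.05))
})

test_that("perturbing a volume fraction keeps the physiology consistent", {
  # the slowly perfused remainder absorbs the change, so simulation still
  # satisfies its mass-balance invariant
  phys <- physiology_params(VLc = 0.034 * 1.05)
  sim <- pbk_simulate(e2_params(), phys = phys,
                      scenario = fast_scenario("oral", 0.02))
  expect_lt(sim$mass_balance_error, 1e-6)
})
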