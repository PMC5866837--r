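test_that("noise-free exponential data are recovered essentially exactly", {
  ut <- make_uterotrophic(a = 100, b = 2, d = 1, noise_cv = 0, n_per_group = 3)
  fit <- fit_exponential(ut)
  expect_equal(fit$a, 100, tolerance = 1e-6)
  expect_equal(fit$b, 2, tolerance = 1e-6)
  expect_equal(fit$d, 1, tolerance = 1e-3)
  expect_true(fit$accepted)
})

test_that("noisy exponential data recover (a, b, d) within 10%", {
  ut <- make_uterotrophic(a = 100, b = 0.02, d = 1, noise_cv = 0.05,
                          doses = c(0, 10, 25, 50, 75, 100),
                          n_per_group = 8, seed = 31)
  fit <- fit_exponential(ut)
  expect_lt(abs(fit$a - 100) / 100, 0.10)
  expect_lt(abs(fit$b - 0.02) / 0.02, 0.10)
  expect_lt(abs(fit$d - 1), 0.4) # shape is weakly identified at d ~ 1
})

test_that("flat data are flagged with no benchmark dose", {
  ut <- make_uterotrophic(a = 100, b = 0, d = 1, noise_cv = 0.05, seed = 8)
  fit <- fit_exponential(ut)
  expect_false(fit$accepted)
  res <- suppressWarnings(bmd(ut))
  expect_false(res$accepted)
  expect_true(is.na(res$bmd10))
})

test_that("rescaling responses rescales a and leaves b, d unchanged", {
  ut <- make_uterotrophic(a = 100, b = 2, d = 1, noise_cv = 0.05, seed = 12)
  f1 <- fit_exponential(ut)
  f2 <- fit_exponential(dplyr::mutate(ut, response = response * 3))
  expect_equal(f2$a, 3 * f1$a, tolerance = 1e-6)
  expect_equal(f2$b, f1$b, tolerance = 1e-6)
  expect_equal(f2$d, f1$d, tolerance = 1e-6)
})

test_that("closed-form BMD matches a brute-force root-find to 1e-10 relative", {
  cases <- list(list(b = 0.02, d = 1), list(b = 0.01, d = 2),
                list(b = 2, d = 1.3), list(b = 5e-4, d = 3.7))
  for (cs in cases) {
    closed <- bmd_at_bmr(cs, bmr = 0.10)
    f <- function(x) cs$b * x^cs$d - log(1.1)
    brute <- uniroot(f, c(1e-12, 1e12), tol = closed * 1e-12)$root
    expect_equal(closed, brute, tolerance = 1e-10)
  }
  expect_equal(bmd_at_bmr(list(b = 0.02, d = 1)), log(1.1) / 0.02,
               tolerance = 1e-12)
  expect_equal(bmd_at_bmr(list(b = 0.01, d = 2)), sqrt(log(1.1) / 0.01),
               tolerance = 1e-12)
  expect_equal(bmd_at_bmr(list(b = 2, d = 1), bmr = 0), 0)
  expect_warning(res <- bmd_at_bmr(list(b = 0, d = 1)), "undefined")
  expect_true(is.na(res))
})

test_that("profile bounds bracket the point estimate on every fit", {
  for (seed in 1:8) {
    ut <- make_uterotrophic(a = 100, b = 2, d = 1, noise_cv = 0.08,
                            n_per_group = 5, seed = seed)
    res <- bmd(ut)
    expect_true(res$accepted)
    expect_lte(res$bmdl10, res$bmd10)
    expect_lte(res$bmd10, res$bmdu10)
    expect_gt(res$bmdl10, 0)
  }
})

test_that("the confidence interval narrows with sample size", {
  small <- bmd(make_uterotrophic(b = 2, noise_cv = 0.1, n_per_group = 4,
                                 seed = 99))
  large <- bmd(make_uterotrophic(b = 2, noise_cv = 0.1, n_per_group = 60,
                                 seed = 99))
  expect_lt(log(large$bmdu10 / large$bmdl10), log(small$bmdu10 / small$bmdl10))
  expect_lt(log(large$bmdu10 / large$bmdl10), 0.25)
})

test_that("profile interval coverage of the true BMD is near nominal", {
  true_bmd <- log(1.1) / 2
  hits <- 0; n_rep <- 250; n_acc <- 0
  for (i in seq_len(n_rep)) {
    ut <- make_uterotrophic(a = 100, b = 2, d = 1, noise_cv = 0.05,
                            n_per_group = 5, seed = 1000 + i)
    res <- suppressWarnings(bmd(ut))
    if (!res$accepted) next
    n_acc <- n_acc + 1
    if (res$bmdl10 <= true_bmd && true_bmd <= res$bmdu10) hits <- hits + 1
  }
  expect_gt(n_acc, 0.9 * n_rep)
  coverage <- hits / n_acc
  # nominal two-sided 90%; allow the usual small-sample optimism of profile
  # intervals at 5 animals/group plus Monte-Carlo error at 250 replicates
  expect_gt(coverage, 0.80)
  expect_lte(coverage, 1)
})

test_that("normal-error variant fits the same model family", {
  ut <- make_uterotrophic(a = 100, b = 2, d = 1, noise_cv = 0.03,
                          n_per_group = 8, seed = 77)
  fit <- fit_exponential(ut, error_model = "normal")
  expect_equal(fit$a, 100, tolerance = 0.05)
  expect_equal(fit$b, 2, tolerance = 0.1)
  expect_true(fit$accepted)
})

test_that("bmd input contract is enforced", {
  expect_error(fit_exponential(tibble::tibble(dose = c(1, 2, 3, 4),
                                              response = c(1, 2, 3, 4))),
               "control")
  expect_error(fit_exponential(tibble::tibble(dose = c(0, 1, 2),
                                              response = c(1, 2, 3))),
               "4 dose groups")
})
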