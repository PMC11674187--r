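test_that("fractional block obeys the Hill equation limits and worked value", {
  expect_equal(fractional_block(0, 87.64), 0)
  expect_equal(fractional_block(50, 50, 1), 0.5)
  expect_equal(fractional_block(123.4, 123.4, 3.7), 0.5)
  expect_equal(fractional_block(200, 87.64, 1), 0.6953, tolerance = 5e-4 / 0.6953)
  # strictly increasing in concentration, decreasing in IC50
  cc <- c(1, 10, 100, 1000)
  expect_true(all(diff(fractional_block(cc, 100)) > 0))
  expect_gt(fractional_block(100, 50), fractional_block(100, 500))
})

test_that("single-point IC50 reproduces the published worked arithmetic", {
  expect_equal(ic50_single_point(200, 0.6953)$ic50, 87.64,
               tolerance = 0.01 / 87.64)
  expect_equal(ic50_single_point(200, 0.3668, 0.2366)$ic50, 1336.1,
               tolerance = 0.1 / 1336.1)
  expect_equal(ic50_single_point(200, 0.1097, 0.041)$ic50, 2711.2,
               tolerance = 0.2 / 2711.2)
  for (d in c(1, 50, 900)) expect_equal(ic50_single_point(d, 0.5)$ic50, d)
  expect_error(ic50_single_point(200, 0.2, 0.3), "no measurable block")
  expect_error(ic50_single_point(200, 1.0), "saturat")
})

test_that("single-point estimator inverts fractional_block for any slope", {
  for (n_h in c(0.5, 1, 2.3)) {
    for (f in c(0.05, 0.3, 0.6953, 0.95)) {
      ic <- ic50_single_point(200, f, n_h = n_h)$ic50
      expect_equal(fractional_block(200, ic, n_h), f, tolerance = 1e-12)
    }
  }
})

test_that("Hill fits recover exact and noisy dose-response parameters", {
  conc <- c(10, 30, 100, 300, 1000)
  pts <- data.frame(concentration = conc,
                    inhibition = fractional_block(conc, 46.5, 1))
  fit <- fit_hill(pts, fix_n_h = 1)
  expect_equal(fit$ic50, 46.5, tolerance = 0.1 / 46.5)

  free <- fit_hill(data.frame(concentration = conc,
                              inhibition = fractional_block(conc, 87.6, 1.6)),
                   fix_n_h = NULL)
  expect_equal(free$ic50, 87.6, tolerance = 1e-3)
  expect_equal(free$n_h, 1.6, tolerance = 1e-3)

  # Monte-Carlo recovery at 10% noise, 4 concentrations
  set.seed(202)
  meds <- replicate(100, {
    cc <- c(20, 60, 180, 540)
    inh <- pmin(pmax(fractional_block(cc, 87.6) *
                       (1 + stats::rnorm(4, sd = 0.1)), 1e-4), 0.999)
    fit_hill(data.frame(concentration = cc, inhibition = inh))$ic50
  })
  expect_lt(abs(stats::median(meds) / 87.6 - 1), 0.15)

  expect_error(fit_hill(data.frame(concentration = c(1, 2, 3),
                                   inhibition = c(0, 0, 0))),
               "non-identifiable")
})

test_that("one-concentration Hill fit with fixed slope equals the closed form", {
  pts <- data.frame(concentration = 200, inhibition = 0.6953)
  fit <- fit_hill(pts, fix_n_h = 1)
  expect_equal(fit$ic50, ic50_single_point(200, 0.6953)$ic50,
               tolerance = 1e-6)
})

test_that("drug model validates fields and the built-in compound is complete", {
  ceno <- cenobamate_model()
  expect_setequal(ceno$channels$channel,
                  c("INa_peak", "INaL", "ICaL", "IKr", "IKs"))
  expect_equal(ceno$c_max, 170)
  expect_equal(ceno$free_fraction, 0.4)
  expect_equal(ugml_to_um(45.5), 169.98, tolerance = 1e-4)

  expect_error(drug_model("x", data.frame(channel = "IKr", ic50 = -1,
                                          n_h = 1)), "> 0")
  expect_error(drug_model("x", data.frame(channel = "IKr", ic50 = 1,
                                          n_h = 1), free_fraction = 1.2),
               "free_fraction")
})
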