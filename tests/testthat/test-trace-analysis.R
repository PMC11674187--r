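test_that("peak measurement handles degenerate, offset and synthetic traces", {
  tt <- seq(0, 100, by = 0.1)
  flat <- rep(0, length(tt))
  pk <- measure_peak(flat, tt, c(20, 60), "inward")
  expect_equal(pk$peak_value, 0)
  expect_equal(pk$peak_time, 20)  # tie broken by earliest sample

  # baseline subtraction makes the measurement offset-invariant
  y <- -exp(-(tt - 40)^2 / 4)
  p0 <- measure_peak(y, tt, c(30, 60), "inward", baseline_window = c(0, 10))
  p5 <- measure_peak(y + 5, tt, c(30, 60), "inward",
                     baseline_window = c(0, 10))
  expect_equal(p0$peak_value, p5$peak_value, tolerance = 1e-12)
  expect_equal(p0$peak_time, 40, tolerance = 0.1)

  expect_error(measure_peak(y, tt, c(200, 300), "inward"), "empty")
})

test_that("peak extraction against a dense-grid oracle on a Markov sweep", {
  proto <- build_protocol("nav_standard", list(n_sweeps = 1))
  ss <- simulate_markov_trace(nav_markov_params(), proto, dt = 0.02)
  tms <- sweep_times(ss)
  pk <- measure_peak(ss$sweeps[1, ], tms, c(40, 80), "inward")
  oracle_idx <- which.min(ss$sweeps[1, tms >= 40 & tms <= 80])
  oracle_t <- tms[tms >= 40 & tms <= 80][oracle_idx]
  expect_equal(pk$peak_time, oracle_t)
  expect_lt(pk$peak_value, 0)
})

test_that("two sweeps with a constructed 0.6953 peak ratio measure exactly", {
  tt <- seq(0, 50, by = 0.02)
  shape <- -(tt >= 10) * exp(-(tt - 10) / 2.36) * pmin((tt - 10) / 0.3, 1)
  s <- sweep_set(rbind(shape, 0.3047 * shape), sample_interval = 0.02)
  pks <- measure_peaks(s, c(5, 40), "inward")
  expect_equal(pks$peak_value[2] / pks$peak_value[1], 0.3047,
               tolerance = 0.001 / 0.6953)
})

test_that("monoexponential fits recover clean and noisy decay constants", {
  tt <- seq(0, 20, by = 0.02)
  y <- -500 * exp(-tt / 2.36) + 3
  fit <- fit_monoexp(y, tt, c(0, 20))
  expect_true(fit$converged)
  expect_equal(fit$tau, 2.36, tolerance = 0.01 / 2.36)
  expect_equal(fit$offset, 3, tolerance = 1e-3)

  # SNR ~ 20 Monte-Carlo: small bias of the tau estimator
  taus <- vapply(1:60, function(s) {
    set.seed(s)
    yn <- y + stats::rnorm(length(y), sd = 25)
    fit_monoexp(yn, tt, c(0, 20))$tau
  }, numeric(1))
  expect_lt(abs(mean(taus) / 2.36 - 1), 0.02)

  expect_error(fit_monoexp(y[1:5], tt[1:5], c(0, 0.08)), "at least 10")
})

test_that("Boltzmann fits recover parameters, midpoints and paired shifts", {
  v <- seq(-80, 20, by = 5)
  act <- 1 / (1 + exp((-40 - v) / 5))
  fit <- fit_boltzmann(v, act, "activation")
  expect_equal(fit$v_half, -40, tolerance = 1e-6)
  expect_equal(fit$k, 5, tolerance = 1e-6)

  # half-maximal response pins v_half to within half the grid spacing
  near <- v[which.min(abs(act - 0.5))]
  expect_lt(abs(fit$v_half - near), 2.5)

  inact <- 1 / (1 + exp((v - (-65)) / 6))
  ifit <- fit_boltzmann(v, inact, "inactivation")
  expect_equal(ifit$v_half, -65, tolerance = 1e-6)

  # paired control/drug curves with a known -12 mV shift
  set.seed(11)
  ctrl <- 1 / (1 + exp((-40 - v) / 5)) + stats::rnorm(length(v), sd = 0.01)
  drug <- 1 / (1 + exp((-52 - v) / 5)) + stats::rnorm(length(v), sd = 0.01)
  shift <- fit_boltzmann(v, drug)$v_half - fit_boltzmann(v, ctrl)$v_half
  expect_equal(shift, -12, tolerance = 0.5 / 12)
})

test_that("conductance normalization linearizes an activation family", {
  v <- seq(-40, 30, by = 5)
  g_true <- 1 / (1 + exp((-15 - v) / 6))
  peaks <- g_true * (v - 65)
  g <- conductance_normalize(peaks, v, e_rev = 65)
  expect_equal(g, g_true / max(g_true), tolerance = 1e-12)
})

test_that("AP metrics reproduce constructed trapezoid geometry", {
  ap <- trapezoid_ap(rp = -85, peak = 40, t_stim = 50, upstroke_ms = 2,
                     plateau_ms = 200, repol_ms = 100)
  m <- ap_metrics(ap$v, ap$time, stimulus_times = 50)
  expect_true(m$captured)
  expect_equal(m$RP, -85, tolerance = 1e-9)
  expect_equal(m$peak, 40, tolerance = 1e-9)
  # takeoff on the linear upstroke; 90% crossing on the linear repolarization
  expected_apd <- (50 + 2 + 200 + 0.9 * 100) - m$takeoff
  expect_equal(m$APD90, expected_apd, tolerance = 0.01)

  # faster repolarization strictly shortens APD90
  fast <- trapezoid_ap(repol_ms = 50)
  slow <- trapezoid_ap(repol_ms = 150)
  expect_lt(ap_metrics(fast$v, fast$time, 50)$APD90,
            ap_metrics(slow$v, slow$time, 50)$APD90)

  # doubling the time resolution moves APD90 by well under 1 ms
  hi <- trapezoid_ap(dt = 0.05)
  expect_lt(abs(ap_metrics(hi$v, hi$time, 50)$APD90 - m$APD90), 1)
})

test_that("sub-threshold responses are reported as not captured", {
  tt <- seq(0, 500, by = 0.5)
  v <- -80 + 10 * exp(-(tt - 50)^2 / 100) * (tt > 45)
  m <- ap_metrics(v, tt, stimulus_times = 50)
  expect_false(m$captured)
  expect_true(is.na(m$APD90))
})
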