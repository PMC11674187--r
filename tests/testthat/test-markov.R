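# The Markov Nav simulator is the ground-truth generator every estimator is
# validated against, so its own invariants are checked tightly here.

test_that("occupancies stay normalized and positive across protocols", {
  par_drug <- nav_markov_params(k_ob = 0.00215, k_ob_inv = 0.189,
                                k_ib = 0.0006698, k_ib_inv = 0.18252,
                                conc = 200)
  for (proto in list(build_protocol("nav_standard", list(n_sweeps = 2)),
                     build_protocol("nav_udb"),
                     build_protocol("hold_only"))) {
    ss <- simulate_markov_trace(par_drug, proto, dt = 0.05)
    occ <- attr(ss, "occupancy")
    expect_true(all(occ >= 0 & occ <= 1))
    expect_true(all(abs(colSums(occ) - 1) < 1e-8))
  }
})

test_that("zero conductance and zero block rates are exact no-ops", {
  proto <- build_protocol("nav_standard", list(n_sweeps = 1))
  z <- simulate_markov_trace(nav_markov_params(g_max = 0), proto, dt = 0.05)
  expect_true(all(z$sweeps == 0))

  p0 <- nav_markov_params(conc = 0, k_ob = 0, k_ib = 0)
  p10 <- nav_markov_params(conc = 10, k_ob = 0, k_ib = 0)
  s0 <- simulate_markov_trace(p0, proto, dt = 0.05)
  s10 <- simulate_markov_trace(p10, proto, dt = 0.05)
  expect_identical(s0$sweeps, s10$sweeps)
})

test_that("peak current is inward and linear in g_max", {
  proto <- build_protocol("nav_standard", list(n_sweeps = 1))
  s1 <- simulate_markov_trace(nav_markov_params(g_max = 5), proto, dt = 0.05)
  s2 <- simulate_markov_trace(nav_markov_params(g_max = 10), proto, dt = 0.05)
  pk1 <- min(s1$sweeps)
  pk2 <- min(s2$sweeps)
  expect_lt(pk1, 0)
  expect_equal(pk2 / pk1, 2, tolerance = 1e-9)
})

test_that("depolarization-step decay carries the programmed tau_i", {
  tau_i <- 2.47
  proto <- build_protocol("nav_standard", list(n_sweeps = 1))
  ss <- simulate_markov_trace(nav_markov_params(tau_i = tau_i), proto,
                              dt = 0.02)
  tms <- sweep_times(ss)
  # decay window: after the peak of the -10 mV step (step starts at 40 ms)
  pk <- measure_peak(ss$sweeps[1, ], tms, c(40, 80), "inward")
  idx <- tms >= pk$peak_time + 0.5 & tms <= 78
  # independent oracle: plain nls on the generated decay
  d <- data.frame(t = tms[idx] - pk$peak_time, y = ss$sweeps[1, idx])
  fit <- stats::nls(y ~ A * exp(-t / tau), data = d,
                    start = list(A = min(d$y), tau = 2))
  expect_equal(unname(stats::coef(fit)["tau"]), tau_i, tolerance = 0.02)
})

test_that("drug-free pulse trains follow the two-state recurrence within 3%", {
  tau_i <- 2.47; tau_r <- 3.81
  proto <- build_protocol("nav_udb")
  ss <- simulate_markov_trace(nav_markov_params(tau_i = tau_i, tau_r = tau_r),
                              proto, dt = 0.05)
  o <- udb_peaks_from_sweeps(ss, proto, 0.05)
  expected <- recurrence_peaks(proto$pulse_duration,
                               proto$variable_interpulse, tau_i, tau_r)
  # the single-interval recurrence is exact for the first decrement; for
  # later pulses it ignores carry-over of earlier inactivation, so full
  # sequences are compared only where recovery is near-complete between
  # pulses (t_r >= 20 ms)
  expect_true(all(abs(o[, 2] / expected[, 2] - 1) < 0.005))
  long <- proto$variable_interpulse >= 20
  expect_true(all(abs(o[long, ] / expected[long, ] - 1) < 0.03))
})

test_that("recording noise is reproducible, unbiased and side-effect free", {
  proto <- build_protocol("hold_only")
  base <- simulate_markov_trace(nav_markov_params(), proto, dt = 1)
  expect_identical(add_noise(base, noise_spec(sd = 0)), base)

  n1 <- add_noise(base, noise_spec(sd = 5, seed = 42))
  n2 <- add_noise(base, noise_spec(sd = 5, seed = 42))
  expect_identical(n1$sweeps, n2$sweeps)
  expect_false(identical(n1$sweeps, base$sweeps))

  zero <- sweep_set(matrix(0, 1, 1e5), sample_interval = 0.01)
  noisy <- add_noise(zero, noise_spec(sd = 5, seed = 7))
  expect_equal(stats::sd(noisy$sweeps[1, ]), 5, tolerance = 0.03)
})

test_that("coarse time steps are rejected, invalid rates refused", {
  proto <- build_protocol("nav_udb")
  expect_error(simulate_markov_trace(nav_markov_params(), proto, dt = 1),
               "too coarse")
  expect_error(nav_markov_params(k_ob = -1), ">= 0")
  expect_error(nav_markov_params(tau_i = 0), "> 0")
})
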