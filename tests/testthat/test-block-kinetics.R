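test_that("recovery-tau recurrence inverts its defining construction exactly", {
  t_d <- 10; tau_i <- 2.47; tau_star <- 3.81
  t_r <- seq(5, 50, by = 5)
  o <- recurrence_peaks(t_d, t_r, tau_i, tau_star)
  udb <- udb_measurement(o, t_d, t_r, "control")
  est <- recovery_tau(udb, tau_i, pulses = "all")
  expect_equal(est$per_interval$tau, rep(tau_star, nrow(est$per_interval)),
               tolerance = 1e-12)
  expect_equal(est$pooled, tau_star, tolerance = 1e-12)
  expect_equal(est$n_excluded, 0L)
})

test_that("zero-recovery boundary ratios are excluded, all-excluded errors", {
  t_d <- 10; tau_i <- 2.47
  r_boundary <- exp(-t_d / tau_i)  # infinite-tau_r limit
  o <- cbind(1, r_boundary)
  udb <- udb_measurement(o, t_d, t_r = 20, "control")
  expect_error(suppressWarnings(recovery_tau(udb, tau_i)), "non-estimable")
  expect_warning(try(recovery_tau(udb, tau_i), silent = TRUE), "excluded")
})

test_that("open-block time constants follow the reciprocal-rate algebra", {
  expect_equal(tau_ob_from_decay(2.23, 2.36), 40.5, tolerance = 0.002)
  expect_equal(tau_ob_from_decay(1, 2), 2)
  expect_error(tau_ob_from_decay(2.36, 2.36), "no resolvable")

  expect_equal(open_rate_sum(0.64, 1.07), 1 / 0.64 - 1 / 1.07)
  expect_equal(open_rate_sum(1.5, 1.5), 0)
  expect_error(open_rate_sum(2, 1), "no resolvable")
})

test_that("inactivated-block recurrence inverts its defining construction", {
  t_d <- 10; tau_i <- 2.47; tau_ob <- 40.5; tau_r <- 3.81; tau_ib <- 4.03
  t_r <- seq(5, 50, by = 5)
  lim <- 1 - exp(-t_d * (1 / tau_i + 1 / tau_ob))
  r <- 1 - lim * exp(-t_r * (1 / tau_r - 1 / tau_ib))
  o <- cbind(1, r)
  udb <- udb_measurement(o, t_d, t_r, "drug")
  est <- inactivated_block_tau(udb, tau_i, tau_ob, tau_r)
  expect_equal(est$per_interval$tau, rep(tau_ib, length(t_r)),
               tolerance = 1e-12)
  expect_equal(est$pooled, tau_ib, tolerance = 1e-12)
})

test_that("drug-free sequences give no estimable inactivated-block constant", {
  t_d <- 10; tau_i <- 2.47; tau_r <- 3.81
  t_r <- seq(5, 50, by = 5)
  # control-like ratios: recovery exactly at the control rate -> 1/tau_ib ~ 0
  o <- recurrence_peaks(t_d, t_r, tau_i, tau_r)
  udb <- udb_measurement(o, t_d, t_r, "drug")
  # with tau_ob -> Inf the bracketed term equals the control recurrence, so
  # 1/tau_ib is zero up to round-off: either flagged non-estimable or an
  # astronomically slow (physically absent) block
  res <- tryCatch(suppressWarnings(
    inactivated_block_tau(udb, tau_i, tau_ob = 1e12, tau_r = tau_r)),
    error = function(e) e)
  if (inherits(res, "error")) expect_match(conditionMessage(res), "non-estimable")
  else expect_gt(res$pooled, 1e6)
})

test_that("dissociation-constant transfer reproduces the reference ratio", {
  lid <- lidocaine_reference()
  expect_equal(lid$kd_o, 2.4744, tolerance = 1e-4)
  expect_equal(lid$kd_i, 7.6825, tolerance = 1e-4)
  expect_equal(lid$kd_ratio, 3.1048, tolerance = 1e-4)
  expect_equal(transfer_kd_ratio(2.4744, 7.6825, 87.77), 272.5083,
               tolerance = 1e-3 / 272.5)
  expect_equal(transfer_kd_ratio(5, 5, 42), 42)
})

test_that("rate pairs satisfy both defining equations to machine precision", {
  cases <- list(c(0.62, 200, 87.77), c(0.2484, 98.44, 272.5083),
                c(1.3, 10, 5))
  for (cs in cases) {
    p <- rates_from_sum_and_kd(cs[1], cs[2], cs[3])
    expect_equal(p$k * cs[2] + p$k_inv, cs[1], tolerance = 1e-12)
    expect_equal(p$k_inv / p$k, cs[3], tolerance = 1e-12)
  }
  # published worked pairs
  open <- rates_from_sum_and_kd(0.62, 200, 87.77)
  expect_equal(open$k, 0.00215, tolerance = 0.5e-4 / 0.00215)
  expect_equal(open$k_inv, 0.189, tolerance = 1e-3 / 0.189)
  inact <- rates_from_sum_and_kd(0.2484, 98.44, 272.5083)
  expect_equal(inact$k_inv, 0.1825, tolerance = 1e-3 / 0.1825)
  expect_equal(inact$k, 0.00067, tolerance = 1e-5 / 0.00067)
  # no-drug limit
  expect_equal(rates_from_sum_and_kd(0.5, 0, 10)$k_inv, 0.5)
})

test_that("fixture tables carry the published rows and exclusion flags", {
  t1 <- fixture_table("udb_tau")
  expect_equal(nrow(t1), 4)
  expect_equal(mean(t1$tau_i), 2.47, tolerance = 0.006 / 2.47)
  expect_equal(mean(t1$tau_r), 3.81, tolerance = 0.006 / 3.81)
  expect_equal(mean(t1$tau_ib_est), 4.03, tolerance = 0.006 / 4.03)
  expect_equal(stats::sd(t1$tau_ib_est), 0.70, tolerance = 0.006 / 0.70)

  t2 <- fixture_table("decay_tau")
  expect_true(is.logical(t2$excluded))
  expect_equal(sum(t2$excluded), 1)
  drug <- t2[t2$condition == "cenobamate" & !t2$excluded, ]
  expect_equal(nrow(drug), 5)
  expect_equal(mean(drug$tau_after), 0.64, tolerance = 1e-9)
  veh <- t2[t2$condition == "vehicle", ]
  expect_equal(mean(veh$tau_initial), 2.15, tolerance = 0.007 / 2.15)
})

test_that("per-experiment recomputation matches the published estimates", {
  # each published tau_ib row is consistent with its own tau_i/tau_r/tau_i+ob
  # through the recurrence chain when the first-decrement ratio is the one
  # implied by the published tau_ib itself (internal consistency check)
  t1 <- fixture_table("udb_tau")
  t1 <- t1[t1$tau_i_ob < t1$tau_i, ]   # rows with resolvable open block
  for (i in seq_len(nrow(t1))) {
    tau_ob <- tau_ob_from_decay(t1$tau_i_ob[i], t1$tau_i[i])
    lim <- 1 - exp(-10 * (1 / t1$tau_i[i] + 1 / tau_ob))
    r <- 1 - lim * exp(-20 * (1 / t1$tau_r[i] - 1 / t1$tau_ib_est[i]))
    udb <- udb_measurement(cbind(1, r), 10, 20, "drug")
    est <- inactivated_block_tau(udb, t1$tau_i[i], tau_ob, t1$tau_r[i])
    expect_equal(est$pooled, t1$tau_ib_est[i], tolerance = 1e-10)
  }
})
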