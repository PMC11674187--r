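test_that("registered protocols resolve with the published step layout", {
  p <- build_protocol("nav_standard")
  roles <- vapply(p$segments, `[[`, character(1), "role")
  act <- p$segments[[which(roles == "activation")]]
  expect_equal(act$level, -10)
  expect_equal(act$duration, 40)
  seal <- p$segments[[which(roles == "seal-test")]]
  expect_equal(seal$level, -110)
  expect_equal(seal$duration, 20)
  expect_equal(p$segments[[1]]$level, -90)
  expect_equal(p$inter_sweep_interval, 1)

  udb <- build_protocol("nav_udb")
  expect_equal(udb$variable_interpulse, seq(5, 50, by = 5))
  expect_equal(udb$n_sweeps, 10)
  expect_equal(udb$pulse_duration, 10)
  expect_equal(udb$n_pulses, 5)
  hold <- vapply(udb$segments, `[[`, character(1), "role")
  expect_equal(udb$segments[[which(hold == "holding")[1]]]$level, -120)

  expect_setequal(
    c("nav_standard", "nav_activation", "nav_inactivation", "nav_udb",
      "cipa_late_ina", "cav_pharm", "cav_actinact", "kv71_two_step",
      "herg_two_step", "hipsc_pacing", "double_ramp", "hold_only"),
    protocol_names())
})

test_that("degenerate single-segment protocol and overrides behave", {
  h <- build_protocol("hold_only", list(level = -90, duration = 100))
  expect_length(h$segments, 1)
  expect_equal(h$n_sweeps, 1)
  expect_equal(h$segments[[1]]$duration, 100)

  over <- build_protocol("nav_udb", list(t_d = 20))
  expect_equal(over$pulse_duration, 20)

  expect_error(build_protocol("no_such_protocol"), "unknown protocol")
  expect_error(build_protocol("nav_standard", list(bogus = 1)),
               "no parameter")
  expect_error(protocol_segment(-10, 0), "positive")
  expect_error(voltage_protocol("x", list(protocol_segment(-90, 10)),
                                n_sweeps = 2, variable_interpulse = c(5)),
               "one entry per sweep")
})

test_that("waveform expansion applies increments and pulse trains", {
  p <- build_protocol("nav_activation")
  wf3 <- protocol_waveform(p, sweep = 3, dt = 0.1)
  act_lv <- wf3$segments$level[wf3$segments$role == "activation"]
  expect_equal(act_lv, -80 + 2 * 5)

  udb <- build_protocol("nav_udb")
  wf2 <- protocol_waveform(udb, sweep = 2, dt = 0.1)
  expect_equal(sum(wf2$segments$role == "activation"), 5)
  recov <- wf2$segments[wf2$segments$role == "recovery", ]
  expect_equal(recov$duration[1:4], rep(10, 4))  # t_r of sweep 2
  expect_equal(unique(recov$level[1:4]), -120)

  ramp <- build_protocol("double_ramp")
  wfr <- protocol_waveform(ramp, sweep = 1, dt = 1)
  expect_equal(range(wfr$command), c(-120, 80), tolerance = 0.01)
})
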