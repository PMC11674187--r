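test_that("conduction velocity follows the activation-map geometry", {
  # uniform 1 ms/cell at 100 um spacing = 10 cm/s
  m <- activation_map(seq_len(50) * 1.0, cell_length_um = 100)
  expect_equal(conduction_velocity(m), 10, tolerance = 1e-9)

  # regression estimate consistent with the two-point estimate on a
  # noiseless uniform map
  m2 <- activation_map(5 + seq_len(50) * 0.37)
  two_point <- (m2$position_um[40] - m2$position_um[10]) * 1e-4 /
    (m2$activation_ms[40] - m2$activation_ms[10]) * 1e3
  expect_equal(conduction_velocity(m2), two_point, tolerance = 0.02)

  # a blocked cell inside the regression window -> undefined cv
  act <- seq_len(50) * 1.0
  act[25] <- NA
  expect_true(is.na(conduction_velocity(activation_map(act))))

  expect_error(conduction_velocity(activation_map(c(1, 2)), cells = 10:40),
               ">= 2 interior")
})

test_that("minimum reentry circuit length is the wavelength product", {
  expect_equal(reentry_min_length(300, 2), 6)
  expect_equal(reentry_min_length(300, 20), 60)
  expect_equal(reentry_min_length(150, 2), 3)
  expect_error(reentry_min_length(-1, 2), "> 0")
  expect_error(reentry_min_length(300, 0), "> 0")
})

test_that("strand configuration validates coupling and size", {
  expect_error(strand_config(n_cells = 1), "n_cells")
  expect_error(strand_config(g_j = -5), "g_j")
  expect_error(strand_config(n_cells = 10, g_j = c(100, 200)),
               "per interface")
  cfg <- strand_config(n_cells = 10, g_j = rep(1000, 9))
  expect_length(cfg$g_j, 9)
})

test_that("a well-coupled short strand propagates in order from the stimulus", {
  p <- ord_params("endo", "cipa")
  pre <- cached("endo_cipa_pre10",
                paced_run(p, NULL, 0, pacing_spec(n_prepace = 10,
                                                  n_record = 1),
                          record_dt = 1))
  cfg <- strand_config(n_cells = 12, g_j = 6000,
                       pacing = pacing_spec(n_prepace = 0, n_record = 1,
                                            cycle_length = 600,
                                            stim_dur = 2))
  r <- simulate_strand(cfg, p, prepaced_state = pre$state)
  expect_false(r$block)
  expect_true(all(r$captured))
  expect_true(all(diff(r$activation_time) > 0))
  expect_equal(dim(r$V), c(length(r$time), 12))
  # all cells reach a full AP overshoot
  expect_true(all(apply(r$V, 2, max) > 0))
})

test_that("weaker coupling slows conduction in the same short strand", {
  p <- ord_params("endo", "cipa")
  pre <- cached("endo_cipa_pre10",
                paced_run(p, NULL, 0, pacing_spec(n_prepace = 10,
                                                  n_record = 1),
                          record_dt = 1))
  delays <- vapply(c(600, 6000), function(gj) {
    cfg <- strand_config(n_cells = 12, g_j = gj,
                         pacing = pacing_spec(n_prepace = 0, n_record = 1,
                                              cycle_length = 600,
                                              stim_dur = 2))
    r <- simulate_strand(cfg, p, prepaced_state = pre$state)
    r$activation_time[12] - r$activation_time[1]
  }, numeric(1))
  expect_gt(delays[1], delays[2])
})
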