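# Short paced runs (few beats) cover the structural invariants here; the
# quantitative APD90 / steady-state reproductions run in test-acceptance.R.

short_pacing <- function(n_pre = 3, n_rec = 1)
  pacing_spec(n_prepace = n_pre, n_record = n_rec)

test_that("blocked-state derivative follows the two-conformation balance", {
  drug <- cenobamate_model()
  st <- list(m = 0.9, h = 0.4, j = 0.5, hp = 0.3, jp = 0.45,
             f_inap = 0.1, b = 0)
  expect_equal(db_dt(st, drug, 0), 0)

  # algebraic fixed point: db/dt = 0 exactly at b = on/(on+off)
  conc <- 170
  m3 <- st$m^3
  avail <- (1 - st$f_inap) * st$h * st$j + st$f_inap * st$hp * st$jp
  on <- (m3 * avail * drug$k_ob + m3 * (1 - avail) * drug$k_ib) * conc
  off <- m3 * avail * drug$k_ob_inv + m3 * (1 - avail) * drug$k_ib_inv
  st$b <- on / (on + off)
  expect_lt(abs(db_dt(st, drug, conc)), 1e-10)

  # equal open/inactivated rates collapse to the single-site m^3 form
  sym <- drug_model("sym", drug$channels, k_ob = 0.002, k_ob_inv = 0.1,
                    k_ib = 0.002, k_ib_inv = 0.1, c_max = 170)
  st$b <- 0.2
  expected <- st$m^3 * (0.002 * conc * (1 - st$b) - 0.1 * st$b)
  expect_equal(db_dt(st, sym, conc), expected, tolerance = 1e-12)
})

test_that("fast Na+ current scales linearly in the unblocked fraction", {
  st <- list(v = -20, e_na = 70, m = 0.95, h = 0.1, j = 0.2, hp = 0.05,
             jp = 0.15, f_inap = 0.2, b = 0)
  i0 <- i_na(st)
  st$b <- 1
  expect_equal(i_na(st), 0)
  st$b <- 0.5
  expect_equal(i_na(st), i0 / 2, tolerance = 1e-12)
})

test_that("static drug scaling uses the Hill factors exactly", {
  p <- ord_params("endo")
  drug <- cenobamate_model()
  none <- apply_drug(p, drug, 0)
  expect_equal(none$mult, p$mult)

  ic_cal <- 509.75
  at_ic <- apply_drug(p, drug, ic_cal)
  expect_equal(unname(at_ic$mult["PCa"]), 0.5, tolerance = 1e-12)

  cmax <- apply_drug(p, drug, 170)
  expect_equal(unname(cmax$mult["GNaL"]), 1 / (1 + 170 / 46.5),
               tolerance = 1e-12)
  expect_equal(unname(cmax$mult["GKr"]), 1 / (1 + 170 / 1869),
               tolerance = 1e-12)
  # fast INa is never statically scaled: handled by the b state
  expect_equal(unname(cmax$mult["GNa"]), 1)
  expect_equal(unname(cmax$nav_block["conc"]), 170)

  free <- apply_drug(p, drug, 170, use_free_fraction = TRUE)
  expect_equal(unname(free$nav_block["conc"]), 68)
})

test_that("zero concentration is bitwise identical to the no-drug path", {
  p <- ord_params("endo")
  r_none <- cached("endo_nodrug_short",
                   paced_run(p, NULL, 0, short_pacing()))
  r_zero <- paced_run(p, cenobamate_model(), 0, short_pacing())
  expect_identical(r_zero$V, r_none$V)
  expect_identical(r_zero$apd90, r_none$apd90)
  expect_identical(r_zero$state, r_none$state)
  # and deterministic across repeated runs
  r_again <- paced_run(p, NULL, 0, short_pacing())
  expect_identical(r_again$V, r_none$V)
})

test_that("blocked fraction stays in [0,1] with drug and washes out without", {
  p <- ord_params("endo")
  drug <- cenobamate_model()
  r <- cached("endo_cmax_short", paced_run(p, drug, 170, short_pacing()))
  expect_true(all(r$b >= 0 & r$b <= 1))
  expect_gt(max(r$b), 0.05)   # block actually develops at C_max

  # washout: start from the blocked state, drop concentration to zero
  r0 <- paced_run(p, drug, 0, short_pacing(n_pre = 9, n_rec = 1),
                  init = r$state)
  expect_lt(tail(r0$b, 1), 1e-6)
})

test_that("drug shortens the AP and suppresses the upstroke", {
  r_none <- cached("endo_nodrug_short",
                   paced_run(ord_params("endo"), NULL, 0, short_pacing()))
  r_drug <- cached("endo_cmax_short",
                   paced_run(ord_params("endo"), cenobamate_model(), 170,
                             short_pacing()))
  expect_lt(tail(r_drug$apd90, 1), tail(r_none$apd90, 1))
  expect_lt(tail(r_drug$dvdt_max, 1), tail(r_none$dvdt_max, 1))
})

test_that("AP metrics from the recorded trace agree with the tracker", {
  r <- cached("endo_nodrug_short",
              paced_run(ord_params("endo"), NULL, 0, short_pacing()))
  stim_t <- max(r$time) - r$pacing$cycle_length
  m <- ap_metrics(r$V, r$time, stimulus_times = stim_t)
  expect_true(m$captured)
  expect_equal(m$APD90, tail(r$apd90, 1), tolerance = 1.5 / 300)
  expect_lt(m$RP, -80)
})

test_that("net-charge bookkeeping sums its components and matches refinement", {
  r <- cached("endo_nodrug_short",
              paced_run(ord_params("endo"), NULL, 0, short_pacing()))
  q <- qnet(r)
  expect_equal(q$qnet, sum(q$components), tolerance = 1e-9)

  # identical dynamics sampled 5x finer: quadrature agrees closely
  r_fine <- paced_run(ord_params("endo"), NULL, 0, short_pacing(),
                      record_dt = 0.01)
  expect_lt(abs(qnet(r_fine)$qnet - q$qnet), 1e-3)

  # all-zero currents integrate to zero
  rz <- r
  rz$currents[] <- 0
  expect_equal(qnet(rz)$qnet, 0)
})

test_that("cell-type and variant parameter sets are wired through", {
  expect_equal(ord_params("mid")$cell_type, 2L)
  expect_equal(ord_params(1)$cell_type_name, "epi")
  ci <- ord_params("endo", "cipa")
  expect_equal(unname(ci$mult["GNaL"]), 2.661)
  expect_equal(unname(ci$mult["GK1"]), 1.698)
  expect_error(ord_params("endo", "bogus"))
})
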