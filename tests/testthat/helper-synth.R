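# Shared synthetic-data helpers and a per-session cache for the expensive
# myocyte runs (several test files probe the same paced configurations).

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.run_cache[[key]])) .run_cache[[key]] <- force(expr)
  .run_cache[[key]]
}

# Peak-sequence matrix constructed directly from the two-state use-dependent
# recurrence o_n = o_{n-1} * (1 - (1 - exp(-t_d/tau_i)) * exp(-t_r/tau_r)).
recurrence_peaks <- function(t_d, t_r, tau_i, tau_r, n_pulses = 5) {
  fac <- 1 - (1 - exp(-t_d / tau_i)) * exp(-t_r / tau_r)
  t(vapply(fac, function(f) f^(0:(n_pulses - 1)), numeric(n_pulses)))
}

# Normalized per-pulse peak sequence measured from a Markov-simulated
# use-dependent block sweep set.
udb_peaks_from_sweeps <- function(ss, protocol, dt) {
  n_pulses <- protocol$n_pulses
  t_d <- protocol$pulse_duration
  hold_ms <- protocol$segments[[1]]$duration
  peaks <- matrix(NA_real_, protocol$n_sweeps, n_pulses)
  tms <- sweep_times(ss)
  for (sw in seq_len(protocol$n_sweeps)) {
    t_r <- protocol$variable_interpulse[sw]
    for (p in seq_len(n_pulses)) {
      t0 <- hold_ms + (p - 1) * (t_d + t_r)
      pk <- measure_peak(ss$sweeps[sw, ], tms, c(t0, t0 + t_d), "inward")
      peaks[sw, p] <- -pk$peak_value
    }
  }
  peaks / peaks[, 1]
}

# Idealized trapezoidal action potential: resting level, linear upstroke,
# flat plateau, linear repolarization. Geometry is fully known.
trapezoid_ap <- function(rp = -85, peak = 40, t_stim = 50, upstroke_ms = 2,
                         plateau_ms = 200, repol_ms = 100, total_ms = 600,
                         dt = 0.1) {
  tt <- seq(0, total_ms, by = dt)
  v <- rep(rp, length(tt))
  t_up0 <- t_stim
  t_up1 <- t_stim + upstroke_ms
  t_pl1 <- t_up1 + plateau_ms
  t_rp1 <- t_pl1 + repol_ms
  ramp_up <- tt >= t_up0 & tt < t_up1
  v[ramp_up] <- rp + (peak - rp) * (tt[ramp_up] - t_up0) / upstroke_ms
  v[tt >= t_up1 & tt < t_pl1] <- peak
  ramp_dn <- tt >= t_pl1 & tt < t_rp1
  v[ramp_dn] <- peak - (peak - rp) * (tt[ramp_dn] - t_pl1) / repol_ms
  list(time = tt, v = v,
       # APD90 from end of upstroke (max dV/dt is constant along the ramp;
       # the tracker picks its last improvement at the ramp start) down to
       # the 90% crossing on the linear repolarization limb.
       t_takeoff = t_up0 + dt, t90 = t_pl1 + 0.9 * repol_ms)
}
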