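#' Voltage- and current-clamp protocol segments
#'
#' A `protocol_segment` is one constant-level step or linear ramp of a clamp
#' protocol. Levels are command voltages in mV (or injected current for
#' current-clamp protocols), durations in ms. `per_sweep_increment` shifts the
#' level by a fixed amount in every successive sweep (families of activation /
#' inactivation steps); `role` is a free-text tag used by analysis code to
#' locate baseline and measurement windows.
#'
#' @param level Command level in mV. For a ramp, a length-2 vector
#'   `c(start, end)`.
#' @param duration Segment duration in ms (> 0).
#' @param per_sweep_increment Level shift in mV applied per sweep (default 0).
#' @param role One of `"holding"`, `"seal-test"`, `"activation"`,
#'   `"recovery"`, `"stimulus"` or other free text.
#' @return An object of class `protocol_segment`.
#' @export
protocol_segment <- function(level, duration, per_sweep_increment = 0,
                             role = "holding") {
  if (!is.numeric(level) || !length(level) %in% c(1L, 2L) || !all(is.finite(level)))
    stop("`level` must be one finite voltage or a ramp start/end pair", call. = FALSE)
  if (!is.numeric(duration) || length(duration) != 1L || !is.finite(duration) ||
      duration <= 0)
    stop("`duration` must be a single positive number (ms)", call. = FALSE)
  structure(
    list(level = as.numeric(level), duration = as.numeric(duration),
         per_sweep_increment = as.numeric(per_sweep_increment),
         role = as.character(role)),
    class = "protocol_segment"
  )
}

is_ramp <- function(seg) length(seg$level) == 2L

#' Assemble a voltage/current clamp protocol
#'
#' @param name Protocol identifier.
#' @param segments List of [protocol_segment()]s, played in order each sweep.
#' @param n_sweeps Number of sweeps (>= 1).
#' @param inter_sweep_interval Start-to-start sweep repeat interval in s.
#' @param variable_interpulse Optional numeric vector of per-sweep recovery
#'   intervals t_r in ms (use-dependent block protocols); length must equal
#'   `n_sweeps`.
#' @param pulse_duration Optional depolarized dwell t_d in ms for pulse-train
#'   protocols.
#' @param n_pulses Optional number of depolarizing pulses per sweep for
#'   pulse-train protocols.
#' @param signal Which quantity the segments command: `"voltage"` (clamp) or
#'   `"current"` (current-clamp stimulus waveform).
#' @return An object of class `voltage_protocol`.
#' @export
voltage_protocol <- function(name, segments, n_sweeps = 1L,
                             inter_sweep_interval = 1,
                             variable_interpulse = NULL,
                             pulse_duration = NULL,
                             n_pulses = NULL,
                             signal = c("voltage", "current")) {
  signal <- match.arg(signal)
  if (!all(vapply(segments, inherits, logical(1), "protocol_segment")))
    stop("all segments must be protocol_segment objects", call. = FALSE)
  n_sweeps <- as.integer(n_sweeps)
  if (n_sweeps < 1L) stop("n_sweeps must be >= 1", call. = FALSE)
  if (!is.null(variable_interpulse)) {
    if (length(variable_interpulse) != n_sweeps)
      stop("variable_interpulse must have one entry per sweep", call. = FALSE)
    if (any(variable_interpulse <= 0))
      stop("recovery intervals t_r must be strictly positive", call. = FALSE)
  }
  if (!is.null(pulse_duration) && pulse_duration <= 0)
    stop("pulse duration t_d must be strictly positive", call. = FALSE)
  structure(
    list(name = name, segments = segments, n_sweeps = n_sweeps,
         inter_sweep_interval = inter_sweep_interval,
         variable_interpulse = variable_interpulse,
         pulse_duration = pulse_duration, n_pulses = n_pulses,
         signal = signal),
    class = "voltage_protocol"
  )
}

#' @export
print.voltage_protocol <- function(x, ...) {
  cat(sprintf("<voltage_protocol> %s: %d segment(s), %d sweep(s)\n",
              x$name, length(x$segments), x$n_sweeps))
  for (s in x$segments) {
    lev <- if (is_ramp(s)) sprintf("%g->%g mV", s$level[1], s$level[2])
           else sprintf("%g mV", s$level[1])
    inc <- if (s$per_sweep_increment != 0)
      sprintf(" (+%g mV/sweep)", s$per_sweep_increment) else ""
    cat(sprintf("  %-11s %s for %g ms%s\n", s$role, lev, s$duration, inc))
  }
  invisible(x)
}

# Registry of the standard whole-cell protocols used throughout: each entry is
# a constructor taking resolved parameter values. Segment levels/durations
# follow the standard manual patch-clamp designs for each channel family.
protocol_registry <- function() {
  seg <- protocol_segment
  list(
    # Nav1.5 standard pharmacology: holding -90, 20 ms seal step at -110,
    # 40 ms activation step at -10 mV, sweeps repeated at 1 s intervals.
    nav_standard = list(
      params = list(holding = -90, seal_level = -110, seal_ms = 20,
                    step_level = -10, step_ms = 40, n_sweeps = 30,
                    interval_s = 1),
      build = function(p) voltage_protocol(
        "nav_standard",
        list(seg(p$holding, 20, role = "holding"),
             seg(p$seal_level, p$seal_ms, role = "seal-test"),
             seg(p$step_level, p$step_ms, role = "activation"),
             seg(p$holding, 20, role = "holding")),
        n_sweeps = p$n_sweeps, inter_sweep_interval = p$interval_s)
    ),
    # Nav activation family: 40 ms steps from -80 to +60 mV in 5 mV increments.
    nav_activation = list(
      params = list(holding = -90, seal_level = -110, seal_ms = 20,
                    from = -80, increment = 5, step_ms = 40, n_sweeps = 29,
                    interval_s = 5),
      build = function(p) voltage_protocol(
        "nav_activation",
        list(seg(p$holding, 20, role = "holding"),
             seg(p$seal_level, p$seal_ms, role = "seal-test"),
             seg(p$from, p$step_ms, per_sweep_increment = p$increment,
                 role = "activation"),
             seg(p$holding, 20, role = "holding")),
        n_sweeps = p$n_sweeps, inter_sweep_interval = p$interval_s)
    ),
    # Nav steady-state inactivation: 1 s conditioning steps from -120 mV,
    # then a 25 ms test step at -30 mV.
    nav_inactivation = list(
      params = list(holding = -120, from = -120, increment = 10,
                    cond_ms = 1000, test_level = -30, test_ms = 25,
                    n_sweeps = 17, interval_s = 5),
      build = function(p) voltage_protocol(
        "nav_inactivation",
        list(seg(p$holding, 20, role = "holding"),
             seg(p$from, p$cond_ms, per_sweep_increment = p$increment,
                 role = "conditioning"),
             seg(p$test_level, p$test_ms, role = "activation"),
             seg(p$holding, 20, role = "holding")),
        n_sweeps = p$n_sweeps, inter_sweep_interval = p$interval_s)
    ),
    # Use-dependent block: holding -120 mV, five 10 ms pulses at -10 mV,
    # interpulse interval growing 5..50 ms in 5 ms increments across sweeps.
    nav_udb = list(
      params = list(holding = -120, pulse_level = -10, t_d = 10,
                    n_pulses = 5, t_r_from = 5, t_r_to = 50, t_r_by = 5,
                    interval_s = 5),
      build = function(p) {
        t_r <- seq(p$t_r_from, p$t_r_to, by = p$t_r_by)
        voltage_protocol(
          "nav_udb",
          list(seg(p$holding, 20, role = "holding"),
               seg(p$pulse_level, p$t_d, role = "activation"),
               seg(p$holding, 50, role = "recovery")),
          n_sweeps = length(t_r), inter_sweep_interval = p$interval_s,
          variable_interpulse = t_r, pulse_duration = p$t_d,
          n_pulses = p$n_pulses)
      }
    ),
    # CiPA-like late-INa protocol (ATX-II experiments): holding -90,
    # preconditioning at -110, long depolarization to read the persistent
    # component, repeat every 8 s.
    cipa_late_ina = list(
      params = list(holding = -90, precond_level = -110, precond_ms = 50,
                    step_level = -10, step_ms = 300, n_sweeps = 10,
                    interval_s = 8),
      build = function(p) voltage_protocol(
        "cipa_late_ina",
        list(seg(p$holding, 20, role = "holding"),
             seg(p$precond_level, p$precond_ms, role = "seal-test"),
             seg(p$step_level, p$step_ms, role = "activation"),
             seg(p$holding, 20, role = "holding")),
        n_sweeps = p$n_sweeps, inter_sweep_interval = p$interval_s)
    ),
    # Cav1.2 pharmacology: holding -80, 100 ms at -50, 200 ms test at 0 mV.
    cav_pharm = list(
      params = list(holding = -80, pre_level = -50, pre_ms = 100,
                    step_level = 0, step_ms = 200, n_sweeps = 20,
                    interval_s = 20),
      build = function(p) voltage_protocol(
        "cav_pharm",
        list(seg(p$holding, 20, role = "holding"),
             seg(p$pre_level, p$pre_ms, role = "seal-test"),
             seg(p$step_level, p$step_ms, role = "activation"),
             seg(p$holding, 20, role = "holding")),
        n_sweeps = p$n_sweeps, inter_sweep_interval = p$interval_s)
    ),
    # Cav activation-inactivation: 1 s steps -80..+50 mV in 10 mV increments
    # followed by a 250 ms test step at +10 mV.
    cav_actinact = list(
      params = list(holding = -80, from = -80, increment = 10, cond_ms = 1000,
                    test_level = 10, test_ms = 250, n_sweeps = 14,
                    interval_s = 20),
      build = function(p) voltage_protocol(
        "cav_actinact",
        list(seg(p$holding, 20, role = "holding"),
             seg(p$from, p$cond_ms, per_sweep_increment = p$increment,
                 role = "conditioning"),
             seg(p$test_level, p$test_ms, role = "activation"),
             seg(p$holding, 20, role = "holding")),
        n_sweeps = p$n_sweeps, inter_sweep_interval = p$interval_s)
    ),
    # Kv7.1+minK two-step: holding -110, 250 ms at -80 with a 50 ms seal dip
    # at -90, 3 s depolarization at +60, 1 s tail at -50 mV.
    kv71_two_step = list(
      params = list(holding = -110, pre_level = -80, dip_level = -90,
                    step_level = 60, step_ms = 3000, tail_level = -50,
                    tail_ms = 1000, n_sweeps = 15, interval_s = 20),
      build = function(p) voltage_protocol(
        "kv71_two_step",
        list(seg(p$holding, 20, role = "holding"),
             seg(p$pre_level, 100, role = "seal-test"),
             seg(p$dip_level, 50, role = "seal-test"),
             seg(p$pre_level, 100, role = "seal-test"),
             seg(p$step_level, p$step_ms, role = "activation"),
             seg(p$tail_level, p$tail_ms, role = "tail"),
             seg(p$holding, 20, role = "holding")),
        n_sweeps = p$n_sweeps, inter_sweep_interval = p$interval_s)
    ),
    # hERG two-step activation: holding -70, 100 ms reference at -50,
    # 2 s at +40, 2 s tail at -50 mV, repeat at 10 s.
    herg_two_step = list(
      params = list(holding = -70, ref_level = -50, ref_ms = 100,
                    step_level = 40, step_ms = 2000, tail_level = -50,
                    tail_ms = 2000, n_sweeps = 15, interval_s = 10),
      build = function(p) voltage_protocol(
        "herg_two_step",
        list(seg(p$holding, 20, role = "holding"),
             seg(p$ref_level, p$ref_ms, role = "seal-test"),
             seg(p$step_level, p$step_ms, role = "activation"),
             seg(p$tail_level, p$tail_ms, role = "tail"),
             seg(p$holding, 20, role = "holding")),
        n_sweeps = p$n_sweeps, inter_sweep_interval = p$interval_s)
    ),
    # hiPSC-CM current-clamp pacing: 3 brief current stimuli at 3 s intervals,
    # first at 500 ms; levels are injected current in nA.
    hipsc_pacing = list(
      params = list(stim_nA = 2, stim_ms = 0.5, n_stim = 3, period_ms = 3000,
                    first_ms = 500, n_sweeps = 1, interval_s = 10),
      build = function(p) {
        segs <- list(seg(0, p$first_ms, role = "holding"))
        for (i in seq_len(p$n_stim)) {
          segs <- c(segs, list(seg(p$stim_nA, p$stim_ms, role = "stimulus")))
          gap <- p$period_ms - p$stim_ms
          if (i == p$n_stim) gap <- 500
          segs <- c(segs, list(seg(0, gap, role = "holding")))
        }
        voltage_protocol("hipsc_pacing", segs, n_sweeps = p$n_sweeps,
                         inter_sweep_interval = p$interval_s,
                         signal = "current")
      }
    ),
    # Double voltage ramp: -120 -> +80 mV in 2 s, then back in 2 s.
    double_ramp = list(
      params = list(holding = -80, low = -120, high = 80, ramp_ms = 2000,
                    n_sweeps = 5, interval_s = 10),
      build = function(p) voltage_protocol(
        "double_ramp",
        list(seg(p$holding, 100, role = "holding"),
             seg(c(p$low, p$high), p$ramp_ms, role = "ramp"),
             seg(c(p$high, p$low), p$ramp_ms, role = "ramp"),
             seg(p$holding, 100, role = "holding")),
        n_sweeps = p$n_sweeps, inter_sweep_interval = p$interval_s)
    ),
    # Degenerate single-segment hold, mostly for tests and baselines.
    hold_only = list(
      params = list(level = -90, duration = 100, n_sweeps = 1, interval_s = 1),
      build = function(p) voltage_protocol(
        "hold_only", list(seg(p$level, p$duration, role = "holding")),
        n_sweeps = p$n_sweeps, inter_sweep_interval = p$interval_s)
    )
  )
}

#' List registered protocol names
#' @return Character vector of protocol identifiers accepted by
#'   [build_protocol()].
#' @export
protocol_names <- function() names(protocol_registry())

#' Build a registered clamp protocol
#'
#' Resolves a named protocol from the built-in library, optionally overriding
#' declared parameters (e.g. the holding level or number of sweeps). Only
#' parameters declared by the entry may be overridden.
#'
#' @param name Protocol identifier; see [protocol_names()].
#' @param overrides Named list of parameter overrides.
#' @return A [voltage_protocol()].
#' @examples
#' build_protocol("nav_standard")
#' build_protocol("nav_udb", list(t_d = 20))
#' @export
build_protocol <- function(name, overrides = list()) {
  reg <- protocol_registry()
  if (!name %in% names(reg))
    stop(sprintf("unknown protocol '%s'; see protocol_names()", name),
         call. = FALSE)
  entry <- reg[[name]]
  bad <- setdiff(names(overrides), names(entry$params))
  if (length(bad))
    stop(sprintf("protocol '%s' has no parameter(s): %s", name,
                 paste(bad, collapse = ", ")), call. = FALSE)
  p <- utils::modifyList(entry$params, overrides)
  entry$build(p)
}

#' Command waveform of one sweep
#'
#' Expands a protocol into the command level sampled at `dt` for a given
#' sweep, applying per-sweep increments and, for pulse-train protocols,
#' the sweep-specific interpulse interval.
#'
#' @param protocol A [voltage_protocol()].
#' @param sweep Sweep index (1-based).
#' @param dt Sample interval in ms.
#' @return A list with `time` (ms) and `command` (mV or nA) vectors, plus
#'   `segments` giving each expanded segment's start index, role and level.
#' @export
protocol_waveform <- function(protocol, sweep = 1L, dt = 0.01) {
  stopifnot(inherits(protocol, "voltage_protocol"))
  if (sweep < 1L || sweep > protocol$n_sweeps)
    stop("sweep index out of range", call. = FALSE)
  segs <- expand_segments(protocol, sweep)
  n_per <- vapply(segs, function(s) max(1L, as.integer(round(s$duration / dt))),
                  integer(1))
  total <- sum(n_per)
  command <- numeric(total)
  starts <- integer(length(segs))
  at <- 1L
  for (i in seq_along(segs)) {
    s <- segs[[i]]
    starts[i] <- at
    idx <- at:(at + n_per[i] - 1L)
    if (is_ramp(s)) {
      frac <- (seq_len(n_per[i]) - 0.5) / n_per[i]
      command[idx] <- s$level[1] + frac * (s$level[2] - s$level[1])
    } else {
      command[idx] <- s$level[1]
    }
    at <- at + n_per[i]
  }
  info <- data.frame(
    start_index = starts,
    start_ms = (starts - 1L) * dt,
    duration = vapply(segs, `[[`, numeric(1), "duration"),
    role = vapply(segs, `[[`, character(1), "role"),
    level = vapply(segs, function(s) s$level[1], numeric(1))
  )
  list(time = (seq_len(total) - 1L) * dt, command = command, segments = info)
}

# Resolve the per-sweep segment list: apply increments; unroll pulse trains
# (protocols with variable_interpulse) into n_pulses pulse/recovery pairs with
# the sweep's t_r.
expand_segments <- function(protocol, sweep) {
  out <- list()
  for (s in protocol$segments) {
    lev <- s$level + s$per_sweep_increment * (sweep - 1L)
    s2 <- s; s2$level <- lev
    if (!is.null(protocol$variable_interpulse) && s$role == "activation") {
      t_r <- protocol$variable_interpulse[sweep]
      n_p <- if (is.null(protocol$n_pulses)) 1L else protocol$n_pulses
      hold_level <- protocol$segments[[1]]$level[1]
      for (k in seq_len(n_p)) {
        out <- c(out, list(s2))
        if (k < n_p)
          out <- c(out, list(protocol_segment(hold_level, t_r,
                                              role = "recovery")))
      }
    } else if (!is.null(protocol$variable_interpulse) && s$role == "recovery") {
      # trailing recovery segment keeps its fixed duration
      out <- c(out, list(s2))
    } else {
      out <- c(out, list(s2))
    }
  }
  out
}
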