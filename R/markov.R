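#' Ground-truth Markov model of Nav1.5 gating with state-specific block
#'
#' Parameters of the five-state scheme C <-> O -> I -> C with drug binding to
#' the open (O <-> OB) and inactivated (I <-> IB) conformations, following the
#' modulated receptor hypothesis: affinity differs by conformation, gating is
#' untouched, closed channels do not bind. Activation kinetics are lumped into
#' a single fast voltage-dependent C <-> O transition; macroscopic inactivation
#' and recovery are governed directly by `tau_i` (at depolarized potentials)
#' and `tau_r` (at hyperpolarized potentials), the two apparent time constants
#' that use-dependent block analysis estimates.
#'
#' @param g_max Maximal conductance scale (nS); current is
#'   `g_max * P(O) * (V - reversal)` in pA.
#' @param reversal Reversal potential in mV (default +65 for Na+).
#' @param tau_i Inactivation time constant at depolarized potentials, ms.
#' @param tau_r Recovery time constant at hyperpolarized potentials, ms.
#' @param k_ob,k_ib Blocking rates for open / inactivated conformations,
#'   in uM^-1 ms^-1.
#' @param k_ob_inv,k_ib_inv Unblocking rates, ms^-1.
#' @param conc Drug concentration `[D]` in uM.
#' @param act_rate Maximal C->O rate (ms^-1); fast relative to `1/tau_i`.
#' @param deact_rate Maximal O->C rate at hyperpolarized potentials (ms^-1).
#' @param v_act,k_act Midpoint (mV) and slope (mV) of the sigmoidal voltage
#'   dependence of activation/deactivation.
#' @param v_rec,k_rec Midpoint and slope of the voltage dependence of
#'   recovery from inactivation.
#' @param ob_ib_exchange If `TRUE`, allow OB <-> IB interconversion mirroring
#'   the gating rates (detailed balance enforced); default off.
#' @return An object of class `nav_markov_params`.
#' @export
nav_markov_params <- function(g_max = 10, reversal = 65,
                              tau_i = 2.47, tau_r = 3.81,
                              k_ob = 0, k_ob_inv = 0,
                              k_ib = 0, k_ib_inv = 0,
                              conc = 0,
                              act_rate = 15, deact_rate = 15,
                              v_act = -45, k_act = 4,
                              v_rec = -70, k_rec = 6,
                              ob_ib_exchange = FALSE) {
  rates <- c(k_ob = k_ob, k_ob_inv = k_ob_inv, k_ib = k_ib,
             k_ib_inv = k_ib_inv, act_rate = act_rate,
             deact_rate = deact_rate, conc = conc, g_max = g_max)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("rates, conductance and concentration must be finite and >= 0",
         call. = FALSE)
  if (tau_i <= 0 || tau_r <= 0)
    stop("tau_i and tau_r must be > 0", call. = FALSE)
  structure(as.list(environment()), class = "nav_markov_params")
}

# State order used throughout: C, O, I, OB, IB.
markov_states <- c("C", "O", "I", "OB", "IB")

sigmoid <- function(x) 1 / (1 + exp(-x))

# Instantaneous generator matrix Q(V) (columns = from-state, dQ/dt = Q p).
markov_generator <- function(p, v) {
  k_co <- p$act_rate * sigmoid((v - p$v_act) / p$k_act)
  k_oc <- p$deact_rate * sigmoid(-(v - p$v_act) / p$k_act)
  k_oi <- 1 / p$tau_i
  k_ic <- (1 / p$tau_r) * sigmoid(-(v - p$v_rec) / p$k_rec)
  on_o <- p$k_ob * p$conc
  on_i <- p$k_ib * p$conc
  Q <- matrix(0, 5, 5, dimnames = list(markov_states, markov_states))
  Q["O", "C"] <- k_co
  Q["C", "O"] <- k_oc
  Q["I", "O"] <- k_oi
  Q["C", "I"] <- k_ic
  Q["OB", "O"] <- on_o;  Q["O", "OB"] <- p$k_ob_inv
  Q["IB", "I"] <- on_i;  Q["I", "IB"] <- p$k_ib_inv
  if (isTRUE(p$ob_ib_exchange) && on_o > 0 && on_i > 0) {
    # mirror gating between the blocked states; detailed balance around the
    # O-I-IB-OB cycle fixes the OB->IB rate given the other three.
    k_ob_ib <- k_oi
    k_ib_ob <- k_ob_ib * (p$k_ib_inv * on_o) / (p$k_ob_inv * on_i)
    Q["IB", "OB"] <- k_ob_ib
    Q["OB", "IB"] <- k_ib_ob
  }
  diag(Q) <- -colSums(Q)
  Q
}

# Equilibrium occupancy at a holding potential, obtained by propagating the
# generator over a long dwell (robust when block states are disconnected,
# e.g. drug-free, where the stationary distribution is not unique and the
# physically relevant limit starts from all-closed channels).
markov_equilibrium <- function(p, v) {
  Q <- markov_generator(p, v)
  horizon <- 50 * max(p$tau_i, p$tau_r, 1)
  P <- pracma::expm(Q * horizon)
  pi <- as.vector(P %*% c(1, 0, 0, 0, 0))
  pi[pi < 0] <- 0
  pi / sum(pi)
}

#' Simulate whole-cell current sweeps from the Markov Nav model
#'
#' Integrates the five-state occupancy along each sweep of a clamp protocol
#' using per-step matrix exponentials of the generator, which preserves
#' positivity and normalization exactly at any step size. For constant-level
#' segments the propagator is computed once per segment; ramps are handled by
#' piecewise-constant voltage at the sample resolution.
#'
#' @param params A [nav_markov_params()].
#' @param protocol A [voltage_protocol()] (voltage signal).
#' @param dt Sample/integration interval in ms. Must resolve the fastest
#'   segment: `dt <= 0.01 * min(segment duration)` is enforced.
#' @param init Initial occupancy; default is the equilibrium at the first
#'   segment's level, reached independently for each sweep (sweeps are assumed
#'   separated by long enough inter-sweep intervals).
#' @return A [sweep_set()] of currents in pA, with attribute `"occupancy"`
#'   holding the final sweep's 5 x n occupancy matrix.
#' @export
simulate_markov_trace <- function(params, protocol, dt = 0.005, init = NULL) {
  stopifnot(inherits(params, "nav_markov_params"),
            inherits(protocol, "voltage_protocol"))
  min_dur <- min(vapply(protocol$segments, `[[`, numeric(1), "duration"))
  if (!is.null(protocol$variable_interpulse))
    min_dur <- min(min_dur, protocol$variable_interpulse)
  if (dt > 0.01 * min_dur + 1e-12)
    stop(sprintf(
      "dt = %g ms too coarse for the shortest segment (%g ms); need dt <= %g",
      dt, min_dur, 0.01 * min_dur), call. = FALSE)

  first_level <- protocol$segments[[1]]$level[1]
  p0 <- if (is.null(init)) markov_equilibrium(params, first_level) else init
  if (abs(sum(p0) - 1) > 1e-8 || any(p0 < -1e-12))
    stop("initial occupancy must be a probability vector", call. = FALSE)

  sweeps <- NULL
  occ_last <- NULL
  prop_cache <- new.env(parent = emptyenv())
  for (sw in seq_len(protocol$n_sweeps)) {
    wf <- protocol_waveform(protocol, sweep = sw, dt = dt)
    n <- length(wf$time)
    occ <- matrix(0, 5, n, dimnames = list(markov_states, NULL))
    pcur <- p0
    v_prev <- NA_real_
    P <- NULL
    for (k in seq_len(n)) {
      v <- wf$command[k]
      if (!identical(v, v_prev)) {
        key <- format(v, digits = 12)
        P <- prop_cache[[key]]
        if (is.null(P)) {
          P <- pracma::expm(markov_generator(params, v) * dt)
          prop_cache[[key]] <- P
        }
        v_prev <- v
      }
      pcur <- as.vector(P %*% pcur)
      # guard against round-off drift
      pcur[pcur < 0] <- 0
      pcur <- pcur / sum(pcur)
      occ[, k] <- pcur
    }
    current <- params$g_max * occ["O", ] * (wf$command - params$reversal)
    if (is.null(sweeps)) sweeps <- matrix(0, protocol$n_sweeps, n)
    sweeps[sw, seq_len(min(n, ncol(sweeps)))] <- current[seq_len(min(n, ncol(sweeps)))]
    if (n != ncol(sweeps)) {
      # pulse-train protocols can differ in length across sweeps; pad with
      # the final holding current (zero open probability at rest).
      if (n < ncol(sweeps)) sweeps[sw, (n + 1):ncol(sweeps)] <- current[n]
      else {
        pad <- matrix(sweeps[, ncol(sweeps)], nrow(sweeps), n - ncol(sweeps))
        sweeps <- cbind(sweeps, pad)
        sweeps[sw, ] <- current
      }
    }
    occ_last <- occ
  }
  out <- sweep_set(sweeps, sample_interval = dt, signal_kind = "current",
                   units = "pA", protocol = protocol$name)
  attr(out, "occupancy") <- occ_last
  out
}

#' Simple Hodgkin-Huxley surrogate sweeps for non-Nav channels
#'
#' Generates idealized whole-cell currents with a single activation gate
#' (power `p_act`) and optional inactivation gate, each relaxing
#' exponentially toward Boltzmann steady states with fixed time constants.
#' Used to emulate Cav/Kv/hERG family recordings for estimator tests; not a
#' mechanistic model of any specific channel.
#'
#' @param protocol A [voltage_protocol()].
#' @param g_max Maximal conductance (nS); current in pA.
#' @param reversal Reversal potential, mV.
#' @param v_half_act,k_act Activation Boltzmann midpoint and slope (mV).
#' @param tau_act Activation time constant, ms.
#' @param p_act Activation gate exponent.
#' @param v_half_inact,k_inact Optional inactivation Boltzmann midpoint and
#'   slope; `NULL` disables inactivation.
#' @param tau_inact Inactivation time constant, ms.
#' @param dt Sample interval, ms.
#' @return A [sweep_set()] of currents in pA.
#' @export
simulate_hh_trace <- function(protocol, g_max = 5, reversal = 0,
                              v_half_act = -10, k_act = 7, tau_act = 5,
                              p_act = 1,
                              v_half_inact = NULL, k_inact = 6,
                              tau_inact = 50, dt = 0.05) {
  stopifnot(inherits(protocol, "voltage_protocol"))
  has_inact <- !is.null(v_half_inact)
  sweeps <- NULL
  for (sw in seq_len(protocol$n_sweeps)) {
    wf <- protocol_waveform(protocol, sweep = sw, dt = dt)
    n <- length(wf$time)
    v0 <- wf$command[1]
    a <- sigmoid((v0 - v_half_act) / k_act)
    h <- if (has_inact) sigmoid(-(v0 - v_half_inact) / k_inact) else 1
    cur <- numeric(n)
    ea <- exp(-dt / tau_act)
    eh <- exp(-dt / tau_inact)
    for (k in seq_len(n)) {
      v <- wf$command[k]
      a_inf <- sigmoid((v - v_half_act) / k_act)
      a <- a_inf + (a - a_inf) * ea
      if (has_inact) {
        h_inf <- sigmoid(-(v - v_half_inact) / k_inact)
        h <- h_inf + (h - h_inf) * eh
      }
      cur[k] <- g_max * a^p_act * h * (v - reversal)
    }
    if (is.null(sweeps)) sweeps <- matrix(0, protocol$n_sweeps, n)
    sweeps[sw, ] <- cur
  }
  sweep_set(sweeps, sample_interval = dt, signal_kind = "current",
            units = "pA", protocol = protocol$name)
}
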