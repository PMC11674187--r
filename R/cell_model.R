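#' Ventricular myocyte model parameter set
#'
#' Selects the transmural cell type and baseline calibration of the
#' O'Hara-Rudy 2011 human ventricular myocyte model. The `"base"` variant is
#' the model as published; `"cipa"` applies the CiPA-lineage conductance
#' recalibration (INaL x2.661, ICaL x1.007, IKr x1.013, IKs x1.87,
#' IK1 x1.698) used by net-charge proarrhythmia work.
#'
#' @param cell_type `"endo"` (0), `"epi"` (1) or `"mid"` (2); integers
#'   accepted.
#' @param variant `"base"` or `"cipa"`.
#' @return An object of class `ord_params` holding the cell type and the
#'   named conductance multipliers applied on top of the published values.
#' @export
ord_params <- function(cell_type = c("endo", "epi", "mid"),
                       variant = c("base", "cipa")) {
  if (is.numeric(cell_type)) {
    stopifnot(cell_type %in% 0:2)
    cell_type <- c("endo", "epi", "mid")[cell_type + 1]
  }
  cell_type <- match.arg(cell_type)
  variant <- match.arg(variant)
  mult <- c(GNa = 1, GNaL = 1, PCa = 1, GKr = 1, GKs = 1, GK1 = 1,
            Gto = 1, Gncx = 1, Pnak = 1)
  if (variant == "cipa") {
    mult["GNaL"] <- 2.661
    mult["PCa"] <- 1.007
    mult["GKr"] <- 1.013
    mult["GKs"] <- 1.87
    mult["GK1"] <- 1.698
  }
  structure(
    list(cell_type = match(cell_type, c("endo", "epi", "mid")) - 1L,
         cell_type_name = cell_type, variant = variant, mult = mult),
    class = "ord_params"
  )
}

#' Pacing specification
#'
#' @param cycle_length Basic cycle length in ms (default 2000, the
#'   net-charge metric convention).
#' @param stim_amp Stimulus amplitude in uA/uF (negative = depolarizing;
#'   default -80).
#' @param stim_dur Stimulus duration in ms.
#' @param n_prepace Pre-pacing beats before recording (default 1000).
#' @param n_record Recorded beats at the end of the train.
#' @return An object of class `pacing_spec`.
#' @export
pacing_spec <- function(cycle_length = 2000, stim_amp = -80, stim_dur = 0.5,
                        n_prepace = 1000, n_record = 2) {
  stopifnot(cycle_length > 0, stim_dur > 0, n_record >= 1)
  structure(
    list(cycle_length = cycle_length, stim_amp = stim_amp,
         stim_dur = stim_dur, n_prepace = as.integer(n_prepace),
         n_record = as.integer(n_record)),
    class = "pacing_spec"
  )
}

#' Apply a drug to the myocyte model
#'
#' Implements the two-tier pharmacology: the late Na+, L-type Ca2+ and
#' delayed-rectifier K+ currents are scaled statically by the Hill factor
#' `1 / (1 + C/IC50)` with their configured potencies, while the fast Na+
#' current is left untouched here and blocked dynamically through the
#' blocked-state variable `b` driven by the drug's state-specific rates.
#'
#' @param params An [ord_params()].
#' @param drug A [drug_model()] or `NULL` for no drug.
#' @param concentration Applied concentration, uM.
#' @param use_free_fraction Multiply the concentration by the drug's free
#'   (unbound) fraction before computing any block (default `FALSE`: nominal
#'   total concentration semantics).
#' @param b_scales_inal Also scale late INa by `(1 - b)` instead of its
#'   static Hill factor (default `FALSE`).
#' @return A list with the scaled `mult` vector and the `nav_block` rate
#'   vector consumed by the integrator.
#' @export
apply_drug <- function(params, drug, concentration,
                       use_free_fraction = FALSE, b_scales_inal = FALSE) {
  stopifnot(inherits(params, "ord_params"))
  mult <- params$mult
  nav <- c(k_ob = 0, k_ob_inv = 0, k_ib = 0, k_ib_inv = 0, conc = 0,
           b_on_inal = as.numeric(b_scales_inal))
  if (!is.null(drug)) {
    stopifnot(inherits(drug, "drug_model"))
    # at zero concentration the unblocking rates stay active (washout of any
    # pre-existing blocked fraction); all Hill scale factors are exactly 1.
    conc <- concentration * if (use_free_fraction) drug$free_fraction else 1
    scale_for <- function(channel)
      1 - fractional_block(conc, channel_ic50(drug, channel)$ic50,
                           channel_ic50(drug, channel)$n_h)
    if (!b_scales_inal) mult["GNaL"] <- mult["GNaL"] * scale_for("INaL")
    mult["PCa"] <- mult["PCa"] * scale_for("ICaL")
    mult["GKr"] <- mult["GKr"] * scale_for("IKr")
    mult["GKs"] <- mult["GKs"] * scale_for("IKs")
    nav <- c(k_ob = drug$k_ob, k_ob_inv = drug$k_ob_inv,
             k_ib = drug$k_ib, k_ib_inv = drug$k_ib_inv, conc = conc,
             b_on_inal = as.numeric(b_scales_inal))
  }
  list(mult = mult, nav_block = nav)
}

#' Blocked-state derivative
#'
#' Rate of change of the Nav1.5 blocked-state occupancy `b` under the
#' modulated receptor hypothesis: binding/unbinding through the open
#' conformation is weighted by the m^3-gated available fraction
#' `m^3 [(1-f_INaP) h j + f_INaP h_p j_p]`, and through the inactivated
#' conformation by its m^3-gated complement.
#'
#' @param state Named list/vector with gates `m`, `h`, `j`, `hp`, `jp`, the
#'   CaMK-phosphorylated fraction `f_inap` and current occupancy `b`.
#' @param drug A [drug_model()].
#' @param concentration Drug concentration, uM.
#' @return `db/dt` in ms^-1.
#' @export
db_dt <- function(state, drug, concentration) {
  m3 <- state$m^3
  avail <- (1 - state$f_inap) * state$h * state$j +
    state$f_inap * state$hp * state$jp
  on <- (m3 * avail * drug$k_ob + m3 * (1 - avail) * drug$k_ib) * concentration
  off <- m3 * avail * drug$k_ob_inv + m3 * (1 - avail) * drug$k_ib_inv
  on * (1 - state$b) - off * state$b
}

#' Fast Na+ current with blocked-state scaling
#'
#' `I_Na = (1-b) G_Na (V-E_Na) m^3 [(1-f_INaP) h j + f_INaP h_p j_p]`.
#'
#' @param state Named list with `v`, `e_na`, gates `m`, `h`, `j`, `hp`,
#'   `jp`, `f_inap` and `b`.
#' @param g_na Maximal fast Na+ conductance, mS/uF (model default 75).
#' @return Current density in uA/uF.
#' @export
i_na <- function(state, g_na = 75) {
  avail <- (1 - state$f_inap) * state$h * state$j +
    state$f_inap * state$hp * state$jp
  (1 - state$b) * g_na * (state$v - state$e_na) * state$m^3 * avail
}

#' Pace a single myocyte to steady state
#'
#' Integrates the drug-extended myocyte model with fixed-step Rush-Larsen /
#' forward-Euler updates, recording the final beats. Determinism: the solver
#' is exact-arithmetic deterministic for fixed inputs.
#'
#' @param params An [ord_params()].
#' @param drug A [drug_model()] or `NULL`.
#' @param concentration Drug concentration, uM.
#' @param pacing A [pacing_spec()].
#' @param dt Integration step, ms (default 0.005).
#' @param record_dt Recording interval, ms.
#' @param init Optional initial state vector (42 values) from a previous
#'   run's `$state`.
#' @param ... Passed to [apply_drug()].
#' @return Object of class `paced_run`: `time`, `V`, `b`, `currents`
#'   (matrix with named columns), `apd90` per beat, `final_apd90`,
#'   `steady` (|delta APD90| of the last two beats < 0.1 ms), `state`
#'   (final state vector), plus the run configuration.
#' @export
paced_run <- function(params, drug = NULL, concentration = 0,
                      pacing = pacing_spec(), dt = 0.005, record_dt = 0.05,
                      init = NULL, ...) {
  stopifnot(inherits(params, "ord_params"), inherits(pacing, "pacing_spec"))
  ap <- apply_drug(params, drug, concentration, ...)
  n_beats <- pacing$n_prepace + pacing$n_record
  res <- ord_paced_cpp(params$cell_type, ap$mult, ap$nav_block,
                       pacing$cycle_length, pacing$stim_amp, pacing$stim_dur,
                       n_beats, pacing$n_record, dt, record_dt,
                       init)
  colnames(res$currents) <- c("INa", "INaL", "Ito", "ICaL", "IKr", "IKs",
                              "IK1", "INaCa", "INaK")
  apd <- res$apd90
  n <- length(apd)
  steady <- n >= 2 && all(is.finite(apd[(n - 1):n])) &&
    abs(apd[n] - apd[n - 1]) < 0.1
  structure(
    list(time = res$time, V = res$V, b = res$b, currents = res$currents,
         apd90 = apd, final_apd90 = apd[n],
         peak_v = res$peak_v, dvdt_max = res$dvdt_max,
         steady = steady, state = res$state,
         params = params, concentration = concentration,
         pacing = pacing, dt = dt, record_dt = record_dt),
    class = "paced_run"
  )
}

#' @export
print.paced_run <- function(x, ...) {
  cat(sprintf("<paced_run> %s/%s, [D] = %g uM, CL %g ms, %d+%d beats\n",
              x$params$cell_type_name, x$params$variant, x$concentration,
              x$pacing$cycle_length, x$pacing$n_prepace, x$pacing$n_record))
  cat(sprintf("  final APD90 = %.2f ms (steady: %s)\n", x$final_apd90,
              x$steady))
  invisible(x)
}

#' Net charge carried by the six CiPA currents over one beat
#'
#' Trapezoidal integral of `I_NaL + I_CaL + I_Kr + I_Ks + I_K1 + I_to` over
#' the final recorded cycle, in uC/uF. Larger (more positive) values indicate
#' lower torsade risk.
#'
#' @param run A [paced_run()] with at least one complete recorded beat.
#' @return Object of class `qnet_result`: `qnet` (uC/uF), `components`
#'   (named per-current integrals), `beat` (index of the beat used).
#' @export
qnet <- function(run) {
  stopifnot(inherits(run, "paced_run"))
  cl <- run$pacing$cycle_length
  t <- run$time
  t_end <- max(t)
  sel <- which(t >= t_end - cl - 1e-9)
  if (length(sel) < 10 || (max(t[sel]) - min(t[sel])) < cl - run$record_dt * 2)
    stop("no complete recorded beat available for the charge integral",
         call. = FALSE)
  comps <- c("INaL", "ICaL", "IKr", "IKs", "IK1", "Ito")
  integrals <- vapply(comps, function(nm)
    pracma::trapz(t[sel], run$currents[sel, nm]) / 1000, numeric(1))
  structure(
    list(qnet = sum(integrals), components = integrals,
         beat = length(run$apd90)),
    class = "qnet_result"
  )
}

#' @export
print.qnet_result <- function(x, ...) {
  cat(sprintf("<qnet_result> Q_net = %.4f uC/uF (beat %d)\n", x$qnet, x$beat))
  invisible(x)
}

#' Reproduction configuration for the printed APD90 anchors
#'
#' The baseline calibration and pacing used when reproducing the published
#' single-cell APD90 pair (control 304.0 ms, 1x C_max 270.5 ms, endo cell):
#' the CiPA-recalibrated O'Hara-Rudy calibration (the net-charge metric's
#' standard baseline), 2000 ms cycle length, -80 uA/uF x 0.5 ms stimulus,
#' 300 pre-pacing beats (last-two-beat APD90 change < 0.1 ms).
#'
#' @return List with `params` ([ord_params()]) and `pacing`
#'   ([pacing_spec()]).
#' @export
repro_config <- function() {
  list(params = ord_params("endo", "cipa"),
       pacing = pacing_spec(cycle_length = 2000, stim_amp = -80,
                            stim_dur = 0.5, n_prepace = 300, n_record = 2))
}
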