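#' Use-dependent block measurement
#'
#' Normalized peak sequence from a pulse-train recording: `o_n` is the peak
#' Na+ current of pulse n relative to the first pulse (the available, i.e.
#' non-inactivated and non-blocked, fraction), with the depolarized dwell
#' `t_d` and the per-sweep recovery interval `t_r`.
#'
#' @param peak_sequence Matrix or list of per-sweep normalized peak
#'   sequences. A numeric matrix `[n_sweeps x n_pulses]` with first column 1.
#' @param t_d Depolarized dwell per pulse, ms.
#' @param t_r Recovery interval per sweep, ms (length = number of sweeps).
#' @param condition `"control"` or `"drug"`.
#' @return An object of class `udb_measurement`.
#' @export
udb_measurement <- function(peak_sequence, t_d, t_r,
                            condition = c("control", "drug")) {
  condition <- match.arg(condition)
  if (!is.matrix(peak_sequence)) peak_sequence <- matrix(peak_sequence, nrow = 1)
  if (t_d <= 0 || any(t_r <= 0))
    stop("t_d and t_r must be strictly positive", call. = FALSE)
  if (length(t_r) != nrow(peak_sequence))
    stop("one t_r per sweep required", call. = FALSE)
  if (any(peak_sequence <= 0))
    stop("peak sequence entries must be positive", call. = FALSE)
  if (any(abs(peak_sequence[, 1] - 1) > 1e-6))
    warning("first-pulse peaks are expected to be normalized to 1")
  nondec <- apply(peak_sequence, 1, function(o) any(diff(o) > 0))
  structure(
    list(peak_sequence = peak_sequence, t_d = t_d, t_r = t_r,
         condition = condition, nonmonotone = nondec),
    class = "udb_measurement"
  )
}

# successive-peak ratios per sweep: [n_sweeps x (n_pulses - 1)]
udb_ratios <- function(udb) {
  o <- udb$peak_sequence
  o[, -1, drop = FALSE] / o[, -ncol(o), drop = FALSE]
}

#' Recovery time constant from a drug-free pulse train
#'
#' Inverts the use-dependent recurrence for the drug-free case: with `o_n`
#' the available fraction at pulse n,
#' `tau_r = t_r / (ln(1 - exp(-t_d/tau_i)) - ln(1 - o_n/o_{n-1}))`.
#' Each valid successive-peak ratio yields one estimate; the pooled value is
#' their unweighted mean. Ratios at or beyond the zero-recovery limit
#' (`o_n/o_{n-1} <= exp(-t_d/tau_i)`, where the denominator is non-positive
#' and the implied tau_r infinite) are excluded with a warning.
#'
#' Only the first decrement (`o_2/o_1`) is used by default: the recurrence
#' tracks a single recovery interval, which is exact for the first pulse pair
#' but increasingly biased as the train saturates toward its use-dependent
#' steady state; set `pulses = "all"` to pool every successive ratio.
#'
#' @param udb A control-condition [udb_measurement()].
#' @param tau_i Drug-free inactivation time constant, ms.
#' @param pulses `"first"` (default) or `"all"`: which successive-peak
#'   ratios enter the pooled estimate.
#' @return List of class `tau_estimate`: `per_interval` data frame
#'   (`t_r`, `pulse`, `ratio`, `tau`), `pooled`, `n_used`, `n_excluded`.
#' @export
recovery_tau <- function(udb, tau_i, pulses = c("first", "all")) {
  pulses <- match.arg(pulses)
  stopifnot(inherits(udb, "udb_measurement"))
  if (tau_i <= 0) stop("tau_i must be > 0", call. = FALSE)
  ratios <- udb_ratios(udb)
  if (pulses == "first") ratios <- ratios[, 1, drop = FALSE]
  lim <- 1 - exp(-udb$t_d / tau_i)
  rows <- list()
  n_excl <- 0L
  for (i in seq_len(nrow(ratios))) {
    for (j in seq_len(ncol(ratios))) {
      r <- ratios[i, j]
      if (!is.finite(r) || r <= 0 || r >= 1) { n_excl <- n_excl + 1L; next }
      den <- log(lim) - log(1 - r)
      if (den <= 0) { n_excl <- n_excl + 1L; next }  # at/past zero-recovery limit
      rows[[length(rows) + 1L]] <- data.frame(
        t_r = udb$t_r[i], pulse = j + 1L, ratio = r,
        tau = udb$t_r[i] / den)
    }
  }
  if (n_excl > 0)
    warning(sprintf("%d interval(s) excluded (apparent full recovery or invalid ratio)",
                    n_excl))
  if (!length(rows))
    stop("non-estimable: all intervals excluded", call. = FALSE)
  per <- do.call(rbind, rows)
  structure(list(per_interval = per, pooled = mean(per$tau),
                 n_used = nrow(per), n_excluded = n_excl,
                 quantity = "tau_r"),
            class = "tau_estimate")
}

#' @export
print.tau_estimate <- function(x, ...) {
  cat(sprintf("<tau_estimate> %s pooled = %.4g ms over %d interval(s) (%d excluded)\n",
              x$quantity, x$pooled, x$n_used, x$n_excluded))
  invisible(x)
}

#' Open-block time constant from apparent decay constants
#'
#' With drug, the apparent current-decay rate during a depolarizing step is
#' the sum of the inactivation rate and the open-block rate:
#' `1/tau_{i+ob} = 1/tau_i + 1/tau_ob`, so
#' `tau_ob = 1 / (1/tau_{i+ob} - 1/tau_i)`.
#'
#' @param tau_i_ob Apparent decay time constant with drug, ms.
#' @param tau_i Drug-free inactivation time constant, ms (must exceed
#'   `tau_i_ob`).
#' @return `tau_ob` in ms.
#' @export
tau_ob_from_decay <- function(tau_i_ob, tau_i) {
  if (tau_i_ob <= 0 || tau_i <= 0) stop("time constants must be > 0",
                                        call. = FALSE)
  if (tau_i_ob >= tau_i)
    stop("no resolvable open block: tau_i+ob must be < tau_i", call. = FALSE)
  1 / (1 / tau_i_ob - 1 / tau_i)
}

#' Sum of open-state blocking and unblocking rates
#'
#' The difference of reciprocal decay constants with and without drug
#' estimates `k_ob * [D] + k_ob^-1` directly:
#' `rate_sum = 1/tau_drug - 1/tau_init`.
#'
#' @param tau_drug Apparent decay time constant with drug, ms.
#' @param tau_init Matched drug-free decay time constant, ms.
#' @return Rate sum in ms^-1 (0 when the inputs are equal).
#' @export
open_rate_sum <- function(tau_drug, tau_init) {
  if (tau_drug <= 0 || tau_init <= 0) stop("time constants must be > 0",
                                           call. = FALSE)
  if (tau_drug > tau_init)
    stop("no resolvable open block: tau_drug must be <= tau_init",
         call. = FALSE)
  1 / tau_drug - 1 / tau_init
}

#' Inactivated-state block/unblock time constant from a drug pulse train
#'
#' Applies the composed "inactivated-or-blocked" recurrence to a pulse train
#' recorded with drug:
#' `1/tau_ib = 1/tau_r - (ln(1 - exp(-t_d (1/tau_i + 1/tau_ob))) -
#'  ln(1 - o_n/o_{n-1})) / t_r`,
#' where `tau_r` comes from the matched control recording and `tau_ob` from
#' the decay-constant analysis. Intervals whose estimate comes out
#' non-positive (apparent recovery faster than control) are excluded with a
#' warning.
#'
#' @param udb_drug A drug-condition [udb_measurement()].
#' @param tau_i Drug-free inactivation time constant, ms.
#' @param tau_ob Open-block time constant, ms.
#' @param tau_r Control recovery time constant, ms.
#' @param pulses `"first"` (default) or `"all"`; see [recovery_tau()].
#' @return A `tau_estimate` for `tau_ib` (per interval + pooled mean).
#' @export
inactivated_block_tau <- function(udb_drug, tau_i, tau_ob, tau_r,
                                  pulses = c("first", "all")) {
  pulses <- match.arg(pulses)
  stopifnot(inherits(udb_drug, "udb_measurement"))
  if (tau_i <= 0 || tau_ob <= 0 || tau_r <= 0)
    stop("time constants must be > 0", call. = FALSE)
  ratios <- udb_ratios(udb_drug)
  if (pulses == "first") ratios <- ratios[, 1, drop = FALSE]
  lim <- 1 - exp(-udb_drug$t_d * (1 / tau_i + 1 / tau_ob))
  rows <- list()
  n_excl <- 0L
  for (i in seq_len(nrow(ratios))) {
    for (j in seq_len(ncol(ratios))) {
      r <- ratios[i, j]
      if (!is.finite(r) || r <= 0 || r >= 1) { n_excl <- n_excl + 1L; next }
      inv <- 1 / tau_r - (log(lim) - log(1 - r)) / udb_drug$t_r[i]
      if (!is.finite(inv) || inv <= 0) { n_excl <- n_excl + 1L; next }
      rows[[length(rows) + 1L]] <- data.frame(
        t_r = udb_drug$t_r[i], pulse = j + 1L, ratio = r, tau = 1 / inv)
    }
  }
  if (n_excl > 0)
    warning(sprintf("%d interval(s) excluded (non-positive 1/tau_ib)", n_excl))
  if (!length(rows))
    stop("non-estimable: all intervals excluded", call. = FALSE)
  per <- do.call(rbind, rows)
  structure(list(per_interval = per, pooled = mean(per$tau),
                 n_used = nrow(per), n_excluded = n_excl,
                 quantity = "tau_ib"),
            class = "tau_estimate")
}

#' Transfer a dissociation-constant ratio between conformations
#'
#' Given a reference compound's open- and inactivated-state dissociation
#' constants, assumes the target compound keeps the same inactivated/open
#' proportion: `Kd(I)_target = Kd(O)_target * (Kd(I)_ref / Kd(O)_ref)`.
#'
#' @param kd_o_ref,kd_i_ref Reference open/inactivated Kd, uM.
#' @param kd_o_target Target compound open-state Kd, uM.
#' @return Target inactivated-state Kd, uM.
#' @export
transfer_kd_ratio <- function(kd_o_ref, kd_i_ref, kd_o_target) {
  if (any(c(kd_o_ref, kd_i_ref, kd_o_target) <= 0))
    stop("all dissociation constants must be > 0", call. = FALSE)
  kd_o_target * (kd_i_ref / kd_o_ref)
}

#' Blocking/unblocking rates from their sum and the dissociation constant
#'
#' Solves the two-equation system `k * [D] + k_inv = rate_sum` and
#' `k_inv / k = K_d`: `k_inv = rate_sum / (1 + [D]/K_d)`,
#' `k = (rate_sum - k_inv) / [D]`.
#'
#' @param rate_sum Total block/unblock rate, ms^-1.
#' @param concentration Drug concentration `[D]`, uM.
#' @param k_d Dissociation constant, uM.
#' @return List with `k` (uM^-1 ms^-1) and `k_inv` (ms^-1).
#' @export
rates_from_sum_and_kd <- function(rate_sum, concentration, k_d) {
  if (rate_sum <= 0 || concentration < 0 || k_d <= 0)
    stop("rate_sum and k_d must be > 0, concentration >= 0", call. = FALSE)
  k_inv <- rate_sum / (1 + concentration / k_d)
  k <- if (concentration > 0) (rate_sum - k_inv) / concentration else 0
  list(k = k, k_inv = k_inv)
}

#' Reference lidocaine-Nav1.5 state-specific rate constants
#'
#' Literature values for lidocaine block of Nav1.5 used as the reference
#' pair when transferring the inactivated/open affinity ratio to another
#' compound: k_ob 5173 M^-1 ms^-1, k_ib 4998.4 M^-1 ms^-1, k_ob^-1
#' 0.0128 ms^-1, k_ib^-1 0.0384 ms^-1, giving Kd(O) 2.4744 uM, Kd(I)
#' 7.6825 uM and a Kd(I)/Kd(O) ratio of 3.1048.
#'
#' @return Named list with the four rates (uM^-1 ms^-1 / ms^-1), both Kd
#'   values (uM) and the `kd_ratio`.
#' @export
lidocaine_reference <- function() {
  k_ob <- 5173 / 1e6      # M^-1 ms^-1 -> uM^-1 ms^-1
  k_ib <- 4998.4 / 1e6
  k_ob_inv <- 0.0128
  k_ib_inv <- 0.0384
  kd_o <- k_ob_inv / k_ob
  kd_i <- k_ib_inv / k_ib
  list(k_ob = k_ob, k_ib = k_ib, k_ob_inv = k_ob_inv, k_ib_inv = k_ib_inv,
       kd_o = kd_o, kd_i = kd_i, kd_ratio = kd_i / kd_o)
}

#' End-to-end state-specific rate estimation from sweep sets
#'
#' Runs the full open- and inactivated-state analysis chain on matched
#' control and drug recordings:
#' decay fits give `tau_i` and `tau_{i+ob}`; the control pulse train gives
#' `tau_r`; the drug pulse train gives `tau_ib`; the open-state rate pair
#' comes from the reciprocal decay difference with `Kd(O)`, and the
#' inactivated-state pair from `1/tau_ib` with `Kd(I)` (transferred from the
#' reference ratio unless supplied).
#'
#' @param tau_i,tau_i_ob Fitted decay constants without/with drug, ms.
#' @param udb_control,udb_drug Control and drug [udb_measurement()]s.
#' @param concentration Drug concentration used for rate extraction, uM.
#' @param kd_o Open-state dissociation constant, uM (conventionally the
#'   peak-current IC50).
#' @param kd_i Inactivated-state Kd, uM; default transfers the lidocaine
#'   reference ratio from `kd_o`.
#' @return List of class `state_rates`: the four rates, both Kd values, the
#'   intermediate `tau_r`, `tau_ob`, `tau_ib` estimates and the applied
#'   concentration.
#' @export
estimate_state_rates <- function(tau_i, tau_i_ob, udb_control, udb_drug,
                                 concentration, kd_o,
                                 kd_i = transfer_kd_ratio(
                                   lidocaine_reference()$kd_o,
                                   lidocaine_reference()$kd_i, kd_o)) {
  tr <- recovery_tau(udb_control, tau_i)
  tau_ob <- tau_ob_from_decay(tau_i_ob, tau_i)
  tib <- inactivated_block_tau(udb_drug, tau_i, tau_ob, tr$pooled)
  open_sum <- open_rate_sum(tau_i_ob, tau_i)
  open_pair <- rates_from_sum_and_kd(open_sum, concentration, kd_o)
  inact_pair <- rates_from_sum_and_kd(1 / tib$pooled, concentration, kd_i)
  structure(
    list(k_ob = open_pair$k, k_ob_inv = open_pair$k_inv,
         k_ib = inact_pair$k, k_ib_inv = inact_pair$k_inv,
         kd_o = kd_o, kd_i = kd_i,
         tau_r = tr$pooled, tau_ob = tau_ob, tau_ib = tib$pooled,
         open_rate_sum = open_sum, concentration = concentration),
    class = "state_rates"
  )
}

#' @export
print.state_rates <- function(x, ...) {
  cat("<state_rates>\n")
  cat(sprintf("  open:        k_ob = %.4g uM^-1 ms^-1, k_ob^-1 = %.4g ms^-1 (Kd %.4g uM)\n",
              x$k_ob, x$k_ob_inv, x$kd_o))
  cat(sprintf("  inactivated: k_ib = %.4g uM^-1 ms^-1, k_ib^-1 = %.4g ms^-1 (Kd %.4g uM)\n",
              x$k_ib, x$k_ib_inv, x$kd_i))
  cat(sprintf("  tau_r %.3g ms, tau_ob %.3g ms, tau_ib %.3g ms at [D] = %g uM\n",
              x$tau_r, x$tau_ob, x$tau_ib, x$concentration))
  invisible(x)
}
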