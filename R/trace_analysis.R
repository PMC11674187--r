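#' Peak current in an analysis window
#'
#' Measures the extremum of a baseline-subtracted sweep inside a time window.
#' Ties are broken by the earliest sample. The baseline is the mean of the
#' sweep over `baseline_window` (conventionally the final few ms of the
#' preceding holding/seal-test segment); pass `NULL` to skip subtraction.
#'
#' @param sweep Numeric trace vector.
#' @param times Sample times in ms (same length as `sweep`).
#' @param window Length-2 ms window to search.
#' @param polarity `"inward"` (most negative) or `"outward"` (most positive).
#' @param baseline_window Length-2 ms window for the baseline, or `NULL`.
#' @return A list of class `peak_measurement` with `peak_value`, `peak_time`,
#'   `baseline`.
#' @export
measure_peak <- function(sweep, times, window,
                         polarity = c("inward", "outward"),
                         baseline_window = NULL) {
  polarity <- match.arg(polarity)
  stopifnot(length(sweep) == length(times))
  idx <- which(times >= window[1] & times <= window[2])
  if (!length(idx)) stop("empty analysis window", call. = FALSE)
  baseline <- 0
  if (!is.null(baseline_window)) {
    bidx <- which(times >= baseline_window[1] & times <= baseline_window[2])
    if (!length(bidx)) stop("empty baseline window", call. = FALSE)
    baseline <- mean(sweep[bidx])
  }
  y <- sweep[idx] - baseline
  k <- if (polarity == "inward") which.min(y) else which.max(y)
  structure(
    list(peak_value = y[k], peak_time = times[idx[k]], baseline = baseline,
         polarity = polarity),
    class = "peak_measurement"
  )
}

#' Peak currents for every sweep of a sweep set
#'
#' @param x A [sweep_set()].
#' @inheritParams measure_peak
#' @return Data frame with one row per sweep: `sweep`, `peak_value`,
#'   `peak_time`, `baseline`.
#' @export
measure_peaks <- function(x, window, polarity = c("inward", "outward"),
                          baseline_window = NULL) {
  stopifnot(inherits(x, "sweep_set"))
  polarity <- match.arg(polarity)
  tms <- sweep_times(x)
  rows <- lapply(seq_len(nrow(x$sweeps)), function(i) {
    pk <- measure_peak(x$sweeps[i, ], tms, window, polarity, baseline_window)
    data.frame(sweep = i, peak_value = pk$peak_value,
               peak_time = pk$peak_time, baseline = pk$baseline)
  })
  do.call(rbind, rows)
}

#' Monoexponential decay fit
#'
#' Least-squares fit of `A * exp(-t / tau) + C` over a window, used for the
#' apparent macroscopic inactivation time constant of Na+ current decays.
#' Starting values come from a log-linear regression on the offset-corrected
#' signal; on failure up to three perturbed restarts are attempted
#' (Levenberg-Marquardt via minpack.lm). Non-convergence is flagged on the
#' returned object, never silent.
#'
#' @param sweep Numeric trace vector.
#' @param times Sample times in ms.
#' @param window Length-2 ms fit window (>= 10 samples).
#' @return A list of class `exp_fit`: `tau` (ms), `amplitude`, `offset`,
#'   `window`, `rms`, `converged`.
#' @export
fit_monoexp <- function(sweep, times, window) {
  stopifnot(length(sweep) == length(times))
  idx <- which(times >= window[1] & times <= window[2])
  if (length(idx) < 10) stop("fit window must hold at least 10 samples",
                             call. = FALSE)
  t <- times[idx] - times[idx[1]]
  y <- sweep[idx]

  # initial guesses: offset from the tail, tau from log-linear slope
  c0 <- mean(y[max(1, length(y) - 4):length(y)])
  a0 <- y[1] - c0
  z <- abs(y - c0)
  ok <- z > max(z) * 1e-3
  tau0 <- if (sum(ok) >= 3) {
    sl <- unname(stats::coef(stats::lm(log(z[ok]) ~ t[ok]))[2])
    if (is.finite(sl) && sl < 0) -1 / sl else diff(range(t)) / 3
  } else diff(range(t)) / 3
  c0 <- unname(c0); a0 <- unname(a0)

  fit <- NULL
  starts <- list(c(a0, tau0, c0), c(a0, tau0 * 3, c0), c(a0, tau0 / 3, c0))
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ A * exp(-t / tau) + C,
                        start = list(A = s[1], tau = abs(s[2]), C = s[3]),
                        lower = c(-Inf, 1e-6, -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    return(structure(list(tau = NA_real_, amplitude = NA_real_,
                          offset = NA_real_, window = window, rms = NA_real_,
                          converged = FALSE),
                     class = "exp_fit"))
  }
  cf <- stats::coef(fit)
  structure(
    list(tau = unname(cf["tau"]), amplitude = unname(cf["A"]),
         offset = unname(cf["C"]), window = window,
         rms = sqrt(mean(stats::residuals(fit)^2)), converged = TRUE),
    class = "exp_fit"
  )
}

#' Boltzmann fit of normalized activation/inactivation data
#'
#' Fits `floor + (ceiling - floor) / (1 + exp((v_half - V)/k))`. For
#' activation data `k > 0` (rising with depolarization); steady-state
#' inactivation curves are fitted with the mirrored form (`direction =
#' "inactivation"`), reported with `k > 0` and a falling curve. Floor and
#' ceiling default to the fixed 0/1 normalization; set `free_limits = TRUE`
#' to fit them.
#'
#' @param voltages Test potentials, mV (>= 5 points spanning the transition).
#' @param response Normalized responses.
#' @param direction `"activation"` or `"inactivation"`.
#' @param free_limits Fit floor/ceiling instead of fixing them at 0/1.
#' @return A list of class `boltzmann_fit`: `v_half`, `k`, `floor`,
#'   `ceiling`, `direction`, `converged`, `low_confidence`.
#' @export
fit_boltzmann <- function(voltages, response,
                          direction = c("activation", "inactivation"),
                          free_limits = FALSE) {
  direction <- match.arg(direction)
  stopifnot(length(voltages) == length(response))
  if (length(voltages) < 5)
    stop("need at least 5 points spanning the transition", call. = FALSE)
  sgn <- if (direction == "activation") 1 else -1
  spans <- diff(range(response))
  low_confidence <- spans < 0.5  # data do not span the transition
  # midpoint guess: voltage whose response is nearest mid-range
  mid <- (max(response) + min(response)) / 2
  v0 <- voltages[which.min(abs(response - mid))]
  model <- if (free_limits)
    response ~ lo + (hi - lo) / (1 + exp(sgn * (v_half - voltages) / k))
  else
    response ~ 1 / (1 + exp(sgn * (v_half - voltages) / k))
  start <- list(v_half = v0, k = 5)
  if (free_limits) start <- c(start, list(lo = min(response), hi = max(response)))
  fit <- tryCatch(
    minpack.lm::nlsLM(model, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(v_half = NA_real_, k = NA_real_, floor = NA_real_,
                          ceiling = NA_real_, direction = direction,
                          converged = FALSE, low_confidence = TRUE),
                     class = "boltzmann_fit"))
  }
  cf <- stats::coef(fit)
  structure(
    list(v_half = unname(cf["v_half"]), k = abs(unname(cf["k"])),
         floor = if (free_limits) unname(cf["lo"]) else 0,
         ceiling = if (free_limits) unname(cf["hi"]) else 1,
         direction = direction, converged = TRUE,
         low_confidence = low_confidence),
    class = "boltzmann_fit"
  )
}

#' Conductance transform for activation curves
#'
#' Converts peak currents from an activation family to chord conductances
#' `G = I / (V - E_rev)` and normalizes to the maximum, the standard
#' preprocessing before a Boltzmann activation fit.
#'
#' @param peaks Peak currents per test potential.
#' @param voltages Test potentials, mV.
#' @param e_rev Reversal potential, mV (default +65 for Na+ under standard
#'   solutions).
#' @return Normalized conductances in `[0, 1]`.
#' @export
conductance_normalize <- function(peaks, voltages, e_rev = 65) {
  g <- peaks / (voltages - e_rev)
  g / max(g)
}

#' Action-potential metrics from a voltage trace
#'
#' For each stimulus, locates the triggered action potential and reports
#' APD90, resting potential, peak overshoot, maximal upstroke velocity and
#' take-off time. The resting potential is the mean voltage over a window
#' before the stimulus; take-off is the time of maximal dV/dt after the
#' stimulus; APD90 is measured from take-off to 90% repolarization from the
#' AP peak down toward the pre-stimulus resting level (robust for both
#' polarized model cells and depolarized hiPSC-CM-like traces). The 90%
#' crossing is located by linear interpolation between samples. If the peak
#' stays below `capture_threshold` the AP is reported as not captured.
#'
#' @param voltage Membrane potential trace, mV.
#' @param times Sample times, ms.
#' @param stimulus_times Stimulus onset times, ms.
#' @param rp_window_ms Width of the pre-stimulus resting-potential window, ms.
#' @param capture_threshold Minimal peak voltage (mV) to count as a captured
#'   AP.
#' @param search_ms How far after each stimulus to search for the AP, ms;
#'   default extends to the next stimulus (or trace end).
#' @return Data frame of class `ap_metrics`, one row per stimulus: `stimulus`,
#'   `captured`, `APD90`, `RP`, `peak`, `dvdt_max`, `takeoff`.
#' @export
ap_metrics <- function(voltage, times, stimulus_times,
                       rp_window_ms = 50, capture_threshold = 0,
                       search_ms = NULL) {
  stopifnot(length(voltage) == length(times), length(stimulus_times) >= 1)
  dt <- stats::median(diff(times))
  out <- lapply(seq_along(stimulus_times), function(si) {
    st <- stimulus_times[si]
    end <- if (!is.null(search_ms)) st + search_ms
           else if (si < length(stimulus_times)) stimulus_times[si + 1]
           else max(times)
    ridx <- which(times >= st - rp_window_ms & times < st)
    rp <- if (length(ridx)) mean(voltage[ridx]) else voltage[1]
    idx <- which(times >= st & times <= end)
    if (length(idx) < 5)
      return(data.frame(stimulus = si, captured = FALSE, APD90 = NA_real_,
                        RP = rp, peak = NA_real_, dvdt_max = NA_real_,
                        takeoff = NA_real_))
    v <- voltage[idx]; tt <- times[idx]
    pk_i <- which.max(v)
    peak <- v[pk_i]
    if (peak < capture_threshold)
      return(data.frame(stimulus = si, captured = FALSE, APD90 = NA_real_,
                        RP = rp, peak = peak, dvdt_max = NA_real_,
                        takeoff = NA_real_))
    dvdt <- diff(v) / diff(tt)
    up_i <- which.max(dvdt[seq_len(max(pk_i - 1, 1))])
    takeoff <- tt[up_i]
    v90 <- peak - 0.9 * (peak - rp)
    below <- which(v[-seq_len(pk_i)] <= v90)
    apd90 <- NA_real_
    if (length(below)) {
      j <- pk_i + below[1]          # first sample at/below v90 after the peak
      if (j > 1 && v[j - 1] > v90) {
        frac <- (v[j - 1] - v90) / (v[j - 1] - v[j])
        t90 <- tt[j - 1] + frac * (tt[j] - tt[j - 1])
      } else t90 <- tt[j]
      apd90 <- t90 - takeoff
    }
    data.frame(stimulus = si, captured = TRUE, APD90 = apd90, RP = rp,
               peak = peak, dvdt_max = max(dvdt[seq_len(max(pk_i - 1, 1))]),
               takeoff = takeoff)
  })
  res <- do.call(rbind, out)
  class(res) <- c("ap_metrics", class(res))
  res
}
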