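#' Strand (1D fiber) configuration
#'
#' A linear string of identical ventricular myocytes coupled by gap-junction
#' conductances, stimulated at one end. `g_j` is the inter-cell coupling
#' normalized to membrane capacitance in pS/pF; 1 pS/pF across a 1 mV
#' difference drives 1e-3 uA/uF of coupling current. The physiological
#' range of interest spans roughly 300 (severely uncoupled, pathological)
#' to 6000 pS/pF (normal working myocardium).
#'
#' @param n_cells Number of cells (default 50).
#' @param g_j Gap-junction conductance, pS/pF; a scalar or one value per
#'   interface (`n_cells - 1`).
#' @param cell_length_um Cell length, um (default 100, the model geometry).
#' @param pacing A [pacing_spec()]; `n_record` beats are run with the strand
#'   coupled (analysis on the last), after single-cell pre-pacing.
#' @param stim_cells Number of cells at the stimulated end receiving the
#'   pacing current (default 3: a single end cell cannot simultaneously
#'   depolarize itself and source its downstream neighbors when the fast
#'   Na+ current is partly blocked).
#' @return Object of class `strand_config`.
#' @export
strand_config <- function(n_cells = 50, g_j = 6000, cell_length_um = 100,
                          pacing = pacing_spec(n_prepace = 300, n_record = 2,
                                               stim_dur = 2),
                          stim_cells = 3L) {
  stopifnot(n_cells >= 2, all(g_j > 0))
  if (length(g_j) != 1 && length(g_j) != n_cells - 1)
    stop("g_j must be a scalar or one value per interface", call. = FALSE)
  if (stim_cells < 1L || stim_cells > n_cells)
    stop("stim_cells must be in 1..n_cells", call. = FALSE)
  structure(
    list(n_cells = as.integer(n_cells), g_j = g_j,
         cell_length_um = cell_length_um, pacing = pacing,
         stim_cells = as.integer(stim_cells)),
    class = "strand_config"
  )
}

#' Simulate action-potential propagation along a myocyte strand
#'
#' Each cell integrates the full drug-extended myocyte model; the total
#' current of cell i is supplemented by the longitudinal coupling term
#' `G_j (V_{i-1} - V_i) + G_j (V_{i+1} - V_i)` with sealed (no-flux) ends.
#' Cells are first pre-paced to single-cell steady state at the run's
#' concentration (coupled pre-pacing of 50 full models being needlessly
#' expensive for a uniform fiber), then the coupled strand is paced through
#' its first `stim_cells` cells for `n_record` beats and the last beat
#' analyzed.
#'
#' Capture classification per cell: peak V >= 0 mV with a maximal upstroke
#' velocity (measured inside the upstroke voltage band) >= 1 mV/ms. An
#' electrotonic bump fails the overshoot criterion; genuinely propagated
#' but gap-junction-limited slow-response upstrokes (a few mV/ms) count as
#' capture.
#'
#' @param config A [strand_config()].
#' @param params An [ord_params()].
#' @param drug A [drug_model()] or `NULL`.
#' @param concentration Drug concentration, uM.
#' @param dt Integration step, ms.
#' @param record_dt Recording interval for the returned V(x, t) matrix, ms.
#' @param prepaced_state Optional pre-paced single-cell state (42-vector);
#'   when supplied the single-cell pre-pacing stage is skipped.
#' @param ... Passed to [apply_drug()].
#' @return Object of class `propagation_result`: `activation_time` (ms, NaN
#'   for non-captured cells), `captured`, `cv` (cm/s over the interior, NA
#'   under block), `delay_ms` (first-to-last activation, NA under block),
#'   `block` flag, `first_blocked_cell`, `V` (time x cell matrix), `time`.
#' @export
simulate_strand <- function(config, params, drug = NULL, concentration = 0,
                            dt = 0.005, record_dt = 0.5,
                            prepaced_state = NULL, ...) {
  stopifnot(inherits(config, "strand_config"), inherits(params, "ord_params"))
  pacing <- config$pacing
  if (is.null(prepaced_state)) {
    pre <- paced_run(params, drug, concentration,
                     pacing = pacing_spec(
                       cycle_length = pacing$cycle_length,
                       stim_amp = pacing$stim_amp, stim_dur = pacing$stim_dur,
                       n_prepace = pacing$n_prepace, n_record = 1),
                     dt = dt, record_dt = 1, ...)
    prepaced_state <- pre$state
  }
  ap <- apply_drug(params, drug, concentration, ...)
  res <- ord_strand_cpp(config$n_cells, prepaced_state, params$cell_type,
                        ap$mult, ap$nav_block, config$g_j,
                        pacing$cycle_length, pacing$stim_amp,
                        pacing$stim_dur, config$stim_cells,
                        pacing$n_record, dt, record_dt)
  captured <- res$dvdt_max >= 1 & res$peak_v >= 0
  act <- ifelse(captured, res$activation_time, NA_real_)
  block <- !all(captured)
  first_blocked <- if (block) min(which(!captured)) else NA_integer_
  amap <- activation_map(act, config$cell_length_um)
  cv <- if (block && !all(captured[10:min(40, config$n_cells)])) NA_real_
        else conduction_velocity(amap)
  delay <- if (block) NA_real_ else act[config$n_cells] - act[1]
  structure(
    list(activation_time = act, captured = captured,
         activation_map = amap, cv = cv, delay_ms = delay,
         block = block, first_blocked_cell = first_blocked,
         time = res$time, V = res$V,
         config = config, concentration = concentration),
    class = "propagation_result"
  )
}

#' @export
print.propagation_result <- function(x, ...) {
  if (x$block)
    cat(sprintf("<propagation_result> BLOCK at cell %d (%d/%d captured)\n",
                x$first_blocked_cell, sum(x$captured), length(x$captured)))
  else
    cat(sprintf("<propagation_result> cv = %.2f cm/s, total delay %.2f ms\n",
                x$cv, x$delay_ms))
  invisible(x)
}

#' Activation map
#'
#' @param activation_time Per-cell activation times, ms (NaN/NA for cells
#'   that never activated).
#' @param cell_length_um Cell length, um.
#' @return Data frame of class `activation_map`: `cell`, `position_um`,
#'   `activation_ms`.
#' @export
activation_map <- function(activation_time, cell_length_um = 100) {
  df <- data.frame(
    cell = seq_along(activation_time),
    position_um = (seq_along(activation_time) - 0.5) * cell_length_um,
    activation_ms = as.numeric(activation_time)
  )
  class(df) <- c("activation_map", class(df))
  df
}

#' Conduction velocity from an activation map
#'
#' Linear regression of position on activation time over the interior cells
#' (10-40 by default, excluding boundary effects); the slope is the
#' conduction velocity in cm/s (100 um per 1 ms = 10 cm/s). A blocked or
#' missing cell inside the regression window makes cv undefined.
#'
#' @param map An [activation_map()].
#' @param cells Integer range of cells used for the regression.
#' @return Conduction velocity in cm/s, or `NA` if any interior cell did not
#'   activate.
#' @export
conduction_velocity <- function(map, cells = 10:40) {
  stopifnot(inherits(map, "activation_map"))
  cells <- cells[cells <= nrow(map)]
  if (length(cells) < 2) stop("need >= 2 interior cells", call. = FALSE)
  sub <- map[map$cell %in% cells, ]
  if (any(!is.finite(sub$activation_ms))) return(NA_real_)
  if (stats::sd(sub$activation_ms) == 0) return(Inf)
  slope_um_ms <- stats::coef(stats::lm(position_um ~ activation_ms,
                                       data = sub))[2]
  unname(slope_um_ms) * 1e-4 * 1e3   # um/ms -> cm/s
}

#' Minimum reentry circuit length
#'
#' Wavelength criterion for slow-to-fast reentry in a two-pathway circuit:
#' the travel time along the slow limb must exceed the refractory period of
#' the fast limb, so the minimum circuit length is
#' `refractory_period x cv_slow`.
#'
#' @param refractory_period Fast-pathway refractory period, ms.
#' @param cv_slow Conduction velocity on the slow pathway, cm/s.
#' @return Minimum circuit length in mm.
#' @export
reentry_min_length <- function(refractory_period, cv_slow) {
  if (refractory_period <= 0 || cv_slow <= 0)
    stop("refractory period and cv must be > 0", call. = FALSE)
  refractory_period * cv_slow / 100   # ms * cm/s = 1e-3 cm = 1e-2 mm
}
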