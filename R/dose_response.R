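#' Fractional block from the Hill equation
#'
#' Fraction of current blocked at a given concentration,
#' `1 / (1 + (IC50 / C)^n_H)`, with the zero-concentration limit 0.
#'
#' @param concentration Drug concentration, uM (>= 0; vectorized).
#' @param ic50 Half-maximal inhibitory concentration, uM (> 0).
#' @param n_h Hill coefficient (> 0), default 1.
#' @return Fraction blocked in `[0, 1)`.
#' @export
fractional_block <- function(concentration, ic50, n_h = 1) {
  if (any(ic50 <= 0) || any(n_h <= 0))
    stop("ic50 and n_h must be > 0", call. = FALSE)
  if (any(concentration < 0))
    stop("concentration must be >= 0", call. = FALSE)
  ifelse(concentration == 0, 0, 1 / (1 + (ic50 / concentration)^n_h))
}

#' Single-point IC50 with control correction
#'
#' The primary potency route for one-concentration pharmacology assays:
#' the net fractional inhibition is the drug-condition inhibition minus the
#' mean control (vehicle rundown) inhibition, a plain subtraction without
#' rescaling; inverting the Hill equation then gives
#' `IC50 = C * ((1 - f) / f)^(1/n_H)`.
#'
#' @param concentration Applied concentration, uM.
#' @param inhibition_drug Fractional inhibition with drug, in (0, 1).
#' @param inhibition_control Mean fractional inhibition in time-matched
#'   vehicle controls (default 0).
#' @param n_h Hill coefficient, default 1.
#' @return A list of class `dose_response_fit` with `ic50` (uM), `n_h`,
#'   `net_inhibition`, `method = "single_point"`.
#' @export
ic50_single_point <- function(concentration, inhibition_drug,
                              inhibition_control = 0, n_h = 1) {
  f <- inhibition_drug - inhibition_control
  if (!is.finite(f) || f <= 0)
    stop("no measurable block: net inhibition <= 0", call. = FALSE)
  if (f >= 1)
    stop("saturated inhibition: net inhibition >= 1", call. = FALSE)
  ic50 <- concentration * ((1 - f) / f)^(1 / n_h)
  structure(
    list(ic50 = ic50, n_h = n_h, net_inhibition = f,
         se_ic50 = NA_real_, se_n_h = NA_real_, method = "single_point"),
    class = "dose_response_fit"
  )
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("<dose_response_fit> IC50 = %.4g uM, n_H = %.3g (%s)\n",
              x$ic50, x$n_h, x$method))
  invisible(x)
}

#' Hill fit across concentrations
#'
#' Weighted nonlinear least squares of fractional inhibition against
#' concentration (fitting log IC50 for positivity). Weights default to
#' `1/SD^2` when per-point dispersions are supplied.
#'
#' @param points Data frame with columns `concentration` (uM),
#'   `inhibition` (fraction in `[0, 1]`), optional `sd`.
#' @param fix_n_h Fix the Hill coefficient at this value (default 1;
#'   `NULL` frees it).
#' @return A `dose_response_fit` with `method = "hill_fit"` and standard
#'   errors from the fit.
#' @export
fit_hill <- function(points, fix_n_h = 1) {
  stopifnot(is.data.frame(points),
            all(c("concentration", "inhibition") %in% names(points)))
  pts <- points[points$concentration > 0, , drop = FALSE]
  ncon <- length(unique(pts$concentration))
  # with the slope fixed a single concentration identifies the IC50 (and
  # reduces to the single-point closed form); a free slope needs >= 3
  need <- if (is.null(fix_n_h)) 3 else 1
  if (ncon < need)
    stop(sprintf("need >= %d distinct concentrations", need), call. = FALSE)
  if (all(pts$inhibition <= 0) || all(pts$inhibition >= 1))
    stop("non-identifiable: all points zero or saturated", call. = FALSE)
  w <- if ("sd" %in% names(pts) && all(is.finite(pts$sd)) && all(pts$sd > 0))
    1 / pts$sd^2 else rep(1, nrow(pts))
  conc <- pts$concentration
  inh <- pts$inhibition
  # anchor the IC50 start at the concentration nearest half block
  l0 <- log(conc[which.min(abs(inh - 0.5))])
  if (is.null(fix_n_h)) {
    fit <- minpack.lm::nlsLM(
      inh ~ 1 / (1 + exp(n_h * (lic50 - log(conc)))),
      start = list(lic50 = l0, n_h = 1), weights = w,
      lower = c(-Inf, 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 500))
    cf <- stats::coef(fit); se <- summary(fit)$coefficients[, "Std. Error"]
    ic50 <- exp(cf["lic50"]); n_h <- cf["n_h"]
    se_ic50 <- ic50 * se["lic50"]; se_nh <- se["n_h"]
  } else {
    n_h <- fix_n_h
    fit <- minpack.lm::nlsLM(
      inh ~ 1 / (1 + exp(n_h * (lic50 - log(conc)))),
      start = list(lic50 = l0), weights = w,
      control = minpack.lm::nls.lm.control(maxiter = 500))
    cf <- stats::coef(fit); se <- summary(fit)$coefficients[, "Std. Error"]
    ic50 <- exp(cf["lic50"]); se_ic50 <- ic50 * se["lic50"]; se_nh <- NA_real_
  }
  structure(
    list(ic50 = unname(ic50), n_h = unname(n_h),
         net_inhibition = NA_real_,
         se_ic50 = unname(se_ic50), se_n_h = unname(se_nh),
         method = "hill_fit"),
    class = "dose_response_fit"
  )
}

#' Drug model: per-channel potency plus Nav state-specific kinetics
#'
#' Bundles everything the myocyte and strand simulators need about one
#' compound: Hill potencies per channel, the four state-specific Nav1.5
#' blocking/unblocking rate constants, the therapeutic peak plasma
#' concentration and the free (unbound) fraction.
#'
#' @param name Compound name.
#' @param channels Data frame with columns `channel` (one of `INa_peak`,
#'   `INaL`, `ICaL`, `IKr`, `IKs`), `ic50` (uM), `n_h`.
#' @param k_ob,k_ib Open-/inactivated-state blocking rates, uM^-1 ms^-1.
#' @param k_ob_inv,k_ib_inv Corresponding unblocking rates, ms^-1.
#' @param c_max Peak therapeutic plasma concentration, uM.
#' @param free_fraction Unbound fraction in plasma, in (0, 1].
#' @return An object of class `drug_model`.
#' @export
drug_model <- function(name, channels, k_ob = 0, k_ob_inv = 0,
                       k_ib = 0, k_ib_inv = 0, c_max = NA_real_,
                       free_fraction = 1) {
  stopifnot(is.data.frame(channels),
            all(c("channel", "ic50", "n_h") %in% names(channels)))
  if (any(channels$ic50 <= 0) || any(channels$n_h <= 0))
    stop("all potencies must be > 0", call. = FALSE)
  if (free_fraction <= 0 || free_fraction > 1)
    stop("free_fraction must be in (0, 1]", call. = FALSE)
  if (any(c(k_ob, k_ob_inv, k_ib, k_ib_inv) < 0))
    stop("rate constants must be >= 0", call. = FALSE)
  structure(
    list(name = name, channels = channels,
         k_ob = k_ob, k_ob_inv = k_ob_inv, k_ib = k_ib, k_ib_inv = k_ib_inv,
         c_max = c_max, free_fraction = free_fraction),
    class = "drug_model"
  )
}

#' @export
print.drug_model <- function(x, ...) {
  cat(sprintf("<drug_model> %s (C_max %g uM, free fraction %g)\n",
              x$name, x$c_max, x$free_fraction))
  print(x$channels, row.names = FALSE)
  cat(sprintf("  Nav rates: k_ob %g uM^-1ms^-1, k_ob^-1 %g ms^-1, k_ib %g, k_ib^-1 %g\n",
              x$k_ob, x$k_ob_inv, x$k_ib, x$k_ib_inv))
  invisible(x)
}

channel_ic50 <- function(drug, channel) {
  i <- match(channel, drug$channels$channel)
  if (is.na(i))
    stop(sprintf("drug model '%s' has no entry for channel %s",
                 drug$name, channel), call. = FALSE)
  list(ic50 = drug$channels$ic50[i], n_h = drug$channels$n_h[i])
}

#' Built-in cenobamate drug model
#'
#' Default potencies from the single-laboratory whole-cell assays: peak I_Na
#' 87.6 uM, late I_Na 46.5 uM, I_CaL 509.75 uM, I_Ks 1336.1 uM; for hERG the
#' adopted regulatory value 1869 uM is used. State-specific Nav1.5 rates are
#' the use-dependent-block estimates (k_ob 0.00215 uM^-1 ms^-1, k_ob^-1
#' 0.189 ms^-1, k_ib 0.0006698 uM^-1 ms^-1, k_ib^-1 0.18252 ms^-1);
#' C_max 170 uM, free fraction 0.4.
#'
#' @return A [drug_model()].
#' @export
cenobamate_model <- function() {
  drug_model(
    "cenobamate",
    channels = data.frame(
      channel = c("INa_peak", "INaL", "ICaL", "IKr", "IKs"),
      ic50 = c(87.6, 46.5, 509.75, 1869, 1336.1),
      n_h = c(1, 1, 1, 1, 1)
    ),
    k_ob = 0.00215, k_ob_inv = 0.189,
    k_ib = 0.0006698, k_ib_inv = 0.18252,
    c_max = 170, free_fraction = 0.4
  )
}

#' Convert ug/mL to uM
#'
#' Helper for plasma concentrations quoted in mass units. The cenobamate
#' molecular weight (267.67 g/mol) is the default.
#'
#' @param ug_ml Concentration in ug/mL.
#' @param mw Molecular weight, g/mol.
#' @return Concentration in uM.
#' @export
ugml_to_um <- function(ug_ml, mw = 267.67) ug_ml / mw * 1000
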