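#' Multi-sweep trace container
#'
#' Holds a matrix of equally sampled sweeps (current or voltage) together with
#' sampling metadata, as produced by the synthetic generator or read from a
#' long-format CSV export.
#'
#' @param sweeps Numeric matrix, one row per sweep.
#' @param sample_interval Sample interval in ms (> 0).
#' @param signal_kind `"current"` or `"voltage"`.
#' @param units One of `"pA"`, `"pA/pF"`, `"uA/uF"`, `"mV"`.
#' @param protocol Name of the protocol that produced the sweeps.
#' @return An object of class `sweep_set`.
#' @export
sweep_set <- function(sweeps, sample_interval,
                      signal_kind = c("current", "voltage"),
                      units = c("pA", "pA/pF", "uA/uF", "mV"),
                      protocol = NA_character_) {
  signal_kind <- match.arg(signal_kind)
  units <- match.arg(units)
  if (!is.matrix(sweeps)) sweeps <- matrix(sweeps, nrow = 1L)
  if (!is.numeric(sample_interval) || sample_interval <= 0)
    stop("sample_interval must be > 0", call. = FALSE)
  if (signal_kind == "voltage" && units != "mV")
    stop("voltage sweeps must carry mV units", call. = FALSE)
  structure(
    list(sweeps = sweeps, sample_interval = as.numeric(sample_interval),
         signal_kind = signal_kind, units = units,
         protocol = protocol),
    class = "sweep_set"
  )
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("<sweep_set> %d sweep(s) x %d samples @ %g ms (%s, %s)%s\n",
              nrow(x$sweeps), ncol(x$sweeps), x$sample_interval,
              x$signal_kind, x$units,
              if (is.na(x$protocol)) "" else paste0(" [", x$protocol, "]")))
  invisible(x)
}

#' Time axis of a sweep set
#' @param x A [sweep_set()].
#' @return Numeric vector of sample times in ms, starting at 0.
#' @export
sweep_times <- function(x) {
  stopifnot(inherits(x, "sweep_set"))
  (seq_len(ncol(x$sweeps)) - 1L) * x$sample_interval
}

#' Additive Gaussian recording noise
#'
#' @param sd Noise standard deviation in trace units (>= 0).
#' @param seed Integer seed; per-sweep substreams are derived from it so the
#'   same sweep gets the same noise regardless of how many sweeps follow it.
#' @param baseline_drift Optional linear baseline slope (units per ms) added
#'   per sweep.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(sd, seed = 1L, baseline_drift = 0) {
  if (!is.finite(sd) || sd < 0) stop("noise sd must be finite and >= 0",
                                     call. = FALSE)
  structure(list(sd = sd, seed = as.integer(seed),
                 baseline_drift = baseline_drift),
            class = "noise_spec")
}

# Fixed per-sweep seed splitting (Knuth multiplicative hashing) so that
# adding sweeps never reshuffles earlier ones. Kept below 2^31.
split_seed <- function(master, i) {
  as.integer((as.numeric(master) + i * 2654435761) %% 2147483647)
}

#' Add recording noise to a sweep set
#'
#' Adds i.i.d. Gaussian noise (and an optional linear baseline drift) to each
#' sweep. Reproducible for a fixed seed; the input object is not modified.
#'
#' @param x A [sweep_set()].
#' @param noise A [noise_spec()].
#' @return A new [sweep_set()] with noise added.
#' @export
add_noise <- function(x, noise) {
  stopifnot(inherits(x, "sweep_set"), inherits(noise, "noise_spec"))
  if (noise$sd == 0 && noise$baseline_drift == 0) return(x)
  out <- x
  tms <- sweep_times(x)
  for (i in seq_len(nrow(x$sweeps))) {
    if (noise$sd > 0) {
      set.seed(split_seed(noise$seed, i))
      out$sweeps[i, ] <- out$sweeps[i, ] +
        stats::rnorm(ncol(x$sweeps), sd = noise$sd)
    }
    if (noise$baseline_drift != 0)
      out$sweeps[i, ] <- out$sweeps[i, ] + noise$baseline_drift * tms
  }
  out
}
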