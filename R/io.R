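#' Read a shipped fixture table
#'
#' The package ships the small published data tables it reproduces as
#' plain-text CSVs: `"udb_tau"` (per-experiment use-dependent-block time
#' constants), `"decay_tau"` (paired apparent decay constants with drug /
#' vehicle, including exclusion flags), and `"worked_inhibition"` (mean
#' fractional inhibition values behind the single-point IC50 estimates).
#'
#' @param name One of `"udb_tau"`, `"decay_tau"`, `"worked_inhibition"`.
#' @return Data frame; exclusion flags come back as logical.
#' @export
fixture_table <- function(name = c("udb_tau", "decay_tau",
                                   "worked_inhibition")) {
  name <- match.arg(name)
  file <- system.file("extdata", paste0(name, "_table.csv"),
                      package = "cardioblock")
  if (file == "")
    file <- system.file("extdata", paste0(name, ".csv"),
                        package = "cardioblock")
  if (file == "") stop("fixture not found: ", name, call. = FALSE)
  utils::read.csv(file, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write / read sweep sets as long-format CSV
#'
#' One row per (sweep, sample): columns `sweep`, `time_ms`, `value`, with the
#' metadata carried in a commented header. Values are written at full
#' precision so a round trip reproduces the in-memory object to within
#' double formatting.
#'
#' @param x A [sweep_set()].
#' @param path Output file path.
#' @return `write_sweepset_csv` returns `path` invisibly;
#'   `read_sweepset_csv` returns a [sweep_set()].
#' @export
write_sweepset_csv <- function(x, path) {
  stopifnot(inherits(x, "sweep_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sweep_set sample_interval=%s signal_kind=%s units=%s protocol=%s",
                     format(x$sample_interval, digits = 17), x$signal_kind,
                     x$units, x$protocol), con)
  df <- data.frame(
    sweep = rep(seq_len(nrow(x$sweeps)), each = ncol(x$sweeps)),
    time_ms = rep(sweep_times(x), times = nrow(x$sweeps)),
    value = as.vector(t(x$sweeps))
  )
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sweepset_csv
#' @export
read_sweepset_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (!startsWith(hdr, "# sweep_set"))
    stop("not a sweep_set CSV (missing header)", call. = FALSE)
  fields <- regmatches(hdr, gregexpr("[a-z_]+=[^ ]+", hdr))[[1]]
  meta <- stats::setNames(
    sub("^[a-z_]+=", "", fields),
    sub("=.*$", "", fields))
  df <- utils::read.csv(path, comment.char = "#")
  sweeps <- do.call(rbind, split(df$value, df$sweep))
  dimnames(sweeps) <- NULL
  sweep_set(sweeps, sample_interval = as.numeric(meta[["sample_interval"]]),
            signal_kind = meta[["signal_kind"]], units = meta[["units"]],
            protocol = if (meta[["protocol"]] == "NA") NA_character_
                       else meta[["protocol"]])
}

#' Serialize / restore a protocol as JSON
#'
#' @param protocol A [voltage_protocol()].
#' @param path Output file path.
#' @return `write_protocol_json` returns `path` invisibly;
#'   `read_protocol_json` returns a [voltage_protocol()].
#' @export
write_protocol_json <- function(protocol, path) {
  stopifnot(inherits(protocol, "voltage_protocol"))
  obj <- list(
    name = protocol$name,
    n_sweeps = protocol$n_sweeps,
    inter_sweep_interval = protocol$inter_sweep_interval,
    variable_interpulse = protocol$variable_interpulse,
    pulse_duration = protocol$pulse_duration,
    n_pulses = protocol$n_pulses,
    signal = protocol$signal,
    segments = lapply(protocol$segments, function(s)
      list(level = s$level, duration = s$duration,
           per_sweep_increment = s$per_sweep_increment, role = s$role))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_protocol_json
#' @export
read_protocol_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  segs <- lapply(obj$segments, function(s)
    protocol_segment(unlist(s$level), s$duration, s$per_sweep_increment,
                     s$role))
  voltage_protocol(obj$name, segs, n_sweeps = obj$n_sweeps,
                   inter_sweep_interval = obj$inter_sweep_interval,
                   variable_interpulse = obj$variable_interpulse,
                   pulse_duration = obj$pulse_duration,
                   n_pulses = obj$n_pulses,
                   signal = obj$signal)
}

#' Serialize / restore a drug model as YAML
#'
#' @param drug A [drug_model()].
#' @param path Output file path.
#' @return `write_drug_yaml` returns `path` invisibly; `read_drug_yaml`
#'   returns a [drug_model()].
#' @export
write_drug_yaml <- function(drug, path) {
  stopifnot(inherits(drug, "drug_model"))
  obj <- list(
    name = drug$name,
    channels = stats::setNames(
      lapply(seq_len(nrow(drug$channels)), function(i)
        list(ic50 = drug$channels$ic50[i], n_h = drug$channels$n_h[i])),
      drug$channels$channel),
    nav_rates = list(k_ob = drug$k_ob, k_ob_inv = drug$k_ob_inv,
                     k_ib = drug$k_ib, k_ib_inv = drug$k_ib_inv),
    c_max = drug$c_max,
    free_fraction = drug$free_fraction
  )
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_drug_yaml
#' @export
read_drug_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  ch <- data.frame(
    channel = names(obj$channels),
    ic50 = vapply(obj$channels, function(x) as.numeric(x$ic50), numeric(1)),
    n_h = vapply(obj$channels, function(x) as.numeric(x$n_h), numeric(1)),
    row.names = NULL
  )
  drug_model(obj$name, ch,
             k_ob = obj$nav_rates$k_ob, k_ob_inv = obj$nav_rates$k_ob_inv,
             k_ib = obj$nav_rates$k_ib, k_ib_inv = obj$nav_rates$k_ib_inv,
             c_max = if (is.null(obj$c_max)) NA_real_ else obj$c_max,
             free_fraction = obj$free_fraction)
}
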