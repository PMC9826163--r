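#' Force trace container
#'
#' A uniformly sampled isometric tension recording: time in seconds,
#' force in milliNewtons, with the sampling rate and region metadata.
#'
#' @param time Numeric vector of sample times (s); strictly increasing and
#'   uniform to within 1e-9 relative.
#' @param force Numeric vector of tension (mN); finite, same length.
#' @param fs Sampling rate (Hz); inferred from `time` when `NULL`.
#' @param metadata Named list (e.g. `region`, `tissue_id`, `schedule`).
#' @return An object of class `force_trace`.
#' @export
force_trace <- function(time, force, fs = NULL, metadata = list()) {
  if (!is.numeric(time) || !is.numeric(force))
    stop_domain("time and force must be numeric")
  if (length(time) != length(force))
    stop_domain("time and force must have equal length")
  if (length(time) < 2L) stop_domain("a force trace needs at least 2 samples")
  if (any(!is.finite(force))) stop_domain("force contains non-finite values")
  dt <- diff(time)
  if (any(dt <= 0)) {
    i <- which(dt <= 0)[1]
    stop_domain("time must be strictly increasing (violated at index ", i + 1L, ")")
  }
  dt_med <- stats::median(dt)
  bad <- which(abs(dt - dt_med) > 1e-9 * max(1, abs(dt_med)) + 1e-12)
  if (length(bad))
    stop_domain("non-uniform sampling at index ", bad[1] + 1L,
                " (dt = ", format(dt[bad[1]]), ", expected ", format(dt_med), ")")
  fs <- fs %||% (1 / dt_med)
  structure(list(time = as.numeric(time), force = as.numeric(force),
                 fs = fs, metadata = metadata),
            class = "force_trace")
}

#' @export
print.force_trace <- function(x, ...) {
  cat(sprintf("Force trace: %d samples, %.1f s at %.4g Hz; force %.2f-%.2f mN\n",
              length(x$time), x$time[length(x$time)] - x$time[1], x$fs,
              min(x$force), max(x$force)))
  if (!is.null(x$metadata$region)) cat("  region:", x$metadata$region, "\n")
  invisible(x)
}

#' Read / write force traces as delimited text
#'
#' The on-disk format is a two-column delimited file `time_s,force_mN`
#' with one header line; values are written with 10 significant digits so
#' a write/read round trip is lossless to numerical noise.
#'
#' @param path File path.
#' @param dialect Field separator: `"comma"` (default) or `"tab"`.
#' @param trace A [force_trace()].
#' @return `read_trace` returns a validated [force_trace()] with `fs`
#'   inferred from the median time step; `write_trace` invisibly returns
#'   `path`.
#' @export
read_trace <- function(path, dialect = c("comma", "tab")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "comma") "," else "\t"
  if (!file.exists(path)) stop_domain("file not found: ", path)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep,
                      colClasses = "numeric", col.names = c("time_s", "force_mN")),
    error = function(e) stop_domain("parse error in '", path, "': ",
                                    conditionMessage(e)))
  force_trace(df$time_s, df$force_mN)
}

#' @rdname read_trace
#' @export
write_trace <- function(trace, path, dialect = c("comma", "tab")) {
  stopifnot(inherits(trace, "force_trace"))
  dialect <- match.arg(dialect)
  sep <- if (dialect == "comma") "," else "\t"
  df <- data.frame(time_s = sprintf("%.10g", trace$time),
                   force_mN = sprintf("%.10g", trace$force))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

# canonical event-table columns (units in names where they are fixed)
EVENT_COLUMNS <- c("onset_s", "peak_s", "offset_s", "C_mN", "D_s", "E_s",
                   "F_s", "G", "H", "AUC_total", "rate_dev", "rate_decay")

#' Write / read a detected-event feature table
#'
#' Columns are exactly `onset_s, peak_s, offset_s, C_mN, D_s, E_s, F_s,
#' G, H, AUC_total, rate_dev, rate_decay`. Areas G, H and AUC_total are
#' in mN.s; rates in mN/s.
#'
#' @param events A data frame of events with features, as returned by
#'   [extract_features()] applied over [detect_contractions()]; an empty
#'   data frame writes a header-only file.
#' @param path File path.
#' @export
write_events <- function(events, path) {
  if (is.null(events) || nrow(events) == 0L) {
    writeLines(paste(EVENT_COLUMNS, collapse = ","), path)
    return(invisible(path))
  }
  missing_cols <- setdiff(EVENT_COLUMNS, names(events))
  if (length(missing_cols))
    stop_domain("event table lacks columns: ", paste(missing_cols, collapse = ", "))
  out <- events[, EVENT_COLUMNS]
  out[] <- lapply(out, function(v) sprintf("%.10g", v))
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, colClasses = "numeric")
  if (!identical(names(df), EVENT_COLUMNS))
    stop_domain("unexpected event-table columns in '", path, "'")
  df
}

#' Treatment schedule
#'
#' Ordered bath additions. Cumulative additions of a substance must be
#' strictly increasing in concentration (cumulative concentration-response
#' protocol); times non-decreasing.
#'
#' @param time_s Addition times (s).
#' @param substance Substance names.
#' @param conc_M Bath concentrations after the addition (M); > 0.
#' @param mode `"cumulative"` (default) or `"single"` per addition.
#' @return A data frame of class `treatment_schedule`.
#' @export
treatment_schedule <- function(time_s, substance, conc_M,
                               mode = "cumulative") {
  n <- length(time_s)
  time_s <- as.numeric(time_s)
  conc_M <- as.numeric(conc_M)
  if (length(substance) == 1L) substance <- rep_len(substance, n)
  if (length(substance) != n || length(conc_M) != n)
    stop_domain("schedule columns must have equal length")
  mode <- rep_len(mode, n)
  if (!all(mode %in% c("cumulative", "single")))
    stop_domain("mode must be 'cumulative' or 'single'")
  if (n > 1 && any(diff(time_s) < 0)) stop_domain("schedule times must be non-decreasing")
  if (any(conc_M <= 0)) stop_domain("concentrations must be > 0")
  for (s in unique(substance)) {
    idx <- which(substance == s & mode == "cumulative")
    if (length(idx) > 1 && any(diff(conc_M[idx]) <= 0))
      stop_domain("cumulative additions of '", s,
                  "' must be strictly increasing in concentration")
  }
  structure(data.frame(time_s = time_s, substance = substance,
                       conc_M = conc_M, mode = mode,
                       stringsAsFactors = FALSE),
            class = c("treatment_schedule", "data.frame"))
}

#' Read / write treatment schedules as JSON
#'
#' The on-disk form is a JSON array of `{time_s, substance, conc_M, mode}`
#' objects.
#'
#' @param schedule A [treatment_schedule()].
#' @param path File path.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "treatment_schedule"))
  jsonlite::write_json(as.data.frame(unclass(schedule)), path,
                       auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  treatment_schedule(df$time_s, df$substance, df$conc_M, df$mode)
}
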