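#' Tensile trace
#'
#' Container for one pull-to-failure test (or a no-specimen drag
#' baseline): time, crosshead extension and load sampled at the
#' acquisition rate.  Loads are stored in newtons; extension is the
#' crosshead displacement relative to the start of the test in mm.
#'
#' @param time Seconds, strictly increasing.
#' @param extension mm, non-decreasing, 0 at test start.
#' @param load Newtons.
#' @param specimen_id Text identifier.
#' @param is_baseline TRUE for a specimen-free drag trace.
#' @return Object of class `tensile_trace` (a list of equal-length
#'   numeric vectors plus metadata).
#' @export
tensile_trace <- function(time, extension, load, specimen_id = "specimen",
                          is_baseline = FALSE) {
  tr <- structure(list(time = as.numeric(time),
                       extension = as.numeric(extension),
                       load = as.numeric(load),
                       specimen_id = as.character(specimen_id),
                       is_baseline = isTRUE(is_baseline)),
                  class = "tensile_trace")
  validate_trace(tr)
  tr
}

#' Validate a tensile trace
#'
#' Checks equal array lengths (>= 2), strictly increasing time and
#' non-decreasing extension; failures name the first offending index.
#'
#' @param trace A `tensile_trace`.
#' @return The trace, invisibly, if valid.
#' @export
validate_trace <- function(trace) {
  stopifnot(inherits(trace, "tensile_trace"))
  n <- length(trace$time)
  if (n < 2 || length(trace$extension) != n || length(trace$load) != n)
    stop("trace arrays must have equal length >= 2")
  if (anyNA(trace$time) || anyNA(trace$extension) || anyNA(trace$load))
    stop("trace contains NA values")
  dtime <- diff(trace$time)
  if (any(dtime <= 0)) {
    i <- which(dtime <= 0)[1]
    stop(sprintf("time must be strictly increasing; violation at index %d", i + 1L))
  }
  dext <- diff(trace$extension)
  if (any(dext < 0)) {
    i <- which(dext < 0)[1]
    stop(sprintf("extension must be non-decreasing; violation at index %d", i + 1L))
  }
  invisible(trace)
}

#' Read a tensile trace from CSV
#'
#' Expects a header with columns `time_s`, `extension_mm`, and either
#' `load_N` or `load_mN` (mN is converted to N on read).  Rows with
#' non-finite values are dropped with a message reporting the count.
#'
#' @param path CSV file path.
#' @param specimen_id Identifier; defaults to the file name sans extension.
#' @param is_baseline Mark as drag baseline.
#' @return A validated [tensile_trace()].
#' @export
read_trace <- function(path, specimen_id = NULL, is_baseline = FALSE) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("time_s", "extension_mm")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("trace file missing column(s): ", paste(miss, collapse = ", "))
  if ("load_N" %in% names(df)) {
    load <- df$load_N
  } else if ("load_mN" %in% names(df)) {
    load <- df$load_mN / 1000
  } else {
    stop("trace file missing column(s): load_N (or load_mN)")
  }
  keep <- is.finite(df$time_s) & is.finite(df$extension_mm) & is.finite(load)
  if (!all(keep))
    message(sum(!keep), " non-finite row(s) dropped from ", basename(path))
  if (is.null(specimen_id))
    specimen_id <- sub("\\.[^.]*$", "", basename(path))
  tensile_trace(df$time_s[keep], df$extension_mm[keep], load[keep],
                specimen_id = specimen_id, is_baseline = is_baseline)
}

#' Write a tensile trace to CSV
#'
#' @param trace A `tensile_trace`.
#' @param path Output path.
#' @param load_units `"N"` (default) or `"mN"`.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, load_units = c("N", "mN")) {
  load_units <- match.arg(load_units)
  validate_trace(trace)
  df <- data.frame(time_s = trace$time, extension_mm = trace$extension)
  if (load_units == "N") df$load_N <- trace$load else df$load_mN <- trace$load * 1000
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write / read per-specimen mechanical summaries
#'
#' One row per specimen with columns `specimen_id, uts_mpa, mtm_mpa,
#' failure_strain, failure_detected, a0_mm2, area_convention,
#' gauge_length_mm, stress_convention`.
#'
#' @param records A data.frame of summaries (as produced by
#'   [analyze_trace()] rows or [run_experiment()]).
#' @param path CSV path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_summary <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0)
    stop("records must be a non-empty data.frame")
  cols <- c("specimen_id", "uts_mpa", "mtm_mpa", "failure_strain",
            "failure_detected", "a0_mm2", "area_convention",
            "gauge_length_mm", "stress_convention")
  miss <- setdiff(cols, names(records))
  if (length(miss)) stop("summary missing column(s): ", paste(miss, collapse = ", "))
  utils::write.csv(records[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_summary
#' @export
read_summary <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @export
print.tensile_trace <- function(x, ...) {
  cat(sprintf("Tensile trace '%s'%s: %d samples, %.1f s, %.3f mm extension, peak load %.4f N\n",
              x$specimen_id, if (x$is_baseline) " (drag baseline)" else "",
              length(x$time), max(x$time) - min(x$time),
              max(x$extension), max(x$load)))
  invisible(x)
}
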