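# Plain-text I/O: 2-column trace CSVs (header time_s,value; optional aux
# third column for TTL) and ground-truth JSON.

#' Write a trace to CSV
#'
#' Diameter traces are written as `time_s,value`; voltage traces add an
#' `aux` column when a TTL channel is present.
#'
#' @param trace A [diameter_trace()] or [voltage_trace()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  if (inherits(trace, "diameter_trace")) {
    df <- data.frame(time_s = trace$t, value = trace$d)
  } else if (inherits(trace, "voltage_trace")) {
    df <- data.frame(time_s = trace$t, value = trace$v)
    if (!is.null(trace$aux)) df$aux <- trace$aux
  } else {
    stop("unsupported trace class", call. = FALSE)
  }
  data.table::fwrite(df, path)
  invisible(path)
}

#' Read a diameter trace from CSV
#'
#' @param path CSV with columns `time_s,value` (diameter in um).
#' @param fps Sampling rate; inferred from the time column when `NULL`.
#' @return A [diameter_trace()].
#' @export
read_diameter_csv <- function(path, fps = NULL) {
  df <- data.table::fread(path)
  if (!all(c("time_s", "value") %in% names(df))) {
    stop("expected columns time_s,value in ", path, call. = FALSE)
  }
  if (is.null(fps)) fps <- 1 / stats::median(diff(df$time_s))
  diameter_trace(df$time_s, df$value, fps, provenance = path)
}

#' Read a voltage trace from CSV
#'
#' @param path CSV with columns `time_s,value` (mV) and optional `aux`.
#' @param rate Sampling rate; inferred from the time column when `NULL`.
#' @return A [voltage_trace()].
#' @export
read_voltage_csv <- function(path, rate = NULL) {
  df <- data.table::fread(path)
  if (!all(c("time_s", "value") %in% names(df))) {
    stop("expected columns time_s,value in ", path, call. = FALSE)
  }
  if (is.null(rate)) rate <- 1 / stats::median(diff(df$time_s))
  voltage_trace(df$time_s, df$value, rate,
                aux = if ("aux" %in% names(df)) df$aux else NULL)
}

#' Write ground truth to JSON
#'
#' @param gt A `ground_truth` from [make_beat_schedule()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(gt, path) {
  stopifnot(inherits(gt, "ground_truth"))
  spec <- unclass(gt$spec)
  jsonlite::write_json(
    list(spec = spec, beats = gt$beats, ap_events = gt$ap_events,
         ttl_window = gt$ttl_window),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read ground truth from JSON
#'
#' @param path A file written by [write_ground_truth_json()].
#' @return A `ground_truth` object.
#' @export
read_ground_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- x$spec
  for (f in c("di_dist", "si_dist", "peaks_per_burst_dist")) {
    spec[[f]] <- as.numeric(spec[[f]])
  }
  spec$seed <- as.integer(spec$seed)
  class(spec) <- "synth_spec"
  structure(list(beats = as.data.frame(x$beats),
                 ap_events = as.data.frame(x$ap_events),
                 ttl_window = as.numeric(x$ttl_window),
                 spec = spec),
            class = "ground_truth")
}
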