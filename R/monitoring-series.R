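#' @keywords internal
"_PACKAGE"

# Variables measured at an automatic air monitoring station. Concentrations in
# ug/m3 except CO (mg/m3); WS m/s, T degC, I W/m2, RH %.
AQ_VARIABLES <- c("O3", "NO", "NO2", "SO2", "CO", "PM10", "WS", "T", "I", "RH")
AQ_CONCENTRATIONS <- c("O3", "NO", "NO2", "SO2", "CO", "PM10")

#' Construct an hourly monitoring series
#'
#' A monitoring series is a data frame with a `timestamp` column (POSIXct,
#' strictly increasing, exactly 1 h spacing) and one numeric column per
#' measured variable. Missing measurements are `NA`. Concentrations must be
#' non-negative and relative humidity within \[0, 100\].
#'
#' Timestamps are handled as fixed-offset local time (stored as UTC); daylight
#' saving transitions are not modelled, matching the fixed hourly cadence of
#' monitoring archives.
#'
#' @param timestamps POSIXct vector, hourly grid.
#' @param values data frame or named list of numeric vectors, names drawn from
#'   `O3, NO, NO2, SO2, CO, PM10, WS, T, I, RH`.
#' @param station_id character label for the station.
#' @return A `monitoring_series` object (data frame).
#' @export
monitoring_series <- function(timestamps, values, station_id = "station") {
  values <- as.data.frame(values, optional = TRUE)
  unknown <- setdiff(names(values), AQ_VARIABLES)
  if (length(unknown) > 0) {
    stop("unknown variable name(s): ", paste(unknown, collapse = ", "))
  }
  if (!inherits(timestamps, "POSIXct")) {
    timestamps <- as.POSIXct(timestamps, tz = "UTC")
  }
  x <- data.frame(timestamp = timestamps, values)
  names(x) <- c("timestamp", names(values))
  attr(x, "station_id") <- station_id
  class(x) <- c("monitoring_series", "data.frame")
  validate_monitoring_series(x)
}

#' Validate a monitoring series
#'
#' Checks the hourly-grid, non-negativity and humidity-range invariants; stops
#' with an informative error on the first violation.
#'
#' @param x a `monitoring_series`.
#' @return `x`, invisibly unchanged, if valid.
#' @export
validate_monitoring_series <- function(x) {
  ts <- x$timestamp
  if (anyDuplicated(ts)) {
    first_dup <- ts[duplicated(ts)][1]
    stop("duplicate timestamp: ", format(first_dup, "%Y-%m-%d %H:%M", tz = "UTC"))
  }
  if (length(ts) > 1) {
    d <- diff(as.numeric(ts))
    if (any(d != 3600)) {
      stop("timestamps are not a strict 1-hour grid (first bad step at index ",
           which(d != 3600)[1], ")")
    }
  }
  for (v in intersect(names(x), AQ_CONCENTRATIONS)) {
    if (any(x[[v]] < 0, na.rm = TRUE)) {
      stop("negative ", v, " concentration at ",
           format(ts[which(x[[v]] < 0)[1]], "%Y-%m-%d %H:%M", tz = "UTC"))
    }
  }
  if ("RH" %in% names(x) &&
      any(x$RH < 0 | x$RH > 100, na.rm = TRUE)) {
    stop("RH outside [0, 100]")
  }
  x
}

#' Read an hourly monitoring CSV
#'
#' Reads a CSV with a header row, an ISO-8601 timestamp column and one column
#' per measured variable. Unparseable numeric cells (empty, `NA`, text) become
#' missing values. Gaps in the hourly grid are filled with all-missing rows so
#' the 1-hour spacing invariant holds. Duplicate timestamps are a hard error.
#'
#' @param path CSV file path.
#' @param schema named character vector mapping variable names (`O3`, `NO`,
#'   ...) to CSV column names; the special name `timestamp` maps the time
#'   column (default column `timestamp`).
#' @param station_id station label recorded in the result.
#' @return A [monitoring_series()].
#' @export
read_monitoring_csv <- function(path, schema = NULL, station_id = "station") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  ts_col <- "timestamp"
  if (!is.null(schema) && "timestamp" %in% names(schema)) {
    ts_col <- schema[["timestamp"]]
    schema <- schema[setdiff(names(schema), "timestamp")]
  }
  if (is.null(schema)) {
    vars <- intersect(names(raw), AQ_VARIABLES)
    schema <- stats::setNames(vars, vars)
  }
  unknown <- setdiff(names(schema), AQ_VARIABLES)
  if (length(unknown) > 0) {
    stop("unknown variable name(s) in schema: ", paste(unknown, collapse = ", "))
  }
  missing_cols <- setdiff(unname(c(ts_col, schema)), names(raw))
  if (length(missing_cols) > 0) {
    stop("column(s) not in file: ", paste(missing_cols, collapse = ", "))
  }
  ts <- as.POSIXct(raw[[ts_col]], tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%dT%H:%M",
                                  "%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M"))
  if (anyNA(ts)) stop("unparseable timestamp at row ", which(is.na(ts))[1])
  if (anyDuplicated(ts)) {
    stop("duplicate timestamp: ",
         format(ts[duplicated(ts)][1], "%Y-%m-%d %H:%M", tz = "UTC"))
  }
  vals <- lapply(unname(schema), function(col) {
    suppressWarnings(as.numeric(raw[[col]]))
  })
  names(vals) <- names(schema)
  # complete the hourly grid with all-missing rows
  ord <- order(ts)
  ts <- ts[ord]
  vals <- lapply(vals, function(v) v[ord])
  grid <- seq(ts[1], ts[length(ts)], by = 3600)
  idx <- match(grid, ts)
  vals <- lapply(vals, function(v) v[idx])
  monitoring_series(grid, vals, station_id = station_id)
}

#' Write a monitoring series as CSV
#'
#' Inverse of [read_monitoring_csv()]: ISO-8601 timestamps, empty cells for
#' missing values.
#'
#' @param x a `monitoring_series`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_monitoring_csv <- function(x, path) {
  out <- as.data.frame(x)
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.monitoring_series <- function(x, ...) {
  vars <- setdiff(names(x), "timestamp")
  compl <- vapply(vars, function(v) mean(!is.na(x[[v]])), numeric(1))
  cat("<monitoring_series> station:", attr(x, "station_id"),
      "| hours:", nrow(x), "\n")
  cat(" span:", format(x$timestamp[1], "%Y-%m-%d %H:%M", tz = "UTC"), "..",
      format(x$timestamp[nrow(x)], "%Y-%m-%d %H:%M", tz = "UTC"), "\n")
  cat(" completeness:",
      paste(sprintf("%s %.1f%%", vars, 100 * compl), collapse = ", "), "\n")
  invisible(x)
}
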