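#' Encode a timestamp as numeric day and hour
#'
#' Monitoring cases carry two numeric time variables, D (day) and H (hour).
#' Two conventions are supported:
#' \describe{
#'   \item{`linear`}{D = day of year (1-366), H = hour of day (0-23). Default.}
#'   \item{`cosine`}{cyclic encoding: D = -cos(2 pi (doy - 1) / 365.25),
#'     peaking at mid-year, and H = -cos(2 pi hour / 24), peaking at midday;
#'     both in \[-1, 1\]. Removes the artificial discontinuity at year/day
#'     boundaries at the cost of aliasing symmetric dates/hours.}
#' }
#'
#' @param timestamps POSIXct vector.
#' @param convention `"linear"` or `"cosine"`.
#' @return data frame with numeric columns `D` and `H`.
#' @export
encode_time <- function(timestamps, convention = c("linear", "cosine")) {
  convention <- match.arg(convention)
  lt <- as.POSIXlt(timestamps, tz = "UTC")
  doy <- lt$yday + 1
  hr <- lt$hour
  if (convention == "linear") {
    data.frame(D = as.numeric(doy), H = as.numeric(hr))
  } else {
    data.frame(D = -cos(2 * pi * (doy - 1) / 365.25),
               H = -cos(2 * pi * hr / 24))
  }
}

#' Expected number of hourly cases in a closed date range
#'
#' The size a gap-free hourly record would have: 24 hours for every calendar
#' day from `start_date` to `end_date` inclusive.
#'
#' @param start_date,end_date coercible to `Date`; `start_date <= end_date`.
#' @return integer hour count.
#' @examples
#' expected_case_count("2011-01-01", "2016-12-31") # 52608
#' @export
expected_case_count <- function(start_date, end_date) {
  s <- as.Date(start_date)
  e <- as.Date(end_date)
  if (e < s) stop("end_date precedes start_date")
  as.integer((as.integer(e) - as.integer(s) + 1L) * 24L)
}
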