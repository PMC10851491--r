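# Calendar helpers. Daymet-style gridded meteorology uses 365-day years:
# December 31 is absent in leap years. The exposure panel inherits that gap,
# which is what drives the "incomplete lag window" record exclusion.

.isLeapYear <- function(year) {
  (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
}

#' Daily dates on a Daymet-style 365-day calendar
#'
#' All calendar dates in the given years except December 31 of leap years,
#' mirroring the 365-day convention of 1-km gridded daily meteorology
#' products.
#'
#' @param years Integer vector of calendar years.
#' @return Sorted `Date` vector.
#' @examples
#' d <- daymetDates(2004)
#' length(d)          # 365, not 366
#' @export
daymetDates <- function(years) {
  years <- sort(unique(as.integer(years)))
  d <- seq(as.Date(paste0(min(years), "-01-01")),
           as.Date(paste0(max(years), "-12-31")), by = "day")
  d <- d[as.integer(format(d, "%Y")) %in% years]
  d[!(.isLeapDec31(d))]
}

.isLeapDec31 <- function(dates) {
  y <- as.integer(format(dates, "%Y"))
  format(dates, "%m-%d") == "12-31" & .isLeapYear(y)
}

#' Lagged moving averages over a daily series with calendar gaps
#'
#' The k-day moving average at date d is the unweighted mean of lags
#' 0..k-1 (dates d-k+1 .. d). A window containing any calendar date absent
#' from `dates` (e.g. December 31 of a leap year on a 365-day calendar, or a
#' date before the series starts) yields `NA`.
#'
#' @param x Numeric matrix (units x dates) or vector, ordered as `dates`.
#' @param dates `Date` vector labelling the columns (or elements) of `x`.
#' @param k Window length in days, 1..5; `k = 1` returns `x` unchanged.
#' @return Object shaped like `x` holding the moving averages.
#' @export
movingAverage <- function(x, dates, k) {
  stopifnot(k %in% 1:5)
  dates <- as.Date(dates)
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1L)
  stopifnot(ncol(x) == length(dates), !is.unsorted(dates))
  if (k == 1L) return(if (vec) x[1L, ] else x)
  full <- seq(min(dates), max(dates), by = "day")
  pos <- match(dates, full)
  wide <- matrix(NA_real_, nrow(x), length(full))
  wide[, pos] <- x
  acc <- wide
  for (lag in seq_len(k - 1L)) {
    shifted <- cbind(matrix(NA_real_, nrow(x), lag),
                     wide[, seq_len(ncol(wide) - lag), drop = FALSE])
    acc <- acc + shifted
  }
  ma <- acc / k
  out <- ma[, pos, drop = FALSE]
  if (vec) out[1L, ] else out
}
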