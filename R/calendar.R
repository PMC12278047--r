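# 365-day no-leap calendar helpers. Day-of-year runs 1..365; the sample for day
# d is centred at time d - 0.5 days, so decimal year = year + (doy - 0.5)/365.

#' Month lengths of the 365-day no-leap calendar
#'
#' @return Integer vector of length 12 summing to 365.
#' @export
noleap_month_lengths <- function() {
  c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
}

.month_bounds <- function() {
  len <- noleap_month_lengths()
  end <- cumsum(len)
  list(start = c(1L, utils::head(end, -1L) + 1L), end = end, len = len)
}

#' Month index (1-12) for each day of a no-leap year
#' @return Integer vector of length 365.
#' @export
month_of_doy <- function() {
  rep.int(seq_len(12L), noleap_month_lengths())
}

#' Month midpoints in day-centre coordinates
#'
#' Midpoint of month m is the mean of the day centres (d - 0.5) it contains;
#' used as the anchor grid when interpolating monthly values to day of year.
#'
#' @return Numeric vector of length 12 (e.g. January = 15.5).
#' @export
month_midpoints <- function() {
  b <- .month_bounds()
  (b$start + b$end) / 2 - 0.5
}

#' Decimal year of a (year, day-of-year) pair on the no-leap calendar
#'
#' @param year Integer year(s).
#' @param doy Day(s) of year in 1..365.
#' @return `year + (doy - 0.5) / 365`.
#' @export
decimal_year <- function(year, doy) {
  stopifnot(all(doy >= 1), all(doy <= 365))
  year + (doy - 0.5) / 365
}

# decimal year at each month midpoint of `year`
.decimal_year_month <- function(year, month) {
  mid <- month_midpoints()
  year + mid[month] / 365
}

# time vectors for a span of years at daily resolution
.daily_axis <- function(years) {
  yy <- seq.int(years[1], years[2])
  list(
    year = rep(yy, each = 365L),
    doy = rep.int(1:365, length(yy)),
    n = 365L * length(yy)
  )
}

.monthly_axis <- function(years) {
  yy <- seq.int(years[1], years[2])
  list(
    year = rep(yy, each = 12L),
    month = rep.int(1:12, length(yy)),
    n = 12L * length(yy)
  )
}

# Linear interpolation of 12 monthly anchor values to arbitrary day-centre
# times `at` (in [0, 365)), periodic in the year.  Anchors sit at the month
# midpoints; the wrap pads December before January and vice versa.
.interp_months <- function(monthly, at) {
  stopifnot(length(monthly) == 12L)
  mid <- month_midpoints()
  x <- c(mid[12L] - 365, mid, mid[1L] + 365)
  y <- c(monthly[12L], monthly, monthly[1L])
  stats::approx(x, y, xout = at, method = "linear")$y
}

# 365-vector of the interpolant at day centres d - 0.5
.interp_months_doy <- function(monthly) {
  .interp_months(monthly, (1:365) - 0.5)
}

# Mean of cos(2*pi*(d - phase)/365) over the days of each calendar month, for a
# vector of phases; returns a 12 x length(phase) matrix.  Exact discrete sums.
.month_mean_cos <- function(phase) {
  b <- .month_bounds()
  out <- matrix(0, 12L, length(phase))
  for (m in 1:12) {
    d <- b$start[m]:b$end[m]
    ang <- outer(d, phase, function(d, p) 2 * pi * (d - p) / 365)
    out[m, ] <- colMeans(cos(ang))
  }
  out
}
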