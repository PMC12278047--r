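# Percentile threshold machinery: the four quantile-threshold permutations
# (seasonally constant / seasonally varying x fixed / adaptive baseline), the
# annual-extreme monthly mean (AMM) percentile proxy, and extreme-day counting.

#' Order-statistic percentile with linear interpolation
#'
#' Linear interpolation between order statistics (R's default type-7
#' estimator); `p = 50` equals the median, `p = 100` the maximum.
#'
#' @param x Numeric values (NA dropped).
#' @param p Percentile level(s) in \[0, 100\].
#' @return Percentile value(s).
#' @export
percentile <- function(x, p) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop("percentile of an empty (or all-missing) sample")
  stopifnot(all(p >= 0), all(p <= 100))
  unname(stats::quantile(x, probs = p / 100, type = 7, names = FALSE))
}

# column-wise type-7 quantile of a matrix at a single level (vectorised)
.col_percentile <- function(m, p) {
  n <- nrow(m)
  s <- apply(m, 2L, sort) # columns must be NA-free
  h <- (n - 1) * p / 100 + 1
  lo <- floor(h); fr <- h - lo
  q <- s[lo, ]
  if (fr > 0) q <- q + fr * (s[pmin(lo + 1, n), ] - q)
  q
}

# circular Gaussian smoothing over day of year; x is 365 x ncell
.gauss_smooth_circ <- function(x, sigma = 10, trunc = 4) {
  if (sigma <= 0) return(x)
  K <- ceiling(trunc * sigma)
  off <- -K:K
  w <- exp(-off^2 / (2 * sigma^2))
  w <- w / sum(w)
  out <- x * 0
  for (j in seq_along(off)) {
    idx <- ((seq_len(365L) - 1L + off[j]) %% 365L) + 1L
    out <- out + w[j] * x[idx, , drop = FALSE]
  }
  out
}

.default_level <- function(tail) if (tail == "upper") 95 else 5

.threshold_field <- function(values, shape, level, field, reference) {
  structure(list(values = values, shape = shape, level = level,
                 variable = field$variable, units = field$units,
                 tail = field$tail, reference = reference,
                 lat = field$lat, lon = field$lon),
            class = "threshold_field")
}

#' @export
print.threshold_field <- function(x, ...) {
  cat(sprintf("<threshold_field> %s, %s, level %g, tail %s (%s)\n",
              x$variable, x$shape,
              x$level, x$tail, paste(unlist(x$reference), collapse = " ")))
  invisible(x)
}

#' Restrict a field to a year range
#' @param field `daily_field` or `monthly_archive`.
#' @param years Length-2 year range, contained in the field's coverage.
#' @return Field of the same class over `years`.
#' @export
subset_years <- function(field, years) {
  if (years[1] < field$years[1] || years[2] > field$years[2]) {
    stop("requested years ", years[1], "-", years[2],
         " not covered by field years ", field$years[1], "-", field$years[2])
  }
  per <- if (inherits(field, "daily_field")) 365L else 12L
  i0 <- (years[1] - field$years[1]) * per + 1L
  i1 <- (years[2] - field$years[1] + 1L) * per
  out <- field
  out$values <- field$values[i0:i1, , drop = FALSE]
  out$years <- as.integer(years)
  out
}

#' Fixed seasonally constant (SC) percentile threshold
#'
#' One constant per cell: the percentile of all daily values over the
#' reference period.  Applied back to its own reference period at level 95,
#' approximately 5% of days (730 of a 40-year segment) exceed it.
#'
#' @param daily A [daily_field()].
#' @param ref_years Reference period (default: the field's full coverage).
#' @param level Percentile level; default 95 for upper-tail variables, 5 for
#'   lower-tail.
#' @return A `threshold_field` with shape `"sc"`.
#' @export
fit_fixed_sc <- function(daily, ref_years = NULL, level = NULL) {
  stopifnot(inherits(daily, "daily_field"))
  if (is.null(ref_years)) ref_years <- daily$years
  if (is.null(level)) level <- .default_level(daily$tail)
  ref <- subset_years(daily, ref_years)
  .threshold_field(.col_percentile(ref$values, level), "sc", level, daily,
                   list(type = "fixed", years = ref_years))
}

#' Fixed seasonally varying (SV) threshold, five-day-bin variant
#'
#' The model year is divided into `bin_days`-day bins, the percentile is
#' estimated within each bin, and the binned levels are interpolated back to
#' 365-day resolution by a circular Gaussian filter (10-day timescale).
#' Because each bin has its own level, this variant tracks seasonal
#' differences in variance as well as in the mean, yielding the most uniform
#' seasonal distribution of extreme days.
#'
#' @inheritParams fit_fixed_sc
#' @param bin_days Bin width in days; must divide 365 (default 5).
#' @param smooth_sd Gaussian smoothing timescale in days (default 10).
#' @return A `threshold_field` with shape `"sv"` (365 x cell values).
#' @export
fit_fixed_sv_binned <- function(daily, ref_years = NULL, level = NULL,
                                bin_days = 5L, smooth_sd = 10) {
  stopifnot(inherits(daily, "daily_field"))
  if (365L %% bin_days != 0L) stop("bin_days must divide 365")
  if (is.null(ref_years)) ref_years <- daily$years
  if (is.null(level)) level <- .default_level(daily$tail)
  ref <- subset_years(daily, ref_years)
  doy <- .daily_axis(ref_years)$doy
  bin <- (doy - 1L) %/% bin_days + 1L
  nbin <- 365L %/% bin_days
  binq <- matrix(0, nbin, ncol(ref$values))
  for (b in seq_len(nbin)) {
    binq[b, ] <- .col_percentile(ref$values[bin == b, , drop = FALSE], level)
  }
  sv <- binq[rep(seq_len(nbin), each = bin_days), , drop = FALSE]
  sv <- .gauss_smooth_circ(sv, smooth_sd)
  .threshold_field(sv, "sv", level, daily,
                   list(type = "fixed", years = ref_years))
}

# smoothed day-of-year climatology of a daily field over its own years
.doy_climatology <- function(values, doy, smooth_sd = 10) {
  clim <- rowsum(values, doy, reorder = TRUE) /
    as.vector(table(doy))
  dimnames(clim) <- NULL
  .gauss_smooth_circ(clim, smooth_sd)
}

#' Fixed seasonally varying (SV) threshold, anomaly-percentile variant
#'
#' The mean seasonal cycle (day-of-year climatology, circularly smoothed with
#' the same 10-day Gaussian) is subtracted and a single percentile of the
#' anomalies is estimated for the whole period, irrespective of time of year;
#' the threshold is climatology + anomaly percentile.  Computationally
#' simpler than the binned variant and the natural basis for the adaptive SV
#' extension via monthly climatology differences.
#'
#' @inheritParams fit_fixed_sv_binned
#' @return A `threshold_field` with shape `"sv"`.
#' @export
fit_fixed_sv_anomaly <- function(daily, ref_years = NULL, level = NULL,
                                 smooth_sd = 10) {
  stopifnot(inherits(daily, "daily_field"))
  if (is.null(ref_years)) ref_years <- daily$years
  if (is.null(level)) level <- .default_level(daily$tail)
  ref <- subset_years(daily, ref_years)
  doy <- .daily_axis(ref_years)$doy
  clim <- .doy_climatology(ref$values, doy, smooth_sd)
  anom <- ref$values - clim[doy, , drop = FALSE]
  q <- .col_percentile(anom, level)
  sv <- sweep(clim, 2L, q, "+")
  .threshold_field(sv, "sv", level, daily,
                   list(type = "fixed", years = ref_years))
}

# per-day threshold matrix aligned with a daily field
.threshold_rows <- function(threshold, field) {
  n <- nrow(field$values)
  if (threshold$shape == "sc") {
    matrix(threshold$values, n, ncol(field$values), byrow = TRUE)
  } else {
    doy <- .daily_axis(field$years)$doy
    threshold$values[doy, , drop = FALSE]
  }
}

.extreme_mask <- function(mask, field, provenance) {
  pct <- 100 * colSums(mask, na.rm = TRUE) / colSums(!is.na(field$values))
  structure(list(mask = mask, percent = pct, variable = field$variable,
                 tail = field$tail, years = field$years,
                 lat = field$lat, lon = field$lon, provenance = provenance),
            class = "extreme_mask")
}

#' @export
print.extreme_mask <- function(x, ...) {
  cat(sprintf("<extreme_mask> %s, years %d-%d, mean %.2f%% of days (%s)\n",
              x$variable, x$years[1], x$years[2], mean(x$percent),
              x$provenance))
  invisible(x)
}

#' Count extreme days against a threshold
#'
#' A day is extreme when its value is strictly above (upper tail) or strictly
#' below (lower tail) the threshold; a value exactly at the threshold is not
#' extreme.  The summary is the percent of non-missing days per cell.
#'
#' @param daily A [daily_field()].
#' @param threshold A `threshold_field` for the same variable and grid.
#' @return An `extreme_mask` (daily logical matrix + per-cell percentages).
#' @export
count_extremes <- function(daily, threshold) {
  stopifnot(inherits(daily, "daily_field"),
            inherits(threshold, "threshold_field"))
  if (!identical(daily$tail, threshold$tail)) {
    stop("field tail (", daily$tail, ") does not match threshold tail (",
         threshold$tail, ")")
  }
  if (ncol(daily$values) != (if (threshold$shape == "sc")
    length(threshold$values) else ncol(threshold$values))) {
    stop("grid shape mismatch between field and threshold")
  }
  thr <- .threshold_rows(threshold, daily)
  mask <- if (daily$tail == "upper") daily$values > thr else daily$values < thr
  prov <- sprintf("%s %s p%g %s", daily$variable, threshold$shape,
                  threshold$level, threshold$reference$type)
  .extreme_mask(mask, daily, prov)
}

# --- AMM proxy ---------------------------------------------------------------

#' Annual extreme of monthly means (AMM series)
#'
#' Per cell and archive year, the maximum (`mode = "max"`, upper-tail
#' variables) or minimum (`mode = "min"`, lower-tail) of the 12 monthly
#' means: the AMM_max / AMM_min proxy series used for adaptive baselines
#' where only monthly data span the full archive.
#'
#' @param archive A [monthly_archive()].
#' @param mode `"max"` or `"min"`; default chosen from the archive's tail.
#' @return An `amm_series`: `values` (year x cell), `years`, `mode`.
#' @export
amm_series <- function(archive, mode = NULL) {
  stopifnot(inherits(archive, "monthly_archive"))
  if (is.null(mode)) mode <- if (archive$tail == "upper") "max" else "min"
  mode <- match.arg(mode, c("max", "min"))
  ax <- .monthly_axis(archive$years)
  ny <- diff(archive$years) + 1L
  f <- if (mode == "max") max else min
  vals <- matrix(0, ny, ncol(archive$values))
  for (y in seq_len(ny)) {
    block <- archive$values[ax$year == archive$years[1] + y - 1L, ,
                            drop = FALSE]
    vals[y, ] <- apply(block, 2L, f)
  }
  structure(list(values = vals, years = seq.int(archive$years[1],
                                                archive$years[2]),
                 mode = mode, variable = archive$variable,
                 lat = archive$lat, lon = archive$lon),
            class = "amm_series")
}

#' Calibrate the AMM percentile proxy against daily percentiles
#'
#' For each integer percentile level, compares the AMM (annual extreme of
#' monthly means) with that year's daily percentile, pooled over cells and
#' overlap years, reporting RMSE and bias; returns the RMSE-minimising
#' integer percentile.  On sinusoid + AR(1) fields the best level is near
#' 93-94 for `max` mode and 6-7 for `min` mode.
#'
#' @param daily A [daily_field()].
#' @param archive A [monthly_archive()] overlapping the daily years.
#' @param mode `"max"` or `"min"` (default from the field tail).
#' @param percentiles Candidate integer levels (default 50..99 for max,
#'   1..50 for min).
#' @return List with `best` (integer percentile) and `table` (data frame of
#'   percentile, rmse, bias).
#' @export
calibrate_amm_percentile <- function(daily, archive, mode = NULL,
                                     percentiles = NULL) {
  stopifnot(inherits(daily, "daily_field"), inherits(archive, "monthly_archive"))
  if (is.null(mode)) mode <- if (daily$tail == "upper") "max" else "min"
  y0 <- max(daily$years[1], archive$years[1])
  y1 <- min(daily$years[2], archive$years[2])
  if (y0 > y1) stop("no overlap between daily field and monthly archive")
  if (is.null(percentiles)) {
    percentiles <- if (mode == "max") 50:99 else 1:50
  }
  amm <- amm_series(subset_years(archive, c(y0, y1)), mode)
  d <- subset_years(daily, c(y0, y1))
  ny <- y1 - y0 + 1L
  ncell <- ncol(d$values)
  err_sum <- err_sq <- numeric(length(percentiles))
  for (y in seq_len(ny)) {
    block <- d$values[((y - 1L) * 365L + 1L):(y * 365L), , drop = FALSE]
    s <- apply(block, 2L, sort)
    for (i in seq_along(percentiles)) {
      h <- 364 * percentiles[i] / 100 + 1
      lo <- floor(h); fr <- h - lo
      q <- s[lo, ]
      if (fr > 0) q <- q + fr * (s[pmin(lo + 1, 365L), ] - q)
      e <- amm$values[y, ] - q
      err_sum[i] <- err_sum[i] + sum(e)
      err_sq[i] <- err_sq[i] + sum(e^2)
    }
  }
  n <- ny * ncell
  tab <- data.frame(percentile = percentiles,
                    rmse = sqrt(err_sq / n),
                    bias = err_sum / n)
  list(best = percentiles[which.min(tab$rmse)], table = tab)
}

#' Percentile rank attained by the AMM of an idealized sinusoidal year
#'
#' For a pure sinusoidal daily seasonal cycle over one 365-day year, computes
#' the maximum monthly mean and returns its percentile rank within the year's
#' daily distribution.  `months = "calendar"` uses the no-leap calendar
#' months and the empirical rank among the 365 daily values; `months =
#' "equal"` uses twelve equal-length months and ranks within the continuous
#' cosine distribution (closed form).  The rank is invariant to amplitude
#' scaling.
#'
#' @param phase_offset Day-of-year of the sinusoid maximum, in \[0, 365).
#' @param months `"calendar"` or `"equal"`.
#' @param amplitude Sinusoid amplitude (default 1; does not affect the rank).
#' @return Percentile rank in \[0, 100\].
#' @export
idealized_amm_percentile <- function(phase_offset, months = c("calendar",
                                                              "equal"),
                                     amplitude = 1) {
  months <- match.arg(months)
  stopifnot(phase_offset >= 0, phase_offset < 365, amplitude > 0)
  if (months == "calendar") {
    s <- amplitude * cos(2 * pi * ((1:365) - phase_offset) / 365)
    b <- .month_bounds()
    mm <- vapply(1:12, function(m) mean(s[b$start[m]:b$end[m]]), 0)
    100 * mean(s < max(mm))
  } else {
    w <- 365 / 12
    a <- (0:11) * w
    mm <- (365 / (2 * pi * w)) *
      (sin(2 * pi * (a + w - phase_offset) / 365) -
         sin(2 * pi * (a - phase_offset) / 365))
    # rank of amplitude * max(mm) within the amplitude-scaled cosine
    # distribution; the amplitude cancels
    100 * (1 - acos(min(max(mm), 1)) / pi)
  }
}

#' Sweep the idealized AMM percentile over phase offsets
#'
#' Uniformly sweeps the phase of [idealized_amm_percentile()] over \[0, 365)
#' and summarises the attained percentile rank.  With calendar months the
#' sweep mean is about 93.4; with equal-length months the mean/min/max are
#' about 93.4 / 90.4 / 95.2.
#'
#' @param n_phase Number of uniformly spaced phases (default 1460).
#' @param months `"calendar"` or `"equal"`.
#' @return List with `mean`, `min`, `max` and the per-phase `ranks`.
#' @export
idealized_amm_sweep <- function(n_phase = 1460L, months = "calendar") {
  phases <- seq(0, 365, length.out = n_phase + 1L)[-(n_phase + 1L)]
  r <- vapply(phases, idealized_amm_percentile, 0, months = months)
  list(mean = mean(r), min = min(r), max = max(r), ranks = r)
}

# --- adaptive baselines ------------------------------------------------------

.check_window <- function(archive, target_year, N) {
  w0 <- target_year - N; w1 <- target_year - 1L
  if (archive$years[1] > w0 || archive$years[2] < w1) {
    stop("monthly archive ", archive$years[1], "-", archive$years[2],
         " does not cover the adaptive window ", w0, "-", w1,
         " (no partial windows)")
  }
  c(w0, w1)
}

#' Adaptive seasonally constant threshold (rolling AMM mean)
#'
#' The threshold for a target year is the mean of the AMM series over the
#' preceding `N` archive years (window excludes the target year): the rolling
#' AMM window mean stands directly for the similarly windowed annual 95th/5th
#' percentile, so the effective level is about the 93rd-94th (upper) or
#' 6th-7th (lower) percentile.
#'
#' @param archive A [monthly_archive()].
#' @param target_year Year the threshold applies to.
#' @param N Window length in years (default 100).
#' @param mode `"max"`/`"min"` (default from the archive tail).
#' @return A `threshold_field`, shape `"sc"`, adaptive reference.
#' @export
adaptive_sc_threshold <- function(archive, target_year, N = 100L, mode = NULL) {
  stopifnot(inherits(archive, "monthly_archive"))
  w <- .check_window(archive, target_year, N)
  amm <- amm_series(subset_years(archive, w), mode)
  .threshold_field(colMeans(amm$values), "sc",
                   if (archive$tail == "upper") 95 else 5, archive,
                   list(type = "adaptive", window = N,
                        target_year = target_year))
}

# 12 x cell monthly climatology of an archive over a year range
.monthly_climatology <- function(archive, years) {
  a <- subset_years(archive, years)
  ax <- .monthly_axis(years)
  out <- rowsum(a$values, ax$month, reorder = TRUE) / (diff(years) + 1L)
  dimnames(out) <- NULL
  out
}

#' Adaptive seasonally varying threshold
#'
#' Adds to a fixed historical SV threshold the difference in monthly-mean
#' climatology between the rolling `N`-year window preceding the target year
#' and the historical reference period, interpolated to day of year (linear
#' between month midpoints, periodic wrap).
#'
#' @param hist_sv Historical SV `threshold_field` (from
#'   [fit_fixed_sv_anomaly()] over `hist_years`).
#' @param archive A [monthly_archive()] covering both windows.
#' @param hist_years Historical reference years of `hist_sv`.
#' @param target_year Year the threshold applies to.
#' @param N Window length in years (default 100).
#' @return A `threshold_field`, shape `"sv"`, adaptive reference.
#' @export
adaptive_sv_threshold <- function(hist_sv, archive, hist_years, target_year,
                                  N = 100L) {
  stopifnot(inherits(hist_sv, "threshold_field"), hist_sv$shape == "sv",
            inherits(archive, "monthly_archive"))
  w <- .check_window(archive, target_year, N)
  if (archive$years[1] > hist_years[1] || archive$years[2] < hist_years[2]) {
    stop("monthly archive does not cover the historical reference period")
  }
  delta <- .monthly_climatology(archive, w) -
    .monthly_climatology(archive, hist_years)
  ddoy <- apply(delta, 2L, .interp_months_doy)
  .threshold_field(hist_sv$values + ddoy, "sv", hist_sv$level, archive,
                   list(type = "adaptive", window = N,
                        target_year = target_year))
}

#' Count extreme days under a per-year adaptive baseline
#'
#' Applies [adaptive_sc_threshold()] or [adaptive_sv_threshold()] separately
#' for every year of the daily segment (each year referenced to its own
#' preceding `N`-year window) and assembles the daily extreme mask.
#'
#' @param daily A [daily_field()].
#' @param archive A [monthly_archive()] covering every window.
#' @param N Window length in years.
#' @param method `"sc"` or `"sv"`.
#' @param hist_sv,hist_years Required for `method = "sv"`: the historical SV
#'   threshold and its reference years.
#' @return An `extreme_mask`.
#' @export
count_extremes_adaptive <- function(daily, archive, N = 100L,
                                    method = c("sc", "sv"),
                                    hist_sv = NULL, hist_years = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(daily, "daily_field"))
  if (method == "sv" && (is.null(hist_sv) || is.null(hist_years))) {
    stop("method 'sv' requires hist_sv and hist_years")
  }
  mask <- daily$values * NA
  for (y in seq.int(daily$years[1], daily$years[2])) {
    thr <- if (method == "sc") {
      adaptive_sc_threshold(archive, y, N)
    } else {
      adaptive_sv_threshold(hist_sv, archive, hist_years, y, N)
    }
    rows <- ((y - daily$years[1]) * 365L + 1L):((y - daily$years[1] + 1L) * 365L)
    yearf <- daily
    yearf$values <- daily$values[rows, , drop = FALSE]
    yearf$years <- c(y, y)
    m <- count_extremes(yearf, thr)
    mask[rows, ] <- m$mask
  }
  mask <- mask > 0
  prov <- sprintf("%s %s adaptive N=%d", daily$variable, method, N)
  .extreme_mask(mask, daily, prov)
}
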