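# Coral-specific and absolute thresholds: degree heating weeks (DHW) thermal
# stress and fixed environmental thresholds (aragonite saturation, pCO2).

#' Detrended monthly SST climatology
#'
#' Per cell, fits an ordinary-least-squares linear trend in decimal year to
#' the monthly series over the reference years, adjusts every value to the
#' pivot year (`value + slope * (pivot - t)`), and takes month-wise means.
#' The climatology is exactly invariant to adding any linear-in-time field
#' anchored at the pivot.
#'
#' @param archive A [monthly_archive()].
#' @param ref_years Reference period (default 1975-2014 intersected with the
#'   archive, i.e. the archive's coverage if narrower).
#' @param pivot Decimal pivot year (default 1988.2857).
#' @return 12 x cell matrix of climatological monthly means.
#' @export
detrended_monthly_climatology <- function(archive, ref_years = NULL,
                                          pivot = 1988.2857) {
  stopifnot(inherits(archive, "monthly_archive"))
  if (is.null(ref_years)) ref_years <- archive$years
  a <- subset_years(archive, ref_years)
  if (diff(ref_years) < 1L) stop("need at least 2 years to fit a trend")
  ax <- .monthly_axis(ref_years)
  t <- .decimal_year_month(ax$year, ax$month)
  X <- cbind(1, t)
  beta <- stats::lm.fit(X, a$values)$coefficients # 2 x ncell
  adj <- a$values + outer(pivot - t, beta[2L, ])
  out <- rowsum(adj, ax$month, reorder = TRUE) / (diff(ref_years) + 1L)
  dimnames(out) <- NULL
  out
}

#' Maximum monthly mean (MMM)
#'
#' The warmest month of a (detrended) monthly climatology; the baseline above
#' which coral thermal stress accumulates.
#'
#' @param climatology 12 x cell matrix (from
#'   [detrended_monthly_climatology()]).
#' @return Per-cell MMM vector.
#' @export
mmm <- function(climatology) {
  stopifnot(nrow(climatology) == 12L)
  apply(climatology, 2L, max)
}

#' Degree heating weeks (DHW)
#'
#' The hotspot is `H(t) = SST(t) - MMM`; DHW at day t is the sum of
#' qualifying hotspots over the 84-day window from 83 days prior up to t,
#' divided by 7, in degC-weeks.  The default counting rule accumulates
#' hotspots of at least `count_threshold` (1 degC, the NOAA Coral Reef Watch
#' definition); `count_rule = "le1"` instead accumulates positive hotspots up
#' to the threshold, reproducing a literal "less than or equal to 1 degC"
#' reading.  Windows at the start of a segment are computed over the
#' available days unless `mask_partial` is set.
#'
#' @param daily_sst A [daily_field()] of SST.
#' @param mmm Per-cell MMM vector.
#' @param window_days Accumulation window (default 84 days = 12 weeks,
#'   inclusive of the current day).
#' @param count_threshold Hotspot qualification level in degC (default 1).
#' @param count_rule `"ge1"` (default: accumulate `H >= count_threshold`) or
#'   `"le1"` (accumulate `0 < H <= count_threshold`).
#' @param mask_partial If `TRUE`, the first `window_days - 1` days are `NA`.
#' @return Time x cell matrix of DHW (degC-weeks).
#' @export
dhw <- function(daily_sst, mmm, window_days = 84L, count_threshold = 1.0,
                count_rule = c("ge1", "le1"), mask_partial = FALSE) {
  stopifnot(inherits(daily_sst, "daily_field"))
  count_rule <- match.arg(count_rule)
  if (length(mmm) != ncol(daily_sst$values)) {
    stop("MMM grid does not match the SST field")
  }
  n <- nrow(daily_sst$values)
  if (window_days > n) stop("window longer than the daily series")
  h <- sweep(daily_sst$values, 2L, mmm, "-")
  q <- switch(count_rule,
              ge1 = h * (h >= count_threshold),
              le1 = h * (h > 0 & h <= count_threshold))
  cs <- apply(q, 2L, cumsum)
  out <- cs
  idx <- (window_days + 1L):n
  out[idx, ] <- cs[idx, , drop = FALSE] - cs[idx - window_days, , drop = FALSE]
  if (mask_partial && window_days > 1L) out[1:(window_days - 1L), ] <- NA
  out / 7
}

#' Extreme days by DHW level
#'
#' @param dhw_series Time x cell DHW matrix (from [dhw()]).
#' @param field The SST [daily_field()] the series was computed from (for
#'   grid/year metadata).
#' @param level DHW threshold in degC-weeks (default 4, the level associated
#'   with coral bleaching).
#' @return An `extreme_mask` of days with DHW strictly above `level`.
#' @export
dhw_extreme_days <- function(dhw_series, field, level = 4) {
  stopifnot(inherits(field, "daily_field"),
            all(dim(dhw_series) == dim(field$values)))
  .extreme_mask(dhw_series > level, field,
                sprintf("DHW>%g (MMM baseline)", level))
}

#' Absolute-threshold exceedance
#'
#' Strict exceedance of a spatially and temporally constant threshold.
#' Presets: `omega_1` (aragonite undersaturation, Omega_a < 1), `omega_3`
#' (coral habitat / reef-sediment dissolution, Omega_a < 3), `hypercapnia`
#' (pCO2 > 1000 uatm).
#'
#' @param daily A [daily_field()].
#' @param threshold Numeric threshold (in the field's units), or `NULL` when
#'   `preset` is given.
#' @param direction `"above"` or `"below"`; default from the field's tail.
#' @param preset Optional preset name (checks the field's variable/units).
#' @return An `extreme_mask`.
#' @export
absolute_exceedance <- function(daily, threshold = NULL,
                                direction = NULL, preset = NULL) {
  stopifnot(inherits(daily, "daily_field"))
  presets <- list(
    omega_1 = list(threshold = 1, direction = "below", units = "1"),
    omega_3 = list(threshold = 3, direction = "below", units = "1"),
    hypercapnia = list(threshold = 1000, direction = "above", units = "uatm")
  )
  if (!is.null(preset)) {
    p <- presets[[match.arg(preset, names(presets))]]
    if (!identical(daily$units, p$units)) {
      stop("preset '", preset, "' expects units '", p$units, "', field has '",
           daily$units, "'")
    }
    threshold <- p$threshold
    direction <- p$direction
  }
  if (is.null(threshold)) stop("either threshold or preset must be given")
  if (is.null(direction)) {
    direction <- if (daily$tail == "upper") "above" else "below"
  }
  direction <- match.arg(direction, c("above", "below"))
  mask <- if (direction == "above") daily$values > threshold
  else daily$values < threshold
  .extreme_mask(mask, daily,
                sprintf("%s %s %g (absolute)", daily$variable,
                        if (direction == "above") ">" else "<", threshold))
}
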