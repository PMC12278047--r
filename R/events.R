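# Compound-event accounting, detrended percentile-change statistics, global
# summaries, joint-distribution coverage regions and site reports.

#' Combine extreme masks into a compound-event mask
#'
#' Day-wise intersection (simultaneous extremes) or union (either extreme) of
#' two or more aligned extreme masks; provenance is concatenated.
#'
#' @param masks List of `extreme_mask` objects on the same grid and years.
#' @param mode `"intersection"` or `"union"`.
#' @return An `extreme_mask`.
#' @export
compound <- function(masks, mode = c("intersection", "union")) {
  mode <- match.arg(mode)
  stopifnot(length(masks) >= 2L,
            all(vapply(masks, inherits, TRUE, "extreme_mask")))
  dims <- lapply(masks, function(m) dim(m$mask))
  yrs <- lapply(masks, function(m) m$years)
  if (!all(vapply(dims, identical, TRUE, dims[[1]])) ||
      !all(vapply(yrs, identical, TRUE, yrs[[1]]))) {
    stop("masks are not aligned (grid or years differ)")
  }
  acc <- masks[[1]]$mask
  for (m in masks[-1L]) {
    acc <- if (mode == "intersection") acc & m$mask else acc | m$mask
  }
  proto <- masks[[1]]
  pseudo_field <- list(values = ifelse(is.na(acc), NA_real_, 0),
                       variable = paste(vapply(masks, `[[`, "", "variable"),
                                        collapse = "+"),
                       tail = proto$tail, years = proto$years,
                       lat = proto$lat, lon = proto$lon)
  .extreme_mask(acc, pseudo_field,
                paste0(mode, "(",
                       paste(vapply(masks, `[[`, "", "provenance"),
                             collapse = "; "), ")"))
}

# adjust a period's values to its midpoint by removing the per-cell OLS trend
.detrend_to_midpoint <- function(daily, period, midpoint_year) {
  d <- subset_years(daily, period)
  ax <- .daily_axis(period)
  t <- decimal_year(ax$year, ax$doy)
  X <- cbind(1, t)
  beta <- stats::lm.fit(X, d$values)$coefficients
  list(values = d$values + outer(midpoint_year - t, beta[2L, ]),
       slope = beta[2L, ], t = t)
}

#' Detrended percentile of a period, anchored at its midpoint
#'
#' Removes the per-cell OLS linear trend over the period and estimates the
#' percentile of the series adjusted to the midpoint year (residuals plus the
#' fitted midpoint value).  The seasonal cycle is not removed, so seasonal
#' amplitude contributes to the percentile.  Exactly invariant to adding any
#' linear trend anchored at the midpoint.
#'
#' @param daily A [daily_field()].
#' @param period Length-2 year range.
#' @param level Percentile level (e.g. 95, or 5 for lower-tail variables).
#' @param midpoint_year Decimal anchor year (default the period midpoint,
#'   e.g. 1995 for 1975-2014).
#' @return Per-cell percentile vector.
#' @export
detrended_percentile <- function(daily, period, level = NULL,
                                 midpoint_year = NULL) {
  stopifnot(inherits(daily, "daily_field"))
  if (is.null(level)) level <- .default_level(daily$tail)
  if (is.null(midpoint_year)) midpoint_year <- mean(period) + 0.5
  adj <- .detrend_to_midpoint(daily, period, midpoint_year)
  .col_percentile(adj$values, level)
}

#' Change in detrended percentile and mean between two periods
#'
#' Per-cell change (future minus historical) in the midpoint-anchored
#' detrended percentile and in the detrended mean, the area-weighted global
#' mean change with its spatial standard deviation, and the amplification map
#' (percentile change minus mean change; positive where the distribution tail
#' shifts more than the mean, e.g. under growing seasonal amplitude).
#'
#' @param hist_daily,future_daily [daily_field()]s of the same variable/grid.
#' @param hist_period,future_period Year ranges (defaults: full coverage).
#' @param level Percentile level (default by tail).
#' @param hist_midpoint,future_midpoint Anchor years (defaults: period
#'   midpoints).
#' @return List with per-cell maps (`pct_hist`, `pct_future`, `pct_change`,
#'   `mean_change`, `amplification`) and global summaries (`global`, a data
#'   frame with statistic, mean, spatial sd).
#' @export
change_summary <- function(hist_daily, future_daily,
                           hist_period = NULL, future_period = NULL,
                           level = NULL,
                           hist_midpoint = NULL, future_midpoint = NULL) {
  stopifnot(identical(hist_daily$lat, future_daily$lat),
            identical(hist_daily$lon, future_daily$lon))
  if (is.null(hist_period)) hist_period <- hist_daily$years
  if (is.null(future_period)) future_period <- future_daily$years
  if (is.null(level)) level <- .default_level(hist_daily$tail)
  if (is.null(hist_midpoint)) hist_midpoint <- mean(hist_period) + 0.5
  if (is.null(future_midpoint)) future_midpoint <- mean(future_period) + 0.5
  ah <- .detrend_to_midpoint(hist_daily, hist_period, hist_midpoint)
  af <- .detrend_to_midpoint(future_daily, future_period, future_midpoint)
  ph <- .col_percentile(ah$values, level)
  pf <- .col_percentile(af$values, level)
  mh <- colMeans(ah$values)
  mf <- colMeans(af$values)
  lat <- hist_daily$lat; lon <- hist_daily$lon
  g <- function(x) global_mean_sd(x, lat, lon)
  gp <- g(pf - ph); gm <- g(mf - mh)
  list(pct_hist = ph, pct_future = pf, pct_change = pf - ph,
       mean_change = mf - mh, amplification = (pf - ph) - (mf - mh),
       level = level,
       global = data.frame(
         statistic = c(sprintf("p%g change", level), "mean change",
                       "amplification"),
         mean = c(gp$mean, gm$mean, gp$mean - gm$mean),
         spatial_sd = c(gp$sd, gm$sd, g((pf - ph) - (mf - mh))$sd)))
}

#' Area-weighted joint distribution with a highest-density coverage region
#'
#' Bins per-cell (x, y) pairs (typically detrended percentile levels of two
#' stressors) into a 2-d histogram weighted by cell area, and finds the
#' smallest set of bins — accumulated in order of decreasing density — whose
#' total weight reaches the coverage fraction: a highest-density region
#' enclosing, by default, 90% of ocean surface area.
#'
#' @param x,y Per-cell values.
#' @param lat,lon Grid coordinates (for area weights).
#' @param coverage Target area fraction (default 0.90).
#' @param bins Number of bins per axis (default 60).
#' @param xlim,ylim Optional bin ranges (defaults: data range).
#' @return List with `xbreaks`, `ybreaks`, `weight` (bins matrix), `region`
#'   (logical bins matrix), `coverage_attained`.
#' @export
joint_distribution <- function(x, y, lat, lon, coverage = 0.90, bins = 60L,
                               xlim = NULL, ylim = NULL) {
  ok <- is.finite(x) & is.finite(y)
  if (!any(ok)) stop("empty domain: no finite (x, y) pairs")
  w <- area_weights(lat, length(lon), missing = !ok)
  if (is.null(xlim)) xlim <- range(x[ok])
  if (is.null(ylim)) ylim <- range(y[ok])
  xb <- seq(xlim[1], xlim[2], length.out = bins + 1L)
  yb <- seq(ylim[1], ylim[2], length.out = bins + 1L)
  ix <- pmin(pmax(findInterval(x, xb, rightmost.closed = TRUE), 1L), bins)
  iy <- pmin(pmax(findInterval(y, yb, rightmost.closed = TRUE), 1L), bins)
  wt <- matrix(0, bins, bins)
  for (k in which(ok)) wt[ix[k], iy[k]] <- wt[ix[k], iy[k]] + w[k]
  ord <- order(wt, decreasing = TRUE)
  cw <- cumsum(wt[ord])
  need <- which(cw >= coverage * sum(wt))[1]
  region <- matrix(FALSE, bins, bins)
  region[ord[seq_len(need)]] <- TRUE
  region <- region & wt > 0
  list(xbreaks = xb, ybreaks = yb, weight = wt, region = region,
       coverage_attained = sum(wt[region]) / sum(wt))
}

#' Overlap between two periods' joint-distribution coverage regions
#'
#' Computes both periods' highest-density regions on a shared bin grid
#' spanning the pooled data range and reports the Jaccard overlap fraction
#' (shared bins / union bins).  Identical inputs give 1; distributions
#' shifted far beyond the historical spread give about 0.
#'
#' @param x1,y1 Historical per-cell values.
#' @param x2,y2 Future per-cell values.
#' @inheritParams joint_distribution
#' @return List with `hist`, `future` (each a [joint_distribution()] result)
#'   and `overlap` (Jaccard fraction in \[0, 1\]).
#' @export
joint_overlap <- function(x1, y1, x2, y2, lat, lon, coverage = 0.90,
                          bins = 60L) {
  xlim <- range(c(x1, x2), finite = TRUE)
  ylim <- range(c(y1, y2), finite = TRUE)
  j1 <- joint_distribution(x1, y1, lat, lon, coverage, bins, xlim, ylim)
  j2 <- joint_distribution(x2, y2, lat, lon, coverage, bins, xlim, ylim)
  inter <- sum(j1$region & j2$region)
  uni <- sum(j1$region | j2$region)
  list(hist = j1, future = j2, overlap = if (uni == 0) NA_real_ else
    inter / uni)
}

#' Per-site stacked percentages of single and compound extreme days
#'
#' For each site, partitions days into mutually exclusive categories —
#' extreme only in the first stressor, only in the second, both, neither —
#' as percentages summing to 100.
#'
#' @param mask_x,mask_y Aligned `extreme_mask` objects.
#' @param sites A [site_set()] with points.
#' @return Data frame: site, only_x, only_y, both, neither.
#' @export
site_report <- function(mask_x, mask_y, sites) {
  stopifnot(inherits(mask_x, "extreme_mask"), inherits(mask_y, "extreme_mask"),
            identical(dim(mask_x$mask), dim(mask_y$mask)))
  idx <- site_cells(sites, mask_x$lat, mask_x$lon)
  out <- data.frame(site = names(idx), only_x = 0, only_y = 0, both = 0,
                    neither = 0)
  for (k in seq_along(idx)) {
    a <- mask_x$mask[, idx[k]]
    b <- mask_y$mask[, idx[k]]
    keep <- !is.na(a) & !is.na(b)
    a <- a[keep]; b <- b[keep]
    n <- length(a)
    out$only_x[k] <- 100 * sum(a & !b) / n
    out$only_y[k] <- 100 * sum(!a & b) / n
    out$both[k] <- 100 * sum(a & b) / n
    out$neither[k] <- 100 * sum(!a & !b) / n
  }
  out
}

#' Area-weighted global mean extreme-day percentage of a mask
#' @param mask An `extreme_mask`.
#' @return Scalar percent of days.
#' @export
global_extreme_percent <- function(mask) {
  stopifnot(inherits(mask, "extreme_mask"))
  global_mean(mask$percent, mask$lat, mask$lon)
}
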