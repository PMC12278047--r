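# Builders for small synthetic test fields.

test_lat <- c(-10, 10, 30)
test_lon <- c(0, 60)

# stationary AR(1) series with marginal sd `sd`
ar1_series <- function(n, rho, sd) {
  e <- stats::rnorm(n, 0, sd * sqrt(1 - rho^2))
  e[1] <- stats::rnorm(1, 0, sd)
  as.numeric(stats::filter(e, rho, method = "recursive"))
}

# daily field: per-cell sinusoid + AR(1) noise (+ linear trend in decimal yr)
make_daily <- function(years = c(1975, 2014), lat = test_lat, lon = test_lon,
                       mean = 0, amp = 0, phase = 196, sd = 0, rho = 0,
                       trend = 0, variable = "tos", units = "degC",
                       tail = "upper", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ny <- years[2] - years[1] + 1
  n <- 365L * ny
  doy <- rep(1:365, ny)
  t <- decimal_year(rep(seq(years[1], years[2]), each = 365L), doy)
  ncell <- length(lat) * length(lon)
  vals <- sapply(seq_len(ncell), function(j) {
    mean + amp * cos(2 * pi * (doy - phase) / 365) + trend * (t - t[1]) +
      (if (sd > 0) ar1_series(n, rho, sd) else 0)
  })
  daily_field(vals, variable, units, tail, years, lat, lon)
}

# monthly archive: per-cell monthly seasonal pattern + linear trend
make_archive <- function(years = c(1875, 2014), lat = test_lat,
                         lon = test_lon, mean = 0, monthly_cycle = rep(0, 12),
                         trend = 0, sd = 0, variable = "tos", units = "degC",
                         tail = "upper", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ny <- years[2] - years[1] + 1
  n <- 12L * ny
  mon <- rep(1:12, ny)
  t <- rep(seq(years[1], years[2]), each = 12L) + (month_midpoints()[mon]) / 365
  ncell <- length(lat) * length(lon)
  vals <- sapply(seq_len(ncell), function(j) {
    mean + monthly_cycle[mon] + trend * (t - t[1]) +
      (if (sd > 0) stats::rnorm(n, 0, sd) else 0)
  })
  monthly_archive(vals, variable, units, tail, years, lat, lon)
}

# one-variable scenario configuration for generator contract tests
one_var_config <- function(mean = 20, amp = 0, phase = 196, amp_trend = 0,
                           rho = 0.5, sd = 0, base_rate = 0, accel = 0,
                           seed = 1, n_lat = 2, n_lon = 2,
                           years_daily_hist = c(1980, 1981),
                           years_daily_future = c(2061, 2062),
                           years_monthly = c(1975, 2100)) {
  scenario_config(
    grid = list(n_lat = n_lat, n_lon = n_lon),
    years_daily_hist = years_daily_hist,
    years_daily_future = years_daily_future,
    years_monthly = years_monthly,
    variables = list(
      x = var_spec("x", "u", "upper", mean = mean, amp = amp, phase = phase,
                   amp_trend = amp_trend, ar1_rho = rho, noise_sd = sd,
                   trend = trend_spec(base_rate, accel = accel))
    ),
    rng_seed = seed
  )
}
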