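test_that("percentile matches linear order-statistic interpolation", {
  expect_equal(percentile(1:100, 95), 95.05)
  expect_equal(percentile(sample(1:100), 50), stats::median(1:100))
  expect_equal(percentile(rep(3.2, 50), 37), 3.2)
  expect_equal(percentile(c(4, 9, 1), 100), 9)
  expect_error(percentile(numeric(0), 95), "empty")
  expect_error(percentile(c(NA_real_, NA_real_), 95), "empty")
})

test_that("fixed SC threshold returns ~5% of its own reference days", {
  f <- make_daily(c(1975, 2014), sd = 1, rho = 0.5, amp = 2, seed = 21)
  thr <- fit_fixed_sc(f)
  m <- count_extremes(f, thr)
  counts <- colSums(m$mask)
  expect_true(all(counts == 730)) # continuous data: exact order-statistic count
  expect_equal(unname(m$percent), rep(100 * 730 / 14600, 6))
})

test_that("thresholds commute with shifts and positive scalings", {
  f <- make_daily(c(2000, 2009), sd = 1, rho = 0.3, amp = 1.5, seed = 22)
  g <- f; g$values <- 2.5 * f$values + 3
  for (fit in list(fit_fixed_sc, fit_fixed_sv_anomaly, fit_fixed_sv_binned)) {
    t1 <- fit(f)
    t2 <- fit(g)
    expect_equal(t2$values, 2.5 * t1$values + 3, tolerance = 1e-10)
  }
})

test_that("constant fields give flat thresholds and zero strict exceedance", {
  f <- make_daily(c(2000, 2004), mean = 4.4)
  for (fit in list(fit_fixed_sc, fit_fixed_sv_binned, fit_fixed_sv_anomaly)) {
    thr <- fit(f)
    expect_true(all(abs(thr$values - 4.4) < 1e-12))
    expect_equal(sum(count_extremes(f, thr)$mask), 0)
  }
})

test_that("binned SV threshold tracks a pure seasonal cycle", {
  f <- make_daily(c(2000, 2009), amp = 2, sd = 0)
  thr <- fit_fixed_sv_binned(f)
  cycle <- 2 * cos(2 * pi * ((1:365) - 196) / 365)
  expect_lt(max(abs(thr$values[, 1] - cycle)), 0.1)
})

test_that("negating the field and flipping the tail reproduces the mask", {
  f <- make_daily(c(2000, 2009), sd = 1, rho = 0.4, amp = 1, seed = 23)
  g <- f; g$values <- -f$values; g$tail <- "lower"
  m1 <- count_extremes(f, fit_fixed_sc(f, level = 95))
  m2 <- count_extremes(g, fit_fixed_sc(g, level = 5))
  expect_identical(m1$mask, m2$mask)
})

test_that("mismatched tails and grids are rejected when counting", {
  f <- make_daily(c(2000, 2001), sd = 1, seed = 1)
  thr <- fit_fixed_sc(f)
  g <- f; g$tail <- "lower"
  expect_error(count_extremes(g, thr), "tail")
})

test_that("binned SV extremes are seasonally uniform under stationarity while SC extremes peak with the cycle", {
  set.seed(31)
  f <- make_daily(c(1975, 2014), amp = 2, sd = 1, rho = 0.5, seed = 31)
  msv <- count_extremes(f, fit_fixed_sv_binned(f))
  msc <- count_extremes(f, fit_fixed_sc(f))
  doy <- rep(1:365, 40)
  mo <- month_of_doy()[doy]
  share <- function(mask) {
    cnt <- vapply(1:12, function(m) sum(mask[mo == m, ]), 0)
    (cnt / sum(cnt)) / (noleap_month_lengths() / 365) # length-normalised
  }
  ssv <- share(msv$mask)
  expect_lt(max(ssv) / min(ssv), 2)
  ssc <- share(msc$mask)
  expect_gt(ssc[7], 2) # July (cycle peak) hoards SC extremes
  expect_lt(min(ssc), 0.1)
})

test_that("anomaly and SC thresholds agree without seasonality; anomaly and binned counts agree when homoscedastic", {
  f <- make_daily(c(1975, 2014), amp = 0, sd = 1, rho = 0, seed = 32)
  ta <- fit_fixed_sv_anomaly(f)
  tc <- fit_fixed_sc(f)
  expect_lt(mean(abs(sweep(ta$values, 2, tc$values, "-"))), 0.1)

  g <- make_daily(c(1975, 2014), amp = 2, sd = 1, rho = 0.5, seed = 33)
  nb <- sum(count_extremes(g, fit_fixed_sv_binned(g))$mask)
  na <- sum(count_extremes(g, fit_fixed_sv_anomaly(g))$mask)
  expect_lt(abs(nb / na - 1), 0.1)
})

test_that("winter-amplified noise splits the binned and anomaly SV definitions", {
  set.seed(34)
  ny <- 40; doy <- rep(1:365, ny)
  winter <- doy <= 60 | doy >= 335
  vals <- sapply(1:6, function(j) {
    2 * cos(2 * pi * (doy - 196) / 365) + stats::rnorm(length(doy)) *
      ifelse(winter, 2, 1)
  })
  f <- daily_field(vals, "tos", "degC", "upper", c(1975, 2014),
                   test_lat, test_lon)
  frac_winter <- function(mask) sum(mask[winter, ]) / sum(mask)
  fb <- frac_winter(count_extremes(f, fit_fixed_sv_binned(f))$mask)
  fa <- frac_winter(count_extremes(f, fit_fixed_sv_anomaly(f))$mask)
  expect_lt(abs(fb - mean(winter)), 0.1) # binned: close to share of days
  expect_gt(fa, 2 * mean(winter)) # anomaly: concentrated in winter
})

test_that("AMM series tracks constants, seasonal peaks and linear trends", {
  a <- make_archive(c(1950, 1999), mean = 6)
  expect_true(all(amm_series(a, "max")$values == 6))

  cyc <- 2 * cos(2 * pi * (month_midpoints() - 196) / 365)
  a2 <- make_archive(c(1950, 1999), monthly_cycle = cyc)
  am <- amm_series(a2, "max")
  expect_equal(am$values[1, 1], cyc[7]) # July
  expect_true(all(amm_series(a2, "min")$values == cyc[1]))

  a3 <- make_archive(c(1950, 1999), monthly_cycle = cyc, trend = 0.05,
                     sd = 0.01, seed = 41)
  am3 <- amm_series(a3, "max")
  slope <- stats::coef(stats::lm(am3$values[, 1] ~ am3$years))[2]
  expect_lt(abs(slope - 0.05), 0.005)
})

test_that("AMM calibration on a pure sinusoid matches the idealized percentile", {
  f <- make_daily(c(1975, 2014), amp = 2, sd = 0, phase = 196)
  arch <- monthly_means(f)
  cal <- calibrate_amm_percentile(f, arch, "max")
  ideal <- idealized_amm_percentile(196)
  expect_lte(abs(cal$best - round(ideal)), 1)
  expect_true(all(c("percentile", "rmse", "bias") %in% names(cal$table)))
  expect_error(calibrate_amm_percentile(
    f, make_archive(c(1875, 1900))), "overlap")
})

test_that("idealized AMM rank is amplitude-invariant and matches brute force", {
  expect_equal(idealized_amm_percentile(100, amplitude = 1),
               idealized_amm_percentile(100, amplitude = 7.3))
  # independent brute force at one phase
  phase <- 42.5
  s <- cos(2 * pi * ((1:365) - phase) / 365)
  mo <- month_of_doy()
  mm <- vapply(1:12, function(m) mean(s[mo == m]), 0)
  expect_equal(idealized_amm_percentile(phase), 100 * mean(s < max(mm)))
})

test_that("adaptive SC threshold equals the preceding-window AMM mean", {
  # stationary archive: threshold constant across target years
  a <- make_archive(c(1875, 2014), mean = 5,
                    monthly_cycle = cos(2 * pi * month_midpoints() / 365))
  t1 <- adaptive_sc_threshold(a, 1990, N = 100)
  t2 <- adaptive_sc_threshold(a, 2010, N = 100)
  expect_equal(t1$values, t2$values)

  # linear AMM trend m/yr: threshold lags the target-year AMM by m (N + 1) / 2
  m <- 0.02
  a3 <- make_archive(c(1875, 2014), trend = m)
  N <- 60
  thr <- adaptive_sc_threshold(a3, 2000, N = N)
  amm <- amm_series(a3, "max")
  amm_target <- amm$values[amm$years == 2000, ]
  expect_equal(unname(amm_target - thr$values), rep(m * (N + 1) / 2, 6),
               tolerance = 1e-8)

  # shorter window under positive trend sits strictly higher
  t50 <- adaptive_sc_threshold(a3, 2000, N = 50)
  t100 <- adaptive_sc_threshold(a3, 2000, N = 100)
  expect_true(all(t50$values > t100$values))

  expect_error(adaptive_sc_threshold(a3, 2000, N = 200), "does not cover")
})

test_that("adaptive SV threshold shifts the historical threshold by the monthly climatology difference", {
  f <- make_daily(c(1975, 2014), amp = 2, sd = 0.5, rho = 0.3, seed = 51)
  hist_sv <- fit_fixed_sv_anomaly(f)
  arch <- monthly_means(f)

  # rolling window identical to the historical window: threshold unchanged
  t_same <- adaptive_sv_threshold(hist_sv, arch, c(1975, 2014), 2015, N = 40)
  expect_equal(t_same$values, hist_sv$values, tolerance = 1e-10)

  # uniform +delta in the rolling window: threshold shifts by exactly delta
  arch2 <- arch
  arch2$values <- rbind(arch$values, arch$values + 1.5)
  arch2$years <- c(1975, 2054)
  t_shift <- adaptive_sv_threshold(hist_sv, arch2, c(1975, 2014), 2055, N = 40)
  expect_equal(t_shift$values, hist_sv$values + 1.5, tolerance = 1e-10)

  expect_error(adaptive_sv_threshold(hist_sv, arch, c(1975, 2014), 2030,
                                     N = 100), "does not cover")
})

test_that("month-to-day interpolation hits the monthly anchors and wraps", {
  delta <- c(1, rep(0, 11))
  at_mid <- oaextremes:::.interp_months(delta, month_midpoints())
  expect_equal(at_mid, delta)
  grid <- oaextremes:::.interp_months_doy(delta)
  expect_equal(which.max(grid), 16L) # day centre 15.5 = January midpoint
  expect_gt(grid[365], 0) # periodic wrap bleeds into late December
  expect_equal(grid[100], 0) # far months untouched
})
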