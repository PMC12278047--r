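test_that("detrended climatology removes midpoint-anchored linear trends exactly", {
  cyc <- 3 * cos(2 * pi * (month_midpoints() - 196) / 365)
  a0 <- make_archive(c(1975, 2014), mean = 25, monthly_cycle = cyc)
  c0 <- detrended_monthly_climatology(a0, c(1975, 2014))
  # finite-sample leakage of the seasonal cycle into the fitted trend is tiny
  expect_equal(c0[, 1], 25 + cyc, tolerance = 0.01)

  # pure linear trend valued c at the pivot: all twelve months equal c
  pivot <- 1988.2857
  ax <- oaextremes:::.monthly_axis(c(1975, 2014))
  t <- oaextremes:::.decimal_year_month(ax$year, ax$month)
  a1 <- a0
  a1$values <- matrix(7 + 0.3 * (t - pivot), ncol = 1)[, rep(1, 6)]
  c1 <- detrended_monthly_climatology(a1, c(1975, 2014))
  expect_equal(unname(c1), matrix(7, 12, 6), tolerance = 1e-9)

  # adding a pivot-anchored linear trend changes nothing, exactly
  a2 <- a0
  a2$values <- a0$values + 0.5 * (t - pivot)
  c2 <- detrended_monthly_climatology(a2, c(1975, 2014))
  expect_equal(c2, c0, tolerance = 1e-9)

  expect_error(detrended_monthly_climatology(
    make_archive(c(2000, 2000)), c(2000, 2000)), "2 years")
})

test_that("MMM is the warmest climatological month, permutation-invariant", {
  clim <- matrix(c(20:26, 28.1, 27, 24, 22, 21), 12, 2)
  expect_equal(mmm(clim), c(28.1, 28.1))
  expect_equal(mmm(clim[sample(12), , drop = FALSE]), c(28.1, 28.1))
  expect_equal(mmm(matrix(5, 12, 3)), rep(5, 3))
})

test_that("DHW matches closed forms for steady and pulsed hotspots", {
  base <- rep(20, 2)
  n <- 365
  # H = 0.9 everywhere: below the counting threshold, DHW identically zero
  f09 <- daily_field(matrix(20.9, n, 2), "tos", "degC", "upper",
                     c(2000, 2000), c(0, 0)[1], c(0, 60))
  expect_true(all(dhw(f09, base) == 0))

  # H = 2 sustained: DHW ramps to the steady state 84 * 2 / 7 = 24
  f2 <- daily_field(matrix(22, n, 2), "tos", "degC", "upper",
                    c(2000, 2000), c(0, 0)[1], c(0, 60))
  d2 <- dhw(f2, base)
  expect_equal(d2[84:n, 1], rep(24, n - 83))
  expect_equal(d2[10, 1], 10 * 2 / 7) # partial start-of-segment window
  dm <- dhw(f2, base, mask_partial = TRUE)
  expect_true(all(is.na(dm[1:83, ])))

  # single 7-day excursion at H = 1: peak DHW 1, gone 90 days after onset
  v <- matrix(20, n, 2)
  v[100:106, ] <- 21
  fex <- daily_field(v, "tos", "degC", "upper", c(2000, 2000),
                     c(0, 0)[1], c(0, 60))
  dex <- dhw(fex, base)
  expect_equal(max(dex), 1)
  expect_equal(dex[106, 1], 1)
  expect_gt(dex[189, 1], 0) # day 106 still inside the window [106, 189]
  expect_equal(dex[190, 1], 0) # window has fully passed the excursion
})

test_that("DHW is linear in qualifying hotspot amplitude and increment-bounded", {
  set.seed(61)
  f <- make_daily(c(2000, 2001), mean = 20, amp = 1.5, sd = 1, rho = 0.8,
                  seed = 61)
  base <- rep(20.5, 6)
  d1 <- dhw(f, base)
  g <- f; g$values <- base[1] + 2 * (f$values - base[1]) # double all hotspots
  d2 <- dhw(g, base)
  q1 <- sweep(f$values, 2, base, "-")
  # days whose whole window qualifies under the original scaling double
  all_qual <- apply(q1 >= 1, 2, function(z) {
    rs <- stats::filter(as.numeric(z), rep(1, 84), sides = 1)
    !is.na(rs) & rs == 84
  })
  expect_equal(d2[all_qual], 2 * d1[all_qual])
  expect_true(all(d2 >= d1 - 1e-9))
  inc <- abs(diff(d1[, 1]))
  expect_true(all(inc <= max(pmax(q1[, 1], 0)) / 7 + 1e-12))
})

test_that("the literal counting rule accumulates small positive hotspots", {
  f <- daily_field(matrix(20.5, 365, 1), "tos", "degC", "upper",
                   c(2000, 2000), 0, 0) # H = 0.5 throughout
  expect_true(all(dhw(f, 20, count_rule = "ge1") == 0))
  d_le <- dhw(f, 20, count_rule = "le1")
  expect_equal(d_le[84, 1], 84 * 0.5 / 7)
  expect_true(all(d_le >= 0))
})

test_that("DHW extreme days respond to level monotonically", {
  f <- make_daily(c(2000, 2003), mean = 20, amp = 1, sd = 0.8, rho = 0.9,
                  seed = 62)
  d <- dhw(f, rep(20, 6))
  m4 <- dhw_extreme_days(d, f, 4)
  m6 <- dhw_extreme_days(d, f, 6)
  expect_true(all(m4$percent >= m6$percent))
  z <- dhw_extreme_days(d * 0, f, 4)
  expect_equal(unname(z$percent), rep(0, 6))

  fconst <- daily_field(matrix(22, 365, 6), "tos", "degC", "upper",
                        c(2000, 2000), test_lat, test_lon)
  dc <- dhw(fconst, rep(20, 6))
  mc <- dhw_extreme_days(dc, fconst, 4)
  expect_equal(unname(colSums(mc$mask)), rep(365 - 14, 6)) # DHW > 4 from day 15
})

test_that("a 1-degree offset beats the SC percentile where variability is low but not under large red noise", {
  set.seed(63)
  ny <- 40; n <- ny * 365; doy <- rep(1:365, ny)
  low <- 20 + 0.3 * cos(2 * pi * (doy - 196) / 365) + ar1_series(n, 0.5, 0.1)
  high <- 20 + 1.0 * cos(2 * pi * (doy - 196) / 365) + ar1_series(n, 0.98, 1.5)
  f <- daily_field(cbind(low, high), "tos", "degC", "upper", c(1975, 2014),
                   0, c(0, 60))
  base <- mmm(detrended_monthly_climatology(monthly_means(f), c(1975, 2014)))
  pct_dhw <- dhw_extreme_days(dhw(f, base), f, 4)$percent
  pct_sc <- count_extremes(f, fit_fixed_sc(f))$percent
  expect_lt(pct_dhw[1], pct_sc[1]) # low-variability cell: offset suppresses
  expect_gt(pct_dhw[2], pct_sc[2]) # red-noise cell: accumulation amplifies
})

test_that("absolute thresholds are strict and count correctly", {
  om <- daily_field(matrix(3, 365, 1), "omega", "1", "lower", c(2000, 2000),
                    0, 0)
  expect_equal(sum(absolute_exceedance(om, preset = "omega_3")$mask), 0)

  pc <- matrix(900, 365, 1)
  pc[1:36, 1] <- 1100
  fpc <- daily_field(pc, "spco2", "uatm", "upper", c(2000, 2000), 0, 0)
  m <- absolute_exceedance(fpc, preset = "hypercapnia")
  expect_equal(unname(m$percent), 100 * 36 / 365)

  expect_error(absolute_exceedance(om, preset = "hypercapnia"), "units")

  # declining omega: annual exceedance of omega < 3 is non-decreasing
  f <- make_daily(c(2000, 2019), mean = 3.3, amp = 0.2, trend = -0.03,
                  variable = "omega", units = "1", tail = "lower")
  mm <- absolute_exceedance(f, preset = "omega_3")
  yearly <- rowsum(rowSums(mm$mask), rep(1:20, each = 365))
  expect_true(all(diff(yearly[, 1]) >= 0))
})
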