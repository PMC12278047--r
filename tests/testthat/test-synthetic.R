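test_that("degenerate constant configuration yields constant fields", {
  cfg <- one_var_config(mean = 20, amp = 0, sd = 0, base_rate = 0)
  w <- generate_scenario(cfg, "historical")
  expect_true(all(w$daily_hist$x$values == 20))
  expect_true(all(w$monthly$x$values == 20))
})

test_that("pure sinusoid reproduces the analytic cycle and its July AMM", {
  cfg <- one_var_config(mean = 10, amp = 2, phase = 196, sd = 0)
  w <- generate_scenario(cfg, "historical")
  doy <- rep(1:365, 2)
  expected <- 10 + 2 * cos(2 * pi * (doy - 196) / 365)
  expect_equal(w$daily_hist$x$values[, 1], expected, tolerance = 1e-12)

  amm <- amm_series(subset_years(w$monthly$x, c(1980, 1981)), "max")
  july <- w$monthly$x$values[(1980 - 1975) * 12 + 7, 1]
  expect_equal(amm$values[1, 1], unname(july))
})

test_that("deseasonalised daily residuals recover the configured AR(1)", {
  cfg <- one_var_config(amp = 1, rho = 0.8, sd = 1, seed = 3,
                        years_daily_hist = c(1975, 2014), n_lat = 1, n_lon = 1)
  w <- generate_scenario(cfg, "historical")
  x <- w$daily_hist$x$values[, 1]
  doy <- rep(1:365, 40)
  resid <- x - ave(x, doy)
  r1 <- stats::acf(resid, lag.max = 1, plot = FALSE)$acf[2]
  expect_lt(abs(r1 - 0.8), 0.02)
})

test_that("identical configuration and seed give bit-identical output", {
  cfg <- one_var_config(amp = 1, rho = 0.7, sd = 0.5, base_rate = 1)
  w1 <- generate_scenario(cfg, "mitigation")
  w2 <- generate_scenario(cfg, "mitigation")
  expect_identical(w1$daily_future$x$values, w2$daily_future$x$values)
  expect_identical(w1$monthly$x$values, w2$monthly$x$values)
})

test_that("monthly archive equals month means of daily output where both exist", {
  cfg <- one_var_config(amp = 2, rho = 0.6, sd = 1, base_rate = 0.5, seed = 9)
  w <- generate_scenario(cfg, "high")
  mm <- monthly_means(w$daily_hist$x)
  i0 <- (cfg$years_daily_hist[1] - cfg$years_monthly[1]) * 12 + 1
  rows <- i0:(i0 + nrow(mm$values) - 1)
  expect_identical(w$monthly$x$values[rows, ], mm$values)
})

test_that("directly generated months match daily-derived months in distribution", {
  # no seasonality, no trend: gap months and daily-derived months should share
  # mean ~0 and comparable spread
  cfg <- one_var_config(mean = 0, amp = 0, rho = 0.8, sd = 1, seed = 11,
                        years_daily_hist = c(1975, 2014),
                        years_monthly = c(1875, 2100))
  w <- generate_scenario(cfg, "historical")
  gap <- w$monthly$x$values[1:(100 * 12), ]
  derived <- monthly_means(w$daily_hist$x)$values
  expect_lt(abs(mean(gap)), 0.05)
  expect_lt(abs(sd(gap) / sd(derived) - 1), 0.2)
})

test_that("scenario trajectories share noise and coincide before divergence", {
  cfg <- one_var_config(amp = 1, rho = 0.6, sd = 0.8, base_rate = 2,
                        accel = 1, seed = 5, years_monthly = c(1975, 2100))
  wm <- generate_scenario(cfg, "mitigation")
  wh <- generate_scenario(cfg, "high")
  expect_identical(wm$daily_hist$x$values, wh$daily_hist$x$values)
  pre <- 1:((2040 - 1975) * 12) # monthly rows through 2039
  expect_identical(wm$monthly$x$values[pre, ], wh$monthly$x$values[pre, ])
  # and they must differ well after divergence
  post <- nrow(wm$monthly$x$values)
  expect_false(isTRUE(all.equal(wm$monthly$x$values[post, ],
                                wh$monthly$x$values[post, ])))
})

test_that("trend trajectories are continuous at divergence and rank as expected", {
  ts <- trend_spec(2, plateau_tau = 15, plateau_peak = 0.5, accel = 1)
  eps <- 1e-8
  for (k in c("linear", "plateau", "accelerating")) {
    expect_lt(abs(trend_value(ts, 2040 + eps, k) -
                    trend_value(ts, 2040 - eps, k)), 1e-6)
  }
  t_pre <- seq(1900, 2040, by = 7)
  expect_equal(trend_value(ts, t_pre, "plateau"),
               trend_value(ts, t_pre, "accelerating"))
  # by late century: accelerating > linear > plateau for positive base rate
  expect_gt(trend_value(ts, 2090, "accelerating"),
            trend_value(ts, 2090, "linear"))
  expect_gt(trend_value(ts, 2090, "linear"), trend_value(ts, 2090, "plateau"))
  # anchored at the reference year
  expect_equal(trend_value(ts, 1995, "plateau"), 0)
})

test_that("omega seasonal climatology opposes SST at every cell", {
  cfg <- default_scenario_config(rng_seed = 2, n_lat = 4, n_lon = 3)
  w <- generate_scenario(cfg, "historical")
  doy <- rep(1:365, 40)
  cors <- vapply(seq_len(12), function(j) {
    a <- tapply(w$daily_hist$tos$values[, j], doy, mean)
    b <- tapply(w$daily_hist$omega$values[, j], doy, mean)
    stats::cor(a, b)
  }, 0)
  expect_true(all(cors < 0))
  # and the positively coupled variables track SST
  corp <- vapply(seq_len(12), function(j) {
    stats::cor(tapply(w$daily_hist$tos$values[, j], doy, mean),
               tapply(w$daily_hist$spco2$values[, j], doy, mean))
  }, 0)
  expect_true(all(corp > 0))
})

test_that("default omega fields stay positive across scenarios", {
  cfg <- default_scenario_config(rng_seed = 3, n_lat = 4, n_lon = 3)
  for (sc in c("historical", "high")) {
    w <- generate_scenario(cfg, sc)
    expect_gt(min(w$monthly$omega$values), 0)
    seg <- if (sc == "historical") w$daily_hist else w$daily_future
    expect_gt(min(seg$omega$values), 0)
  }
})

test_that("unknown scenario labels are rejected", {
  cfg <- one_var_config()
  expect_error(generate_scenario(cfg, "rcp85"), "unknown scenario")
})

test_that("pH conversion follows 10^(-pH) with missing-value propagation", {
  expect_equal(ph_to_hplus(8), 1e-8)
  expect_equal(ph_to_hplus(7), 1e-7)
  expect_identical(ph_to_hplus(c(8, NA, 7)), c(1e-8, NA, 1e-7))
  m <- matrix(c(8, 7.5, NaN, 8.1), 2)
  out <- ph_to_hplus(m)
  expect_equal(dim(out), dim(m))
  expect_true(is.na(out[1, 2]))
  expect_error(ph_to_hplus(-1), "pH")
  # averaging pH before conversion is not the same as averaging H+
  h_of_mean <- ph_to_hplus(mean(c(8, 7)))
  mean_of_h <- mean(ph_to_hplus(c(8, 7)))
  expect_gt(abs(mean_of_h - h_of_mean) / mean_of_h, 0.01)
  expect_equal(mean_of_h, 5.5e-8)
})
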