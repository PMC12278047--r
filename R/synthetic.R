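# Synthetic multi-variable scenario generator.
#
# Each variable is mean + scenario trend + (possibly amplitude-trending)
# sinusoidal seasonal cycle + AR(1) anomalies, with anomaly coupling of the
# acidification variables to SST.  Scenario trajectories share a common ramp
# and diverge at a configured year into a plateau (mitigation) or an
# accelerating path (high emission).  One master seed; every noise stream is
# seeded deterministically from (seed, variable, stream), so scenarios share
# internal variability bit-for-bit and adding a variable never reshuffles the
# streams of another.

#' Scenario trend specification
#'
#' The common trajectory is flat before `ramp_start`, then a cubic ramp
#' whose rate grows quadratically from zero to `base_rate` (units/decade) at
#' `divergence_year` — slow early change accelerating towards the present,
#' as in observed greenhouse forcing.  After divergence the path continues according to the
#' scenario kind: `"linear"` keeps the divergence-year rate, `"plateau"`
#' relaxes the rate to zero on timescale `plateau_tau` years, and
#' `"accelerating"` adds `accel` (units/decade^2) of curvature.  All kinds are
#' continuous (and C1) across the divergence year and identical before it.
#' Values are reported relative to `ref_year` (the trajectory is zero there).
#'
#' The plateau kind mixes a monotone saturation with a peak-and-decay
#' response via `plateau_peak`: with `plateau_peak = 0` the trajectory
#' approaches `base_rate * plateau_tau / 10` above the divergence value
#' (committed change that holds, as for temperature under strong
#' mitigation); with `plateau_peak = 1` it peaks about `plateau_tau` years
#' after divergence and relaxes back to the divergence value (variables that
#' track a peaking and declining atmospheric CO2 burden).  The long-run
#' settle level is `base_rate * plateau_tau * (1 - plateau_peak) / 10` above
#' the divergence value.
#'
#' @param base_rate Rate at the divergence year, units per decade.
#' @param divergence_year Year the scenarios separate (default 2040).
#' @param ramp_start First year of the common ramp (default 1900).
#' @param ref_year Year at which the trajectory is anchored to zero
#'   (default 1995, the historical-period midpoint).
#' @param plateau_tau Relaxation timescale (years) of the plateau kind.
#' @param plateau_peak Fraction of the plateau response that decays back
#'   after peaking (default 0, monotone plateau).
#' @param accel Acceleration (units/decade^2) of the accelerating kind.
#' @return An object of class `trend_spec`.
#' @export
trend_spec <- function(base_rate, divergence_year = 2040, ramp_start = 1900,
                       ref_year = 1995, plateau_tau = 15, plateau_peak = 0,
                       accel = 0) {
  stopifnot(ramp_start < divergence_year, plateau_tau > 0,
            plateau_peak >= 0, plateau_peak <= 1)
  structure(list(base_rate = base_rate, divergence_year = divergence_year,
                 ramp_start = ramp_start, ref_year = ref_year,
                 plateau_tau = plateau_tau, plateau_peak = plateau_peak,
                 accel = accel),
            class = "trend_spec")
}

#' Evaluate a scenario trend trajectory
#'
#' @param spec A [trend_spec()].
#' @param t Decimal years.
#' @param kind `"linear"`, `"plateau"` or `"accelerating"` post-divergence
#'   behaviour.
#' @return Trajectory values (zero at `spec$ref_year`).
#' @export
trend_value <- function(spec, t, kind = c("linear", "plateau", "accelerating")) {
  kind <- match.arg(kind)
  r <- spec$base_rate / 10 # units per year at divergence
  t0 <- spec$ramp_start; td <- spec$divergence_year
  ramp <- function(t) {
    u <- pmin(pmax(t, t0), td) - t0
    r * u^3 / (3 * (td - t0)^2)
  }
  post <- function(dt) {
    tau <- spec$plateau_tau
    pk <- spec$plateau_peak
    switch(kind,
      linear = r * dt,
      plateau = r * tau * ((1 - pk) * (1 - exp(-dt / tau)) +
                             pk * (dt / tau) * exp(-dt / tau)),
      accelerating = r * dt + (spec$accel / 100) * dt^2
    )
  }
  v <- ramp(t) + ifelse(t > td, post(pmax(t - td, 0)), 0)
  v_ref <- ramp(spec$ref_year) +
    if (spec$ref_year > td) post(spec$ref_year - td) else 0
  v - v_ref
}

#' Per-variable block of a scenario configuration
#'
#' Spatial parameters (`mean`, `amp`, `phase`) may be a scalar, a vector of
#' length `n_lat` (replicated across longitude) or a function of latitude in
#' degrees.
#'
#' @param name Variable name.
#' @param units Units string.
#' @param tail `"upper"` or `"lower"` stressful tail.
#' @param mean Mean field at the trend reference year.
#' @param amp Seasonal cycle amplitude (units of the variable).
#' @param phase Day of year of the seasonal maximum.
#' @param amp_trend Fractional amplitude change per decade (relative to the
#'   trend reference year).
#' @param ar1_rho Lag-1 autocorrelation of the daily anomaly.
#' @param noise_sd Marginal standard deviation of the variable's own AR(1)
#'   anomaly (coupling contributions add to this).
#' @param trend A [trend_spec()].
#' @return A list of class `var_spec`.
#' @export
var_spec <- function(name, units, tail, mean, amp, phase, amp_trend = 0,
                     ar1_rho = 0.9, noise_sd = 0, trend = trend_spec(0)) {
  stopifnot(abs(ar1_rho) < 1, noise_sd >= 0)
  structure(list(name = name, units = units, tail = tail, mean = mean,
                 amp = amp, phase = phase, amp_trend = amp_trend,
                 ar1_rho = ar1_rho, noise_sd = noise_sd, trend = trend),
            class = "var_spec")
}

#' Full scenario-world configuration
#'
#' @param grid List with `n_lat`, `n_lon` and optional explicit `lat`, `lon`
#'   centre vectors (defaults to a regular global grid).
#' @param years_daily_hist,years_daily_future Daily output segments.
#' @param years_monthly Monthly archive span (must contain both daily
#'   segments; for adaptive baselines it should start at least a window
#'   length before the first target year).
#' @param variables Named list of [var_spec()] blocks.
#' @param coupling List with `source` (variable whose anomalies drive the
#'   others) and `coef` (named coefficients of each coupled variable's anomaly
#'   on the source anomaly).
#' @param scenario_kinds Named character map from scenario label to trend kind.
#' @param rng_seed Master seed.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(grid = list(n_lat = 10L, n_lon = 20L),
                            years_daily_hist = c(1975L, 2014L),
                            years_daily_future = c(2061L, 2100L),
                            years_monthly = c(1875L, 2100L),
                            variables,
                            coupling = list(source = NULL, coef = NULL),
                            scenario_kinds = c(historical = "linear",
                                               mitigation = "plateau",
                                               high = "accelerating"),
                            rng_seed = 1L) {
  if (is.null(grid$lat)) {
    dl <- 180 / grid$n_lat
    grid$lat <- seq(-90 + dl / 2, 90 - dl / 2, by = dl)
  }
  if (is.null(grid$lon)) {
    dl <- 360 / grid$n_lon
    grid$lon <- seq(-180 + dl / 2, 180 - dl / 2, by = dl)
  }
  grid$n_lat <- length(grid$lat); grid$n_lon <- length(grid$lon)
  stopifnot(sum(noleap_month_lengths()) == 365L)
  stopifnot(years_monthly[1] <= years_daily_hist[1],
            years_daily_hist[2] < years_daily_future[1])
  stopifnot(!is.null(names(variables)), all(vapply(variables, inherits,
            TRUE, "var_spec")))
  if (!is.null(coupling$source)) {
    stopifnot(coupling$source %in% names(variables))
  }
  structure(list(grid = grid, years_daily_hist = as.integer(years_daily_hist),
                 years_daily_future = as.integer(years_daily_future),
                 years_monthly = as.integer(years_monthly),
                 variables = variables, coupling = coupling,
                 scenario_kinds = scenario_kinds,
                 rng_seed = as.integer(rng_seed)),
            class = "scenario_config")
}

#' Default scenario configuration
#'
#' A stylised four-variable world (SST `tos` in degC, hydrogen ion
#' concentration `hplus` in mol/kg, surface `spco2` in uatm, aragonite
#' saturation state `omega`, dimensionless) on a regular 10 x 20 global grid:
#' latitude-dependent means, seasonal amplitudes and hemisphere-dependent
#' phases; common warming/acidification ramp diverging in 2040 into a
#' mitigation plateau or an accelerating high-emission path; AR(1) daily
#' anomalies with the acidification variables coupled to the SST anomaly
#' (positively for `hplus`/`spco2`, negatively for `omega`, whose seasonal
#' phase also opposes SST).
#'
#' @param rng_seed Master seed.
#' @param n_lat,n_lon Grid size.
#' @return A `scenario_config`.
#' @export
default_scenario_config <- function(rng_seed = 1L, n_lat = 10L, n_lon = 20L) {
  rad <- function(lat) lat * pi / 180
  nh_phase <- function(lat) ifelse(lat >= 0, 196, 15)
  sh_phase <- function(lat) ifelse(lat >= 0, 15, 196)
  vars <- list(
    tos = var_spec("tos", "degC", "upper",
                   mean = function(lat) 28 * cos(rad(lat))^1.5,
                   amp = function(lat) 0.5 + 4 * sin(rad(lat))^2,
                   phase = nh_phase, amp_trend = 0.02,
                   ar1_rho = 0.9, noise_sd = 0.4,
                   trend = trend_spec(0.25, accel = 0.02)),
    hplus = var_spec("hplus", "mol/kg", "upper",
                     mean = 8.0e-9,
                     amp = function(lat) 5e-10 + 5e-10 * sin(rad(lat))^2,
                     phase = nh_phase, amp_trend = 0.05,
                     ar1_rho = 0.9, noise_sd = 0.7e-10,
                     trend = trend_spec(4e-10, plateau_peak = 0.8,
                                        accel = 4e-10)),
    spco2 = var_spec("spco2", "uatm", "upper",
                     mean = 360,
                     amp = function(lat) 20 + 25 * sin(rad(lat))^2,
                     phase = nh_phase, amp_trend = 0.06,
                     ar1_rho = 0.9, noise_sd = 4,
                     trend = trend_spec(25, plateau_peak = 0.8, accel = 15)),
    omega = var_spec("omega", "1", "lower",
                     mean = function(lat) 2.0 + 1.8 * cos(rad(lat))^2,
                     amp = function(lat) 0.08 + 0.12 * sin(rad(lat))^2,
                     phase = sh_phase, amp_trend = 0.02,
                     ar1_rho = 0.9, noise_sd = 0.03,
                     trend = trend_spec(-0.05, plateau_peak = 0.8,
                                        accel = -0.03))
  )
  scenario_config(grid = list(n_lat = n_lat, n_lon = n_lon),
                  variables = vars,
                  coupling = list(source = "tos",
                                  coef = c(hplus = 1.5e-10, spco2 = 6,
                                           omega = -0.03)),
                  rng_seed = rng_seed)
}

#' Hydrogen ion concentration from pH
#'
#' `H+ = 10^(-pH)` in mol/kg; vectorises over arrays.  Non-finite input is
#' treated as missing and propagated as `NA`; finite values outside (0, 14)
#' are an error.
#'
#' @param ph pH values.
#' @return H+ concentrations (mol/kg), same shape as `ph`.
#' @export
ph_to_hplus <- function(ph) {
  bad <- !is.finite(ph)
  if (any(ph[!bad] <= 0 | ph[!bad] >= 14)) {
    stop("pH values must lie in (0, 14)")
  }
  out <- 10^(-ph)
  out[bad] <- NA_real_
  out
}

# --- noise streams -----------------------------------------------------------

.stream_seed <- function(master, key) {
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483563
  as.integer((abs(master) * 2654435 + h) %% 2147483563)
}

# Stationary AR(1) noise, time x cell; sd is the marginal standard deviation.
.ar1_noise <- function(n, ncell, rho, sd, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  e <- matrix(stats::rnorm(n * ncell), n, ncell)
  if (sd == 0) return(matrix(0, n, ncell))
  e[1, ] <- e[1, ] * sd
  if (n > 1L) e[-1, ] <- e[-1, ] * (sd * sqrt(1 - rho^2))
  x <- stats::filter(e, rho, method = "recursive")
  matrix(as.numeric(x), n, ncell)
}

# Marginal sd and lag-1 autocorrelation of calendar-month means of daily AR(1)
# noise (30-day month approximation), used to generate the monthly archive
# directly outside the daily segments.
.monthly_ar1_params <- function(rho, sd) {
  if (sd == 0) return(list(sd = 0, rho = 0))
  L <- 30
  k <- seq_len(L - 1)
  v <- sd^2 / L^2 * (L + 2 * sum((L - k) * rho^k))
  s1 <- (1 - rho^L) / (1 - rho)
  cv <- sd^2 * s1 * (rho * (1 - rho^L) / (1 - rho)) / L^2
  list(sd = sqrt(v), rho = max(min(cv / v, 0.99), -0.99))
}

.resolve_param <- function(p, lat, lon) {
  ncell <- length(lat) * length(lon)
  cl <- .cell_lat(lat, lon)
  if (is.function(p)) return(p(cl))
  if (length(p) == 1L) return(rep(p, ncell))
  if (length(p) == length(lat)) return(rep(p, times = length(lon)))
  if (length(p) == ncell) return(p)
  stop("spatial parameter must be scalar, length n_lat, length n_cell, ",
       "or a function of latitude")
}

# --- generation --------------------------------------------------------------

# all noise streams for one variable; keys are scenario-independent so that
# scenarios share internal variability exactly
.var_streams <- function(cfg, vs, gaps) {
  ncell <- cfg$grid$n_lat * cfg$grid$n_lon
  nyh <- diff(cfg$years_daily_hist) + 1L
  nyf <- diff(cfg$years_daily_future) + 1L
  mp <- .monthly_ar1_params(vs$ar1_rho, vs$noise_sd)
  s <- function(key) .stream_seed(cfg$rng_seed, paste0(vs$name, "/", key))
  out <- list(
    daily_hist = .ar1_noise(365L * nyh, ncell, vs$ar1_rho, vs$noise_sd,
                            s("daily_hist")),
    daily_future = .ar1_noise(365L * nyf, ncell, vs$ar1_rho, vs$noise_sd,
                              s("daily_future"))
  )
  for (g in names(gaps)) {
    ny <- diff(gaps[[g]]) + 1L
    out[[g]] <- .ar1_noise(12L * ny, ncell, mp$rho, mp$sd, s(g))
  }
  out
}

#' Generate one scenario's daily fields and monthly archive
#'
#' Produces, for every configured variable, daily fields over the configured
#' daily segments (the historical segment always; the future segment for
#' future scenarios) and a monthly archive over the monthly span.  Monthly
#' values over years covered by daily output are exact calendar-month means
#' of the daily values; other years are generated directly at monthly
#' resolution with noise moments matched to month-averaged daily AR(1) noise.
#' Identical configuration and seed give bit-identical output, and scenarios
#' share the same noise streams, so trajectories are identical before the
#' divergence year.
#'
#' @param config A [scenario_config()].
#' @param scenario Scenario label (one of `names(config$scenario_kinds)`).
#' @return List with `scenario`, `daily_hist`, `daily_future` (named lists of
#'   [daily_field()]s; `daily_future` is `NULL` for the historical scenario)
#'   and `monthly` (named list of [monthly_archive()]s).
#' @export
generate_scenario <- function(config, scenario) {
  stopifnot(inherits(config, "scenario_config"))
  if (!scenario %in% names(config$scenario_kinds)) {
    stop("unknown scenario label '", scenario, "'; configured: ",
         paste(names(config$scenario_kinds), collapse = ", "))
  }
  kind <- config$scenario_kinds[[scenario]]
  lat <- config$grid$lat; lon <- config$grid$lon
  is_hist <- scenario == "historical"
  ym <- config$years_monthly
  if (is_hist) ym <- c(ym[1], config$years_daily_hist[2])

  # monthly-resolution gaps not covered by daily output
  gaps <- list()
  if (ym[1] < config$years_daily_hist[1]) {
    gaps$monthly_pre <- c(ym[1], config$years_daily_hist[1] - 1L)
  }
  if (!is_hist && ym[2] > config$years_daily_hist[2]) {
    gaps$monthly_mid <- c(config$years_daily_hist[2] + 1L,
                          config$years_daily_future[1] - 1L)
  }
  if (!is_hist && ym[2] > config$years_daily_future[2]) {
    gaps$monthly_post <- c(config$years_daily_future[2] + 1L, ym[2])
  }

  # noise: source variable first, then couple the others to it
  src <- config$coupling$source
  streams <- list()
  ord <- names(config$variables)
  if (!is.null(src)) ord <- c(src, setdiff(ord, src))
  for (v in ord) {
    st <- .var_streams(config, config$variables[[v]], gaps)
    if (!is.null(src) && v != src) {
      cf <- config$coupling$coef[[v]]
      if (!is.null(cf) && cf != 0) {
        for (k in names(st)) st[[k]] <- st[[k]] + cf * streams[[src]][[k]]
      }
    }
    streams[[v]] <- st
  }

  assemble_daily <- function(vs, years, anom) {
    ax <- .daily_axis(years)
    t <- decimal_year(ax$year, ax$doy)
    mean_c <- .resolve_param(vs$mean, lat, lon)
    amp_c <- .resolve_param(vs$amp, lat, lon)
    ph_c <- .resolve_param(vs$phase, lat, lon)
    ampf <- pmax(0, 1 + vs$amp_trend * (t - vs$trend$ref_year) / 10)
    seas <- cos(outer(ax$doy, ph_c, function(d, p) 2 * pi * (d - p) / 365)) *
      rep(amp_c, each = ax$n) * ampf
    tr <- trend_value(vs$trend, t, kind)
    vals <- seas + anom + rep(mean_c, each = ax$n) + tr
    daily_field(vals, vs$name, vs$units, vs$tail, years, lat, lon)
  }

  assemble_monthly_gap <- function(vs, years, anom) {
    ax <- .monthly_axis(years)
    t <- .decimal_year_month(ax$year, ax$month)
    mean_c <- .resolve_param(vs$mean, lat, lon)
    amp_c <- .resolve_param(vs$amp, lat, lon)
    ph_c <- .resolve_param(vs$phase, lat, lon)
    mcos <- .month_mean_cos(ph_c) # 12 x ncell
    ampf <- pmax(0, 1 + vs$amp_trend * (t - vs$trend$ref_year) / 10)
    seas <- mcos[ax$month, , drop = FALSE] * rep(amp_c, each = ax$n) * ampf
    tr <- trend_value(vs$trend, t, kind)
    seas + anom + rep(mean_c, each = ax$n) + tr
  }

  out <- list(scenario = scenario, daily_hist = list(),
              daily_future = if (is_hist) NULL else list(), monthly = list())
  for (v in names(config$variables)) {
    vs <- config$variables[[v]]
    dh <- assemble_daily(vs, config$years_daily_hist, streams[[v]]$daily_hist)
    out$daily_hist[[v]] <- dh
    blocks <- list()
    if (!is.null(gaps$monthly_pre)) {
      blocks[[length(blocks) + 1L]] <-
        assemble_monthly_gap(vs, gaps$monthly_pre, streams[[v]]$monthly_pre)
    }
    blocks[[length(blocks) + 1L]] <- monthly_means(dh)$values
    if (!is_hist) {
      df <- assemble_daily(vs, config$years_daily_future,
                           streams[[v]]$daily_future)
      out$daily_future[[v]] <- df
      if (!is.null(gaps$monthly_mid)) {
        blocks[[length(blocks) + 1L]] <-
          assemble_monthly_gap(vs, gaps$monthly_mid, streams[[v]]$monthly_mid)
      }
      blocks[[length(blocks) + 1L]] <- monthly_means(df)$values
      if (!is.null(gaps$monthly_post)) {
        blocks[[length(blocks) + 1L]] <-
          assemble_monthly_gap(vs, gaps$monthly_post,
                               streams[[v]]$monthly_post)
      }
    }
    out$monthly[[v]] <- monthly_archive(do.call(rbind, blocks), vs$name,
                                        vs$units, vs$tail, ym, lat, lon)
  }
  out
}
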