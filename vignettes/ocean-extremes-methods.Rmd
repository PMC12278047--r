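---
title: "Diagnosing ocean warming and acidification extreme days: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing ocean warming and acidification extreme days: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Whether a day counts as an ocean "extreme" depends on methodological choices
that are easy to leave implicit: is the threshold an absolute level with
physiological meaning, or a percentile of a reference distribution?  Is the
percentile taken relative to the full distribution (seasonally constant, SC)
or relative to the time of year (seasonally varying, SV)?  And is the
reference period fixed in the past, or does it roll forward with time, as it
would for organisms able to adapt to gradual change?  These choices can turn
the same projected fields into qualitatively different pictures of ecosystem
stress.  `oaextremes` implements the full matrix of these definitions for
four surface stressor variables — sea surface temperature (`tos`, degC),
hydrogen ion concentration (`hplus`, mol/kg), CO2 partial pressure (`spco2`,
uatm) and aragonite saturation state (`omega`, dimensionless) — together
with coral-specific metrics and compound-event statistics, and pairs them
with a synthetic scenario generator so that every stage can be verified on
data whose truth is known.

All calculations use a 365-day no-leap calendar (the convention of
Earth-system-model output); day-of-year runs 1-365 and the decimal time of
day `d` in year `y` is `y + (d - 0.5)/365`.

# Threshold definitions

## Fixed-baseline percentile thresholds

Thresholds default to the 95th percentile for variables whose stressful tail
is the upper one (`tos`, `hplus`, `spco2`) and the 5th for `omega`, which
declines under acidification; the level is an explicit argument everywhere
(93, 95, 98 are the levels worth exploring).  Percentiles are estimated by
linear interpolation between order statistics (R's type-7 default).  With a
continuous 40-year daily reference this makes the self-referenced exceedance
count exact: `0.05 * 40 * 365 = 730` days per cell, which the test suite
asserts.  Exceedance is strict — a value exactly at the threshold is not
extreme — so the self-reference count can never exceed the nominal rate.

* `fit_fixed_sc()` — one constant per cell, the percentile of all reference
  days (SC).
* `fit_fixed_sv_binned()` — the year is cut into five-day bins (73 bins),
  the percentile estimated per bin, and the binned levels carried back to
  365-day resolution with a circular Gaussian filter with a 10-day
  timescale.  Because each bin has its own level, seasonal differences in
  *variance* as well as in the mean are absorbed, which makes the seasonal
  distribution of extreme days nearly uniform.
* `fit_fixed_sv_anomaly()` — the smoothed day-of-year climatology is
  subtracted, a single anomaly percentile is estimated for the whole period,
  and the threshold is climatology + that constant.  Under homoscedastic
  noise this is practically indistinguishable from the binned variant (the
  tests require extreme-day counts within 10%), but when noise variance
  itself has a seasonal cycle the two differ by design: the binned variant
  keeps extremes seasonally uniform, the anomaly variant concentrates them
  in the noisy season.  Both are provided; the anomaly variant is the basis
  of the adaptive SV extension because it decomposes into a climatology plus
  a constant.

The Gaussian smoothing uses sigma = 10 days, kernel truncated at 4 sigma,
wrapped circularly over the year boundary; the same filter is applied to
binned thresholds and to seasonal climatologies so the two SV variants are
directly comparable.

## Adaptive (rolling-baseline) thresholds

Adaptive thresholds reference the `N` years *preceding* each target year
(the target year itself is excluded; windows never shorten silently — an
archive too short for the window is an error).  `N = 100` years is the
default adaptation timescale, taken from the coral-bleaching literature; the
window length is a parameter.

Outside the daily time slices only monthly fields exist, so the daily
95th/5th percentile cannot be computed directly.  The annual extreme of
monthly means (AMM) serves as a proxy: for a pure sinusoidal seasonal cycle
sampled daily over a calendar-month year, the maximum monthly mean falls at
roughly the 90-96th percentile of the year's daily values depending on how
the cycle aligns with month boundaries, with a phase-average near 93.3
(`idealized_amm_percentile()`, `idealized_amm_sweep()`).  Two constructions
of this idealized result are implemented: `months = "calendar"` (daily
sampling, calendar months, empirical rank) and `months = "equal"` (twelve
equal-length months ranked against the continuous cosine distribution).
Their phase-sweep statistics differ slightly — the calendar construction
gives a wider range — and both are pinned against independent brute-force
values in the tests.  `calibrate_amm_percentile()` performs the empirical
counterpart: it scans integer percentiles and reports RMSE and bias of the
AMM against each year's daily percentile, pooled over cells and years; on
the default synthetic fields the RMSE-minimising level is 93-94 for the
upper tail and 6-7 for the lower.

* `adaptive_sc_threshold()` — the windowed mean of the AMM series is used
  *directly* as the threshold level, i.e. the effective level is the
  93rd-94th (or 6th-7th) percentile, not re-inflated to 95/5.  Under a
  linear AMM trend of `m` per year the threshold lags the target-year AMM by
  `m (N + 1) / 2`, which the tests verify in closed form.
* `adaptive_sv_threshold()` — the historical SV (anomaly-variant) threshold
  plus the difference between the rolling window's and the historical
  period's monthly climatologies, interpolated to day of year.  The
  interpolation is linear between month midpoints with periodic wrap — the
  simplest periodic interpolant that passes through the twelve monthly
  anchors.  (Whether month midpoints or month starts should anchor the
  interpolation is underdetermined; midpoints are the natural reading since
  a monthly mean estimates the mid-month value.)

`count_extremes_adaptive()` applies either construction year by year over a
daily segment, so each year is referenced to its own preceding window.

## Absolute and coral thresholds

`absolute_exceedance()` applies spatially and temporally constant levels,
with presets for aragonite undersaturation (`omega_1`: Omega_a < 1), the
coral habitat / reef-sediment dissolution level (`omega_3`: Omega_a < 3) and
environmental hypercapnia (`hypercapnia`: pCO2 > 1000 uatm).  Strict
inequalities, consistent with the percentile machinery.

Degree heating weeks (`dhw()`) accumulate thermal stress above the maximum
monthly mean (MMM): the hotspot is `H(t) = SST(t) - MMM`, and DHW at day `t`
sums qualifying hotspots over the 84 days (12 weeks) from `t - 83` to `t`,
divided by 7.  The MMM is the warmest month of a monthly climatology
detrended relative to decimal year 1988.2857
(`detrended_monthly_climatology()` fits an OLS trend per cell and adjusts
every value to the pivot before averaging by month; the adjustment makes the
climatology exactly invariant to adding any pivot-anchored linear trend).
One wording issue deserves a visible switch: the accumulation rule is
sometimes stated as counting hotspots "less than or equal to 1 degC", which
contradicts the NOAA Coral Reef Watch definition in which hotspots of *at
least* 1 degC accumulate.  The default (`count_rule = "ge1"`) follows the
Coral Reef Watch definition; `count_rule = "le1"` reproduces the literal
wording (restricted to positive hotspots so DHW stays non-negative).  The
first 83 days of a segment are computed over the partial window by default
(negligible against 40-year segments); `mask_partial = TRUE` masks them.

DHW and SC-percentile thresholds can disagree in both directions, and the
test suite demonstrates each regime: where variability is small the 1 degC
offset above MMM is a proportionally large hurdle and DHW flags *fewer* days
than the SC 95th percentile; under large, persistent (red-noise) anomalies
the 12-week accumulation extends events and flags *more*.

# Event statistics

* `compound()` — day-wise intersection (simultaneous stress) or union
  (either stress) of aligned masks; the Boolean inequalities
  (intersection <= each <= union <= sum) are asserted as properties.
* `detrended_percentile()` / `change_summary()` — percentile change between
  two periods with the 40-year OLS trend removed relative to each period's
  midpoint (1995 and 2081 for the default segments).  The seasonal cycle is
  *not* removed, so growing seasonal amplitude shows up as amplification:
  percentile change exceeding mean change.  Detrending is exactly invariant
  to midpoint-anchored trends and recovers a pure inter-period shift exactly
  at every level; both are tested.
* `joint_distribution()` / `joint_overlap()` — area-weighted 2-d histogram
  of per-cell percentile pairs (default 60 x 60 bins over the data range)
  with a highest-density coverage region: bins are accumulated in order of
  decreasing weight until the target fraction (default 90%) of ocean area is
  enclosed.  A highest-density region is one defensible reading of a
  "region enclosing ~90% of cells" contour; the choice is configurable
  through `coverage` and `bins`.  Overlap between two periods' regions is
  reported as the Jaccard fraction of shared bins on a common grid.
* `site_report()` — per-site partition of days into only-X / only-Y / both /
  neither, summing to 100%.

Global summaries weight cells by the cosine of latitude
(`area_weights()`), renormalising over non-missing cells.

# The synthetic scenario generator

`generate_scenario()` emulates the statistical structure the analysis
assumes, not any particular model:

```
value(t, cell) = mean(cell)
               + trend_scenario(t)
               + amp(cell) * ampfactor(t) * cos(2 pi (doy - phase(cell)) / 365)
               + AR(1) anomaly
```

with `ampfactor(t) = 1 + amp_trend * (t - 1995)/10` (fractional amplitude
change per decade) and anomalies coupled across variables: the `hplus` and
`spco2` anomalies add a positive multiple of the SST anomaly, `omega` a
negative multiple, and the `omega` seasonal phase opposes SST so its
seasonal climatology anti-correlates with temperature cell by cell.

Scenario trajectories share a common ramp — flat before 1900, then a cubic
path whose rate grows quadratically to `base_rate` (units/decade) at the
2040 divergence year, emulating slowly accelerating historical forcing —
and then diverge: the high-emission kind keeps accelerating
(`accel` units/decade^2), while the mitigation kind relaxes its rate to zero
on a `plateau_tau = 15` year timescale.  For temperature the mitigation
plateau is monotone (committed warming holds); for the CO2-tracking
variables (`hplus`, `spco2`, `omega`) the response peaks and partially
recovers (`plateau_peak = 0.8`), reflecting a peaking and declining
atmospheric CO2 burden under strong mitigation.  All kinds are continuous
and C1 across the divergence year and bit-identical before it, because every
noise stream is seeded from (master seed, variable, stream) independently of
the scenario label.

Default magnitudes are chosen to be representative of open-ocean surface
conditions: SST mean `28 cos(lat)^1.5` degC with seasonal amplitude
0.5-4.5 degC (hemisphere-dependent phase, maximum around day 196 in the
north), daily anomaly sd 0.4 degC with lag-1 autocorrelation 0.9; H+ around
8e-9 mol/kg with amplitude 5e-10 to 1e-9; pCO2 around 360 uatm with
amplitude 20-45 uatm and the strongest fractional amplitude growth
(+6%/decade); Omega_a 2.0-3.8 with amplitude 0.08-0.2.  Divergence-year
rates (+0.25 degC, +4e-10 mol/kg, +25 uatm, -0.05 per decade) put the
mitigation and high-emission end-of-century states near +1.3/+2.3 degC and
-0.26/-0.9 Omega_a relative to 1995.  These choices were fixed once, on the
criterion that the documented behaviour of the method should emerge from
realistic signal-to-variability ratios: the AMM calibration lands on the
93rd-94th/6th-7th percentile, fixed-baseline OA extremes saturate under both
future scenarios while adaptive extremes separate them, and aragonite
undersaturation appears only at high latitudes late in the high-emission
century.

The monthly archive (1875-2100 by default) equals calendar-month means of
the daily fields wherever daily output exists; other years are generated
directly at monthly resolution, with AR(1) parameters analytically matched
to the month-mean of the daily process (variance and adjacent-month
covariance computed from the daily lag-1 autocorrelation over a 30-day
month).  A test checks the two sources agree in distribution on overlap
years.

What the generator deliberately does **not** emulate: spatial correlation of
anomalies (cells are independent, so spatial patterns of synthetic extremes
are noisier than real fields), interannual-to-decadal variability beyond
what daily AR(1) aggregates to, skewness, marine-heatwave event structure
beyond red noise, and any carbonate-system chemistry (Omega_a, pCO2 and H+
are generated, not solved from DIC/alkalinity; H+ is related to pH only
through `ph_to_hplus()`).  Passing tests therefore show the *method* behaves
as documented under known statistical structure, not that any real region
behaves like a synthetic cell.

# Storage, pipeline and reproducibility

Fields travel as a self-describing plain-text format (header with variable,
units, stressful tail, `noleap` calendar, steps per year, year range and
grid centres; one explicitly indexed row per time step) written and read by
`write_field()`/`read_field()` at full double precision.  Leap calendars,
incomplete years and non-monotone time axes are rejected on read.

`run_pipeline()` chains simulate -> thresholds -> count -> coral -> events
-> report through files only, so any stage can be rerun or tested in
isolation; a `manifest.json` records the config hash, seed, stages, outputs
and package version, and a rerun with the same config and seed is
bit-identical.  The `oax` script under `exec/` exposes `simulate` and
`pipeline` subcommands with exit codes 0/1/2 (ok / user error / internal).
Site sets are plain `name,lat,lon` tables; points map to the nearest cell by
rectangular (lat, lon) distance — adequate at the grid scales used here —
with ties broken toward the lower cell index.

# Numerical choices and degenerate inputs

* Percentile estimator: type 7 (linear interpolation between order
  statistics); chosen as the common default, and the self-reference
  tolerance in the tests allows for estimator variants.
* Strict inequalities for all exceedance tests; constant fields therefore
  produce zero extreme days against their own thresholds.
* Empty or all-missing samples are errors, not NAs; percentile levels are
  validated to (0, 100); `ph_to_hplus()` propagates non-finite values as
  missing and rejects finite pH outside (0, 14).
* Missing cells drop out of global means with weight renormalisation.
* Nearest-cell ties break toward the lower cell index (deterministic).
* Adaptive windows must be fully covered by the archive; no silent
  shortening.

# Problem sizes

The test suite and examples run on deliberately small worlds: grids of 2 x 3
to 6 x 10 cells, 40-year daily segments, and a 1875-2100 monthly archive.
At these sizes the full suite completes in well under a minute and the
end-to-end scenario comparison (three scenarios, four variables, adaptive
and fixed thresholds) in a few tens of seconds.  The default configuration
grid is 10 x 20; all operations accept any grid, and memory scales linearly
in cells x days (a 40-year daily variable on 10 x 20 cells is about 23 MB).

# Known limitations

* No spatial correlation in synthetic anomalies; no regridding or GIS
  ingestion (site sets are plain coordinate tables).
* The AMM proxy inherits its 93-94/6-7 effective level; adaptive SC
  thresholds are therefore slightly less extreme than nominal 95/5, by
  design.
* Event counting is day counting: no minimum-duration criterion and no
  event labelling (DHW is the only duration-sensitive metric).
* The plain-text field format trades compactness for transparency; it is
  not a gridded-binary interchange format.
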