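# Demonstration pipeline configuration: small grid and decade-long daily
# segments so a full run finishes in well under a minute.  Generator
# parameters not listed here use the package defaults.
grid:
  n_lat: 3
  n_lon: 4
rng_seed: 1
years_daily_hist: [2005, 2014]
years_daily_future: [2091, 2100]
years_monthly: [1905, 2100]
analysis:
  level: 95
  adaptive_window: 100
  dhw_level: 4
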