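# Reproducible file-based pipeline: simulate -> thresholds -> count -> coral
# -> events -> report.  Stages hand off through files only, so each stage is
# independently testable and a run is reproducible from its manifest.

.pipeline_stages <- c("simulate", "thresholds", "count", "coral", "events",
                      "report")

#' Read a pipeline configuration file
#'
#' YAML with optional keys: `grid` (`n_lat`, `n_lon`), `rng_seed`,
#' `years_daily_hist`, `years_daily_future`, `years_monthly`, `scenarios`
#' (labels to simulate), `analysis` (`level`, `adaptive_window`,
#' `dhw_level`), `sites` (path to a name,lat,lon CSV), and `variables`
#' (named blocks overriding scalar generator parameters: `mean`, `amp`,
#' `phase`, `amp_trend`, `ar1_rho`, `noise_sd`, `base_rate`, `accel`,
#' `plateau_tau`).  Unspecified values fall back to
#' [default_scenario_config()].
#'
#' @param path YAML file path.
#' @return List with `config` (a `scenario_config`), `scenarios`, `analysis`,
#'   `sites`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  g <- y$grid
  cfg <- default_scenario_config(
    rng_seed = if (!is.null(y$rng_seed)) y$rng_seed else 1L,
    n_lat = if (!is.null(g$n_lat)) g$n_lat else 10L,
    n_lon = if (!is.null(g$n_lon)) g$n_lon else 20L
  )
  for (k in c("years_daily_hist", "years_daily_future", "years_monthly")) {
    if (!is.null(y[[k]])) cfg[[k]] <- as.integer(y[[k]])
  }
  for (v in names(y$variables)) {
    if (!v %in% names(cfg$variables)) {
      stop("config error at variables.", v, ": unknown variable")
    }
    blk <- y$variables[[v]]
    for (f in names(blk)) {
      if (f %in% c("mean", "amp", "phase", "amp_trend", "ar1_rho",
                   "noise_sd")) {
        cfg$variables[[v]][[f]] <- blk[[f]]
      } else if (f %in% c("base_rate", "accel", "plateau_tau")) {
        cfg$variables[[v]]$trend[[f]] <- blk[[f]]
      } else {
        stop("config error at variables.", v, ".", f, ": unknown key")
      }
    }
  }
  scen <- if (!is.null(y$scenarios)) y$scenarios else
    names(cfg$scenario_kinds)
  bad <- setdiff(scen, names(cfg$scenario_kinds))
  if (length(bad)) stop("config error at scenarios: unknown label(s) ",
                        paste(bad, collapse = ", "))
  analysis <- list(level = 95, adaptive_window = 100L, dhw_level = 4)
  for (k in names(y$analysis)) {
    if (!k %in% names(analysis)) stop("config error at analysis.", k,
                                      ": unknown key")
    analysis[[k]] <- y$analysis[[k]]
  }
  list(config = cfg, scenarios = scen, analysis = analysis, sites = y$sites)
}

.sim_path <- function(dir, scenario, var, segment) {
  file.path(dir, "simulate", sprintf("%s_%s_%s.txt", scenario, var, segment))
}

.need_artifact <- function(path, stage) {
  if (!file.exists(path)) {
    stop("missing artifact '", path, "': run stage '", stage, "' first")
  }
  path
}

.write_tsv <- function(df, path) {
  utils::write.table(format(df, digits = 10, trim = TRUE, scientific = NA),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the extreme-day analysis pipeline
#'
#' Executes the requested stages in order against a configuration file,
#' writing every artifact under `out_dir` and a run manifest
#' (`manifest.json`) recording the config hash, seed, stages, outputs and
#' package version.  Re-running with the same configuration and seed
#' reproduces identical numerical outputs.
#'
#' Stages: `simulate` (scenario fields to text storage), `thresholds` (fixed
#' SC and SV-anomaly thresholds from the historical segment), `count` (fixed
#' and adaptive extreme-day masks and global summaries, the Figure-1/4
#' analogues), `coral` (MMM, DHW and absolute thresholds, Figure-6
#' analogue), `events` (compound DHW/aragonite events, percentile-change and
#' joint-overlap summaries, Figure-7/8 analogues), `report` (per-site
#' stacked percentages, Figure-10 analogue).
#'
#' @param config_path YAML configuration ([read_pipeline_config()]).
#' @param out_dir Output directory (created if needed).
#' @param stages Character vector of stages (default: all, in order).
#' @param seed Optional override of the configured master seed.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config_path, out_dir,
                         stages = .pipeline_stages, seed = NULL) {
  stages <- match.arg(stages, .pipeline_stages, several.ok = TRUE)
  stages <- .pipeline_stages[.pipeline_stages %in% stages]
  pc <- read_pipeline_config(config_path)
  if (!is.null(seed)) pc$config$rng_seed <- as.integer(seed)
  cfg <- pc$config
  vars <- names(cfg$variables)
  lvl <- pc$analysis$level
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character()
  note <- function(p) { outputs <<- c(outputs, p); p }

  if ("simulate" %in% stages) {
    dir.create(file.path(out_dir, "simulate"), showWarnings = FALSE)
    for (sc in pc$scenarios) {
      w <- generate_scenario(cfg, sc)
      for (v in vars) {
        write_field(w$daily_hist[[v]], note(.sim_path(out_dir, sc, v,
                                                      "daily_hist")))
        if (!is.null(w$daily_future)) {
          write_field(w$daily_future[[v]], note(.sim_path(out_dir, sc, v,
                                                          "daily_future")))
        }
        write_field(w$monthly[[v]], note(.sim_path(out_dir, sc, v,
                                                   "monthly")))
      }
    }
  }

  hist_label <- pc$scenarios[1]
  read_sim <- function(sc, v, seg, stage_needed = "simulate") {
    read_field(.need_artifact(.sim_path(out_dir, sc, v, seg), stage_needed))
  }
  seg_of <- function(sc) if (sc == hist_label) "daily_hist" else "daily_future"

  if ("thresholds" %in% stages) {
    dir.create(file.path(out_dir, "thresholds"), showWarnings = FALSE)
    for (v in vars) {
      dh <- read_sim(hist_label, v, "daily_hist")
      lv <- if (dh$tail == "upper") lvl else 100 - lvl
      for (m in c("sc", "sv")) {
        thr <- if (m == "sc") fit_fixed_sc(dh, level = lv) else
          fit_fixed_sv_anomaly(dh, level = lv)
        p <- note(file.path(out_dir, "thresholds",
                            sprintf("%s_%s.tsv", v, m)))
        utils::write.table(rbind(thr$values), p, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = FALSE)
      }
    }
  }

  if ("count" %in% stages) {
    dir.create(file.path(out_dir, "count"), showWarnings = FALSE)
    summ <- NULL
    for (sc in pc$scenarios) {
      for (v in vars) {
        d <- read_sim(sc, v, seg_of(sc))
        lv <- if (d$tail == "upper") lvl else 100 - lvl
        hist_daily <- read_sim(hist_label, v, "daily_hist")
        arch <- read_sim(sc, v, "monthly")
        fits <- list(
          sc_fixed = count_extremes(d, fit_fixed_sc(hist_daily, level = lv)),
          sv_fixed = count_extremes(d, fit_fixed_sv_anomaly(hist_daily,
                                                            level = lv)),
          sc_adaptive = count_extremes_adaptive(
            d, arch, pc$analysis$adaptive_window, "sc"),
          sv_adaptive = count_extremes_adaptive(
            d, arch, pc$analysis$adaptive_window, "sv",
            hist_sv = fit_fixed_sv_anomaly(hist_daily, level = lv),
            hist_years = hist_daily$years)
        )
        for (m in names(fits)) {
          p <- note(file.path(out_dir, "count",
                              sprintf("%s_%s_%s_percent.tsv", sc, v, m)))
          utils::write.table(rbind(fits[[m]]$percent), p, sep = "\t",
                             quote = FALSE, row.names = FALSE,
                             col.names = FALSE)
          summ <- rbind(summ, data.frame(
            scenario = sc, variable = v, method = m,
            global_percent = global_extreme_percent(fits[[m]])))
        }
      }
    }
    .write_tsv(summ, note(file.path(out_dir, "count",
                                    "global_extreme_percent.tsv")))
  }

  if ("coral" %in% stages) {
    dir.create(file.path(out_dir, "coral"), showWarnings = FALSE)
    arch_sst <- read_sim(hist_label, "tos", "monthly")
    clim <- detrended_monthly_climatology(arch_sst, cfg$years_daily_hist)
    base <- mmm(clim)
    summ <- NULL
    for (sc in pc$scenarios) {
      sst <- read_sim(sc, "tos", seg_of(sc))
      dm <- dhw_extreme_days(dhw(sst, base), sst, pc$analysis$dhw_level)
      masks <- list(dhw4 = dm)
      if ("omega" %in% vars) {
        om <- read_sim(sc, "omega", seg_of(sc))
        masks$omega_3 <- absolute_exceedance(om, preset = "omega_3")
        masks$omega_1 <- absolute_exceedance(om, preset = "omega_1")
      }
      if ("spco2" %in% vars) {
        pco2 <- read_sim(sc, "spco2", seg_of(sc))
        masks$hypercapnia <- absolute_exceedance(pco2, preset = "hypercapnia")
      }
      for (m in names(masks)) {
        p <- note(file.path(out_dir, "coral",
                            sprintf("%s_%s_percent.tsv", sc, m)))
        utils::write.table(rbind(masks[[m]]$percent), p, sep = "\t",
                           quote = FALSE, row.names = FALSE,
                           col.names = FALSE)
        summ <- rbind(summ, data.frame(
          scenario = sc, threshold = m,
          global_percent = global_extreme_percent(masks[[m]])))
      }
    }
    .write_tsv(summ, note(file.path(out_dir, "coral",
                                    "global_absolute_percent.tsv")))
  }

  if ("events" %in% stages) {
    dir.create(file.path(out_dir, "events"), showWarnings = FALSE)
    arch_sst <- read_sim(hist_label, "tos", "monthly")
    base <- mmm(detrended_monthly_climatology(arch_sst, cfg$years_daily_hist))
    comp <- NULL
    for (sc in pc$scenarios) {
      sst <- read_sim(sc, "tos", seg_of(sc))
      om <- read_sim(sc, "omega", seg_of(sc))
      dm <- dhw_extreme_days(dhw(sst, base), sst, pc$analysis$dhw_level)
      o3 <- absolute_exceedance(om, preset = "omega_3")
      for (mode in c("intersection", "union")) {
        cm <- compound(list(dm, o3), mode)
        comp <- rbind(comp, data.frame(
          scenario = sc, mode = mode,
          global_percent = global_extreme_percent(cm)))
      }
    }
    .write_tsv(comp, note(file.path(out_dir, "events",
                                    "compound_dhw_omega3.tsv")))
    futures <- setdiff(pc$scenarios, hist_label)
    if (length(futures)) {
      chg <- NULL
      for (sc in futures) {
        for (v in vars) {
          dh <- read_sim(hist_label, v, "daily_hist")
          df <- read_sim(sc, v, "daily_future")
          lv <- if (dh$tail == "upper") lvl else 100 - lvl
          cs <- change_summary(dh, df, level = lv)
          chg <- rbind(chg, cbind(scenario = sc, variable = v, cs$global))
        }
        sst_h <- read_sim(hist_label, "tos", "daily_hist")
        sst_f <- read_sim(sc, "tos", "daily_future")
        om_h <- read_sim(hist_label, "omega", "daily_hist")
        om_f <- read_sim(sc, "omega", "daily_future")
        jo <- joint_overlap(
          detrended_percentile(sst_h, sst_h$years, lvl),
          detrended_percentile(om_h, om_h$years, 100 - lvl),
          detrended_percentile(sst_f, sst_f$years, lvl),
          detrended_percentile(om_f, om_f$years, 100 - lvl),
          cfg$grid$lat, cfg$grid$lon)
        chg <- rbind(chg, data.frame(scenario = sc, variable = "tos/omega",
                                     statistic = "region overlap",
                                     mean = jo$overlap, spatial_sd = NA))
      }
      .write_tsv(chg, note(file.path(out_dir, "events",
                                     "percentile_change.tsv")))
    }
  }

  if ("report" %in% stages) {
    dir.create(file.path(out_dir, "report"), showWarnings = FALSE)
    sites <- if (!is.null(pc$sites)) read_sites(pc$sites) else
      read_sites(system.file("extdata", "mpa_sites_synthetic.csv",
                             package = "oaextremes", mustWork = TRUE))
    rep_all <- NULL
    for (sc in pc$scenarios) {
      sst <- read_sim(sc, "tos", seg_of(sc))
      pco2 <- read_sim(sc, "spco2", seg_of(sc))
      hist_sst <- read_sim(hist_label, "tos", "daily_hist")
      hist_pco2 <- read_sim(hist_label, "spco2", "daily_hist")
      mx <- count_extremes(sst, fit_fixed_sc(hist_sst, level = lvl))
      my <- count_extremes(pco2, fit_fixed_sc(hist_pco2, level = lvl))
      sr <- site_report(mx, my, sites)
      rep_all <- rbind(rep_all, cbind(scenario = sc, sr))
    }
    .write_tsv(rep_all, note(file.path(out_dir, "report",
                                       "site_sst_pco2.tsv")))
  }

  manifest <- list(
    config_path = normalizePath(config_path),
    config_md5 = unname(tools::md5sum(config_path)),
    seed = cfg$rng_seed,
    stages = stages,
    outputs = outputs,
    package_version = as.character(utils::packageVersion("oaextremes")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
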