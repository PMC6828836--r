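#' Assemble a full pipeline configuration
#'
#' Bundles everything one reproducible run needs: the synthetic scenario, the
#' dispersion surrogate parameters, the per-class hotspot sample size, the
#' confidence threshold, exposure thresholds, health-case specifications and
#' the crude death rate. A configuration plus its seed fully determines every
#' output.
#'
#' @param scenario a [synthetic_scenario()]; defaults to
#'   [scenario_study_preset()] seeded with `seed`.
#' @param dispersion [dispersion_params()].
#' @param n_per_class hotspots sampled per peat class and year for plume
#'   averaging (default 15; the class-mean plume converges quickly because
#'   same-day plumes are identical in source-relative coordinates).
#' @param min_confidence detection-confidence retention threshold (default 80).
#' @param thresholds exposure summary thresholds, see [summarize_exposure()].
#' @param cases health-case table, see [health_cases()].
#' @param cdr crude death rate (default 0.0058).
#' @param seed master seed; also used for the per-year sampling draws.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(scenario = NULL, dispersion = dispersion_params(),
                            n_per_class = 15L, min_confidence = 80,
                            thresholds = c(10, 20, 80), cases = health_cases(),
                            cdr = 0.0058, seed = 1L) {
  if (is.null(scenario)) scenario <- scenario_study_preset(seed = seed)
  cfg <- structure(list(scenario = scenario, dispersion = dispersion,
                        n_per_class = as.integer(n_per_class),
                        min_confidence = min_confidence, thresholds = thresholds,
                        cases = cases, cdr = cdr, seed = as.integer(seed)),
                   class = "pipeline_config")
  problems <- validate_config(cfg)
  if (length(problems)) {
    stop("invalid pipeline configuration:\n  ", paste(problems, collapse = "\n  "))
  }
  cfg
}

#' Validate a pipeline configuration
#'
#' @param config a `pipeline_config` (or plain list with the same fields).
#' @return Character vector of problems, empty when valid; each message names
#'   the offending field.
#' @export
validate_config <- function(config) {
  p <- character()
  p <- c(p, validate_scenario(config$scenario))
  if (config$n_per_class < 1) p <- c(p, "n_per_class: must be >= 1")
  if (config$min_confidence < 0 || config$min_confidence > 101)
    p <- c(p, "min_confidence: must be within 0-101")
  if (config$cdr < 0) p <- c(p, "cdr: must be non-negative")
  if (length(config$thresholds) != 3 || is.unsorted(config$thresholds))
    p <- c(p, "thresholds: need three non-decreasing values")
  cs <- config$cases
  bad <- cs$percent_of_deaths < 0 | cs$percent_of_deaths > 1
  if (any(bad)) p <- c(p, paste0("cases: percent_of_deaths outside [0, 1] for ",
                                 paste(cs$name[bad], collapse = ", ")))
  if (any(cs$beta <= 0)) p <- c(p, paste0("cases: beta must be > 0 for ",
                                          paste(cs$name[cs$beta <= 0], collapse = ", ")))
  if (any(cs$age_fraction < 0 | cs$age_fraction > 1))
    p <- c(p, "cases: age_fraction outside [0, 1]")
  p
}

#' Run the full assessment pipeline
#'
#' Orchestrates scenario generation, hotspot filtering and classification,
#' per-class plume averaging, annual scale-up and station calibration,
#' village exposure extraction and the health impact assessment with its
#' sensitivity analysis. Fully deterministic for a fixed configuration.
#'
#' A year with no retained hotspots yields a zero exposure increment for that
#' year (calibration is skipped since there is nothing to scale).
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory; when given, exposure and impact
#'   CSVs, GeoJSON, the 5-year mean field, a run log and a markdown summary
#'   are written there.
#' @param quiet suppress progress messages?
#' @return A `pipeline_result` list: `scenario`, per-year calibrated `fields`,
#'   `five_year_field`, `villages` (with exposures), `exposure_summary`,
#'   `impact`, `sensitivity`, `calibration` (per-year factors) and the echoed
#'   `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  problems <- validate_config(config)
  if (length(problems)) stop("invalid pipeline configuration: ",
                             paste(problems, collapse = "; "))
  say <- function(...) if (!quiet) message(...)

  say("generating scenario (seed ", config$seed, ") ...")
  scen <- generate_scenario(config$scenario)
  region <- config$scenario$region
  grid <- conc_field(matrix(0, region$nx, region$ny), 0, 0, region$res)

  retained <- filter_hotspots(scen$hotspots, config$min_confidence)
  if (nrow(retained) > 0) retained <- keep_on_peat(retained, scen$peat_map)
  say(nrow(retained), " of ", nrow(scen$hotspots),
      " hotspots retained at confidence >= ", config$min_confidence)

  years <- config$scenario$years
  fields <- list()
  calib <- data.frame(year = years, station_mean = NA_real_,
                      factor = NA_real_, n_shallow = 0L, n_deep = 0L)
  for (i in seq_along(years)) {
    yr <- years[i]
    avail <- retained[retained$year == yr, , drop = FALSE]
    counts <- c(shallow = sum(avail$peat_class == "shallow"),
                deep = sum(avail$peat_class == "deep"))
    calib$n_shallow[i] <- counts["shallow"]; calib$n_deep[i] <- counts["deep"]
    sser <- scen$station$series
    obs_mean <- mean(sser$pm25_ugm3[format(sser$date, "%Y") == as.character(yr)])
    calib$station_mean[i] <- obs_mean
    if (nrow(avail) == 0) {
      say(yr, ": no retained hotspots; zero exposure increment")
      fields[[as.character(yr)]] <- conc_field(matrix(0, grid$nx, grid$ny),
                                               grid$xmin, grid$ymin, grid$res,
                                               label = sprintf("annual mean, %d", yr))
      next
    }
    present <- names(counts)[counts > 0]
    sampled <- withCallingHandlers(
      sample_hotspots(avail, config$n_per_class, seed = config$seed + yr),
      warning = function(w) invokeRestart("muffleWarning"))
    kernels <- mean_plume_per_class(sampled, scen$met, config$dispersion,
                                    classes = present)
    dens <- lapply(present, function(cls)
      hotspot_density(avail[avail$peat_class == cls, ], grid))
    names(dens) <- present
    raw <- scale_up(kernels, counts[present], dens, grid)
    fld <- calibrate(raw, obs_mean, scen$station$location)
    calib$factor[i] <- attr(fld, "calibration_factor")
    fld$label <- sprintf("annual mean, %d", yr)
    fields[[as.character(yr)]] <- fld
    say(yr, ": ", sum(counts), " hotspots (", counts["shallow"], " shallow, ",
        counts["deep"], " deep); calibration factor ",
        signif(calib$factor[i], 4))
  }

  say("computing village exposures ...")
  villages <- village_exposures(fields, scen$villages)
  summary <- summarize_exposure(villages, config$thresholds)
  five_year <- conc_field(
    Reduce(`+`, lapply(fields, `[[`, "values")) / length(fields),
    grid$xmin, grid$ymin, grid$res,
    label = sprintf("%d-year mean, %d-%d", length(years), min(years), max(years)))

  say("running health impact assessment ...")
  impact <- run_hia(villages, config$cases, config$cdr)
  sens <- sensitivity_analysis(villages, config$cases, config$cdr,
                               x_o = impact$x_o)

  result <- structure(list(scenario = scen, fields = fields,
                           five_year_field = five_year, villages = villages,
                           exposure_summary = summary, impact = impact,
                           sensitivity = sens, calibration = calib,
                           config = config),
                      class = "pipeline_result")
  if (!is.null(out_dir)) write_report_bundle(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$exposure_summary)
  print(x$impact)
  invisible(x)
}

#' Write the report bundle of a pipeline run
#'
#' Emits `exposure.csv`, `villages.geojson` (with exposures), `impact.csv`
#' (the report table with whole-number deaths), `sensitivity.csv`,
#' `field_5yr_mean.csv`, `calibration.csv`, the scenario input files, a
#' `run_log.yaml` echoing seed and parameters, and `summary.md`.
#'
#' @param result a `pipeline_result`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report_bundle <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_exposure_csv(result$villages, file.path(out_dir, "exposure.csv"))
  write_rect_geojson(result$villages, file.path(out_dir, "villages.geojson"),
                     props = c("village_id", "population", "mean_pm25"))
  utils::write.csv(format_impact_table(result$impact),
                   file.path(out_dir, "impact.csv"), row.names = FALSE)
  utils::write.csv(result$sensitivity, file.path(out_dir, "sensitivity.csv"),
                   row.names = FALSE)
  utils::write.csv(result$calibration, file.path(out_dir, "calibration.csv"),
                   row.names = FALSE)
  write_field_csv(result$five_year_field, file.path(out_dir, "field_5yr_mean.csv"))
  write_scenario(result$scenario, file.path(out_dir, "inputs"))

  cfg <- result$config
  log <- list(seed = cfg$seed,
              years = cfg$scenario$years,
              n_villages = cfg$scenario$n_villages,
              total_population = cfg$scenario$total_population,
              n_per_class = cfg$n_per_class,
              min_confidence = cfg$min_confidence,
              cdr = cfg$cdr,
              x_o = result$impact$x_o,
              dispersion = unclass(cfg$dispersion),
              calibration_factors = stats::setNames(as.list(result$calibration$factor),
                                                    result$calibration$year))
  yaml::write_yaml(log, file.path(out_dir, "run_log.yaml"))
  writeLines(render_summary_md(result), file.path(out_dir, "summary.md"))
  invisible(out_dir)
}

render_summary_md <- function(result) {
  s <- result$exposure_summary
  tab <- format_impact_table(result$impact)
  lines <- c(
    "# Peat-smoke health impact assessment",
    "",
    sprintf("Seed %d; %d villages, %s inhabitants.", result$config$seed,
            s$n_villages, format(s$population, big.mark = ",")),
    "",
    "## Exposure (PM2.5 increment from peat fires)",
    "",
    sprintf("- regional village-mean: %.1f ug/m3 (range %.1f-%.1f)", s$mean, s$min, s$max),
    sprintf("- reference concentration X_o: %.2f ug/m3", s$x_o),
    sprintf("- villages < %g ug/m3: %d; >= %g: %d (%s people); > %g: %d",
            s$thresholds[1], s$villages_below_low, s$thresholds[2],
            s$villages_ge_mid, format(s$population_ge_mid, big.mark = ","),
            s$thresholds[3], s$villages_gt_high),
    "",
    "## Attributable mortality (per year)",
    "",
    "| category | age group | baseline deaths | attributable deaths | per 100k |",
    "|---|---|---|---|---|",
    sprintf("| %s | %s | %d | %d | %d |", tab$category, tab$age_group,
            tab$baseline_deaths, tab$attributable_deaths, tab$per_100k),
    "",
    "## Sensitivity (percent change in attributable deaths)",
    "",
    "| variant | category | % change |",
    "|---|---|---|",
    sprintf("| %s | %s | %.1f |", result$sensitivity$variant,
            result$sensitivity$category, result$sensitivity$pct_change)
  )
  lines
}

# ---------------------------------------------------------------------------
# Config file I/O (YAML)

#' Read a pipeline configuration file
#'
#' YAML file with optional blocks `scenario` (set `preset: study` for the
#' study-scale preset), `dispersion`, `health`,
#' `exposure` and a top-level `seed`; omitted entries fall back to the
#' defaults of [pipeline_config()]. `scenario.hotspot_totals` (one total per
#' year) is split into deep/shallow counts with the 8% deep excess.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  seed <- if (!is.null(raw$seed)) as.integer(raw$seed) else 1L
  sc <- raw$scenario %||% list()
  sc_args <- list(seed = seed)
  for (f in c("years", "n_villages", "total_population", "station_location",
              "station_annual_means", "wind", "cluster", "dry_season_weight",
              "station_noise_sd", "region")) {
    if (!is.null(sc[[f]])) sc_args[[f]] <- sc[[f]]
  }
  if (!is.null(sc_args$station_location)) sc_args$station_location <- unlist(sc_args$station_location)
  if (!is.null(sc_args$station_annual_means))
    sc_args$station_annual_means <- unlist(sc_args$station_annual_means)
  if (!is.null(sc$hotspot_totals)) {
    yrs <- sc_args$years %||% 2011:2015
    sc_args$hotspot_counts <- split_hotspot_totals(yrs, unlist(sc$hotspot_totals))
  }
  scenario <- if (isTRUE(sc$preset == "study") && length(sc_args) == 1) {
    scenario_study_preset(seed = seed)
  } else {
    do.call(synthetic_scenario, sc_args)
  }
  dp <- raw$dispersion %||% list()
  disp_args <- dp[intersect(names(dp), names(formals(dispersion_params)))]
  hl <- raw$health %||% list()
  ex <- raw$exposure %||% list()
  pipeline_config(
    scenario = scenario,
    dispersion = do.call(dispersion_params, disp_args),
    n_per_class = dp$n_per_class %||% 15L,
    min_confidence = dp$min_confidence %||% 80,
    thresholds = unlist(ex$thresholds %||% c(10, 20, 80)),
    cases = health_cases(cardiovascular_beta = hl$cardiovascular_beta %||% 0.15515),
    cdr = hl$cdr %||% 0.0058,
    seed = seed
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
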