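#' Define a synthetic fire-and-smoke scenario
#'
#' A scenario fixes everything the downstream pipeline consumes: the region
#' grid, a peat-depth map, per-year hotspot counts split into deep and shallow
#' peat, the village tiling and populations, a daily wind regime, and the
#' observed annual-mean PM2.5 at the single monitoring station used for
#' calibration. The geometry is deliberately simple — a rectangular region in
#' projected km coordinates, rectangular peat polygons and square-tile
#' villages — because the exposure and health arithmetic is invariant to
#' polygon shape and tiles make zonal statistics exactly checkable.
#'
#' @param seed integer RNG seed recorded in all outputs.
#' @param years calendar years covered.
#' @param hotspot_counts data frame with columns `year`, `deep`, `shallow`:
#'   hotspot records to generate per year and peat class.
#' @param region list with `nx`, `ny`, `res` (km): the grid extent.
#' @param n_villages number of villages tiling the region.
#' @param total_population people, summed over all villages.
#' @param station_location `c(x, y)` km; must lie inside the region.
#' @param station_annual_means named numeric, one observed annual-mean PM2.5
#'   (ug/m3) per year; this is the ground truth the dispersion model is
#'   calibrated against.
#' @param wind list `mean_speed` (m/s), `mean_direction` (degrees
#'   counter-clockwise from +x, the direction the wind blows toward),
#'   `speed_sd` and `direction_sd` (variability of the daily draws).
#' @param cluster list `fraction` (share of hotspots drawn around cluster
#'   centres rather than uniformly over the peat polygons), `sd_km` (spatial
#'   spread of a cluster) and optionally `centers` (named list `deep`,
#'   `shallow` of `c(x, y)` centres; defaults to an interior point of each
#'   class's largest polygon). Controls exposure heterogeneity: adjacent
#'   centres emulate one intensively burned area dominating the exposure
#'   peak.
#' @param dry_season_weight relative weight of July-November when drawing
#'   hotspot dates (fire activity concentrates in the dry season).
#' @param station_noise_sd day-to-day noise (ug/m3) of the synthetic station
#'   series around its seasonal profile.
#' @param children_u5_fraction,adults_30plus_fraction village age-group
#'   fractions (defaults 10% and 44.5% of population).
#' @return A `synthetic_scenario` configuration list.
#' @seealso [scenario_study_preset()] for the default large preset,
#'   [generate_scenario()] to realise the scenario.
#' @export
synthetic_scenario <- function(seed = 1L,
                               years = 2011:2015,
                               hotspot_counts = NULL,
                               region = list(nx = 120L, ny = 120L, res = 1),
                               n_villages = 100L,
                               total_population = 100000,
                               station_location = c(68, 80),
                               station_annual_means = NULL,
                               wind = list(mean_speed = 1.8, mean_direction = 135,
                                           speed_sd = 0.25, direction_sd = 180),
                               cluster = list(fraction = 0.5, sd_km = 6.5,
                                              centers = list(deep = c(78, 48),
                                                             shallow = c(84, 64))),
                               dry_season_weight = 6,
                               station_noise_sd = 8,
                               children_u5_fraction = 0.10,
                               adults_30plus_fraction = 0.445) {
  if (is.null(hotspot_counts)) {
    totals <- rep(200L, length(years))
    hotspot_counts <- split_hotspot_totals(years, totals)
  }
  if (is.null(station_annual_means)) {
    station_annual_means <- stats::setNames(rep(40, length(years)), years)
  }
  cfg <- list(
    seed = as.integer(seed), years = as.integer(years),
    hotspot_counts = hotspot_counts, region = region,
    n_villages = as.integer(n_villages), total_population = total_population,
    station_location = station_location,
    station_annual_means = station_annual_means,
    wind = wind, cluster = cluster,
    dry_season_weight = dry_season_weight,
    station_noise_sd = station_noise_sd,
    children_u5_fraction = children_u5_fraction,
    adults_30plus_fraction = adults_30plus_fraction
  )
  class(cfg) <- "synthetic_scenario"
  problems <- validate_scenario(cfg)
  if (length(problems)) {
    stop("invalid scenario configuration:\n  ", paste(problems, collapse = "\n  "))
  }
  cfg
}

# Split per-year hotspot totals into deep/shallow with deep 8% more frequent,
# the split observed over the study period.
split_hotspot_totals <- function(years, totals, deep_to_shallow = 1.08) {
  deep <- round(totals * deep_to_shallow / (1 + deep_to_shallow))
  data.frame(year = as.integer(years), deep = as.integer(deep),
             shallow = as.integer(totals - deep))
}

#' The study-scale preset scenario
#'
#' Five fire seasons (2011-2015) with per-year peatland hotspot totals
#' 3155, 3604, 1246, 7454 and 21408, about 1569 villages tiling a
#' 120 x 120 km region, 2.5 million inhabitants, and a single monitoring
#' station whose observed annual means average 38 ug/m3 over the period with
#' 65 ug/m3 in the extreme 2015 fire season. Deep-peat hotspots outnumber
#' shallow-peat ones by 8%.
#'
#' @param seed integer RNG seed.
#' @param n_villages,total_population override the defaults (1569 villages,
#'   2.5e6 people) for scaled-down runs.
#' @return A `synthetic_scenario`.
#' @export
scenario_study_preset <- function(seed = 1L, n_villages = 1569L,
                                total_population = 2.5e6) {
  years <- 2011:2015
  totals <- c(3155L, 3604L, 1246L, 7454L, 21408L)
  synthetic_scenario(
    seed = seed, years = years,
    hotspot_counts = split_hotspot_totals(years, totals),
    region = list(nx = 120L, ny = 120L, res = 1),
    n_villages = n_villages, total_population = total_population,
    station_location = c(68, 80),
    station_annual_means = stats::setNames(c(28, 30, 22, 45, 65), years)
  )
}

#' Validate a scenario configuration
#'
#' @param config a `synthetic_scenario`.
#' @return character vector of problems; empty when the configuration is valid.
#' @export
validate_scenario <- function(config) {
  p <- character()
  r <- config$region
  if (is.null(r$nx) || is.null(r$ny) || r$nx < 1 || r$ny < 1 || r$res <= 0)
    p <- c(p, "region: nx, ny must be >= 1 and res > 0")
  if (config$n_villages < 1) p <- c(p, "n_villages: must be >= 1")
  if (!is.null(r$nx) && config$n_villages > r$nx * r$ny)
    p <- c(p, "n_villages: more villages than grid cells")
  if (config$total_population <= 0) p <- c(p, "total_population: must be > 0")
  hc <- config$hotspot_counts
  if (!all(c("year", "deep", "shallow") %in% names(hc))) {
    p <- c(p, "hotspot_counts: needs columns year, deep, shallow")
  } else {
    if (any(hc$deep < 0) || any(hc$shallow < 0))
      p <- c(p, "hotspot_counts: counts must be >= 0")
    if (!setequal(hc$year, config$years))
      p <- c(p, "hotspot_counts: years must match the configured years")
  }
  if (!all(as.character(config$years) %in% names(config$station_annual_means)))
    p <- c(p, "station_annual_means: one value per year required")
  loc <- config$station_location
  if (!is.null(r$nx) &&
      (loc[1] <= 0 || loc[1] >= r$nx * r$res || loc[2] <= 0 || loc[2] >= r$ny * r$res))
    p <- c(p, "station_location: station must lie inside the region")
  if (config$wind$mean_speed < 0) p <- c(p, "wind: mean_speed must be >= 0")
  if (config$cluster$fraction < 0 || config$cluster$fraction > 1)
    p <- c(p, "cluster: fraction must be in [0, 1]")
  if (config$dry_season_weight < 1)
    p <- c(p, "dry_season_weight: must be >= 1")
  p
}

# ---------------------------------------------------------------------------
# Peat map: rectangular depth polygons covering ~18% of the region.
# D1/D2 = shallow (50-200 cm), D3/D4 = deep (> 200 cm). The deep block in the
# south-centre plays the role of an intensively drained area where fires (and
# hence exposure) concentrate.
default_peat_map <- function(region) {
  sx <- region$nx * region$res / 120
  sy <- region$ny * region$res / 120
  pm <- data.frame(
    depth_code = c("D1", "D2", "D3", "D4"),
    xmin = c(12, 72, 15, 55) * sx, xmax = c(42, 107, 45, 100) * sx,
    ymin = c(62, 58, 12, 15) * sy, ymax = c(92, 96, 40, 52) * sy,
    stringsAsFactors = FALSE
  )
  class(pm) <- c("peat_map", "data.frame")
  pm
}

#' Peat class of a depth code
#'
#' Depth codes D1 and D2 denote shallow peat (50-200 cm), D3 and D4 deep peat
#' (> 200 cm).
#'
#' @param depth_code character vector of codes in `D1..D4`.
#' @return character vector, `"shallow"` or `"deep"`.
#' @export
peat_class_of <- function(depth_code) {
  ok <- depth_code %in% c("D1", "D2", "D3", "D4")
  if (!all(ok)) stop("unknown peat depth code: ", paste(depth_code[!ok], collapse = ", "))
  ifelse(depth_code %in% c("D1", "D2"), "shallow", "deep")
}

# ---------------------------------------------------------------------------
# Hotspot generation

month_weights <- function(dry_season_weight) {
  w <- rep(1, 12)
  w[7:11] <- dry_season_weight  # July-November fire season
  w
}

random_dates <- function(n, year, dry_season_weight) {
  if (n == 0) return(as.POSIXct(character(), tz = "UTC"))
  months <- sample.int(12, n, replace = TRUE, prob = month_weights(dry_season_weight))
  dim <- days_in_month(year)
  days <- vapply(months, function(m) sample.int(dim[m], 1L), integer(1))
  hours <- sample.int(24, n, replace = TRUE) - 1L
  as.POSIXct(sprintf("%d-%02d-%02d %02d:00:00", year, months, days, hours), tz = "UTC")
}

days_in_month <- function(year) {
  leap <- (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
  c(31, if (leap) 29 else 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
}

# Sample n points inside the polygons of one peat class: a `fraction` around
# the class cluster centre (rejection-sampled Gaussian), the rest uniform over
# the class polygons weighted by area.
sample_points_in_class <- function(n, peat_map, class, cluster) {
  polys <- peat_map[peat_class_of(peat_map$depth_code) == class, , drop = FALSE]
  if (nrow(polys) == 0 || n == 0)
    return(data.frame(x = numeric(), y = numeric(), depth_code = character()))
  areas <- (polys$xmax - polys$xmin) * (polys$ymax - polys$ymin)
  centre <- cluster$centers[[class]]
  if (is.null(centre) || point_in_which_poly(centre[1], centre[2], polys) == 0) {
    # configured centre absent or off this class's peat (e.g. a rescaled
    # region): fall back to an interior point of the class's largest polygon
    big <- which.max(areas)
    centre <- c(polys$xmin[big] + 0.4 * (polys$xmax[big] - polys$xmin[big]),
                polys$ymin[big] + 0.5 * (polys$ymax[big] - polys$ymin[big]))
  }
  n_cl <- rbinom(1, n, cluster$fraction)
  pts <- matrix(NA_real_, n, 2)
  got <- 0L
  tries <- 0L
  while (got < n_cl) {
    m <- (n_cl - got) * 2L + 8L
    cand <- cbind(rnorm(m, centre[1], cluster$sd_km), rnorm(m, centre[2], cluster$sd_km))
    keep <- point_in_which_poly(cand[, 1], cand[, 2], polys) > 0
    cand <- cand[keep, , drop = FALSE]
    take <- min(nrow(cand), n_cl - got)
    if (take > 0) pts[(got + 1):(got + take), ] <- cand[seq_len(take), , drop = FALSE]
    got <- got + take
    tries <- tries + 1L
    if (tries > 200L && got < n_cl) {
      # pathological acceptance rate: place the remainder uniformly instead
      n_cl <- got
      break
    }
  }
  n_un <- n - n_cl
  if (n_un > 0) {
    pick <- sample.int(nrow(polys), n_un, replace = TRUE, prob = areas)
    pts[(n_cl + 1):n, 1] <- runif(n_un, polys$xmin[pick], polys$xmax[pick])
    pts[(n_cl + 1):n, 2] <- runif(n_un, polys$ymin[pick], polys$ymax[pick])
  }
  idx <- point_in_which_poly(pts[, 1], pts[, 2], polys)
  data.frame(x = pts[, 1], y = pts[, 2], depth_code = polys$depth_code[idx],
             stringsAsFactors = FALSE)
}

# index of the (first) polygon containing each point, 0 if none
point_in_which_poly <- function(x, y, polys) {
  idx <- integer(length(x))
  for (k in seq_len(nrow(polys))) {
    inside <- x >= polys$xmin[k] & x < polys$xmax[k] &
      y >= polys$ymin[k] & y < polys$ymax[k]
    idx[inside & idx == 0L] <- k
  }
  idx
}

# ---------------------------------------------------------------------------
# Villages: tile the grid with rectangles of whole cells.

make_tile_villages <- function(region, n_villages) {
  nx <- region$nx; ny <- region$ny; res <- region$res
  nr <- max(1L, min(ny, as.integer(round(sqrt(n_villages * ny / nx)))))
  while (ceiling(n_villages / nr) > nx) nr <- nr + 1L
  # villages per tile-row and cell-rows per tile-row, spread as evenly as possible
  per_row <- distribute_evenly(n_villages, nr)
  row_heights <- distribute_evenly(ny, nr)
  out <- vector("list", nr)
  iy0 <- 1L
  vid <- 0L
  for (r in seq_len(nr)) {
    widths <- distribute_evenly(nx, per_row[r])
    ix0 <- 1L
    rows <- data.frame(
      village_id = sprintf("V%04d", vid + seq_len(per_row[r])),
      ix0 = integer(per_row[r]), ix1 = integer(per_row[r]),
      iy0 = iy0, iy1 = iy0 + row_heights[r] - 1L,
      stringsAsFactors = FALSE
    )
    for (c in seq_len(per_row[r])) {
      rows$ix0[c] <- ix0; rows$ix1[c] <- ix0 + widths[c] - 1L
      ix0 <- ix0 + widths[c]
    }
    out[[r]] <- rows
    vid <- vid + per_row[r]
    iy0 <- iy0 + row_heights[r]
  }
  v <- do.call(rbind, out)
  v$xmin <- (v$ix0 - 1L) * res; v$xmax <- v$ix1 * res
  v$ymin <- (v$iy0 - 1L) * res; v$ymax <- v$iy1 * res
  v
}

distribute_evenly <- function(total, k) {
  base <- total %/% k
  out <- rep(base, k)
  extra <- total - base * k
  if (extra > 0) out[seq_len(extra)] <- out[seq_len(extra)] + 1L
  as.integer(out)
}

# Round positive weights to integers summing exactly to `total` (largest
# remainder), each at least 1.
round_to_total <- function(weights, total) {
  if (total < length(weights)) stop("total population smaller than number of villages")
  raw <- weights / sum(weights) * (total - length(weights))
  out <- floor(raw)
  rem <- total - length(weights) - sum(out)
  if (rem > 0) {
    idx <- order(raw - out, decreasing = TRUE)[seq_len(rem)]
    out[idx] <- out[idx] + 1
  }
  as.integer(out + 1)
}

# ---------------------------------------------------------------------------

#' Realise a synthetic scenario
#'
#' Draws, deterministically for a fixed seed, everything the analysis chain
#' needs: the peat map, one hotspot record per configured count (with uniform
#' 0-100 detection confidences, dry-season-weighted dates and cluster-plus-
#' background spatial placement inside the matching peat polygons), the
#' village tiling with log-normal populations rescaled to the configured
#' total, daily winds, and the daily monitoring-station PM2.5 series whose
#' annual means equal the configured observed values exactly.
#'
#' @param config a [synthetic_scenario()].
#' @return A `peat_scenario` list with elements `peat_map`, `hotspots`,
#'   `villages`, `met`, `station` and the echoed `config`.
#' @export
generate_scenario <- function(config) {
  stopifnot(inherits(config, "synthetic_scenario"))
  problems <- validate_scenario(config)
  if (length(problems)) stop("invalid scenario configuration: ", paste(problems, collapse = "; "))
  set.seed(config$seed)
  region <- config$region
  peat_map <- default_peat_map(region)

  # hotspots, year by year, exact per-class counts
  hs <- list()
  for (i in seq_len(nrow(config$hotspot_counts))) {
    yr <- config$hotspot_counts$year[i]
    for (cls in c("deep", "shallow")) {
      n <- config$hotspot_counts[[cls]][i]
      if (n == 0) next
      pts <- sample_points_in_class(n, peat_map, cls, config$cluster)
      hs[[length(hs) + 1L]] <- data.frame(
        year = yr, x = pts$x, y = pts$y,
        datetime = random_dates(n, yr, config$dry_season_weight),
        confidence = sample.int(101L, n, replace = TRUE) - 1L,
        depth_code = pts$depth_code, peat_class = cls,
        stringsAsFactors = FALSE
      )
    }
  }
  hotspots <- do.call(rbind, hs)
  if (is.null(hotspots)) {
    # all per-year counts zero: an empty record table with the full schema
    hotspots <- data.frame(year = integer(), x = numeric(), y = numeric(),
                           datetime = as.POSIXct(character(), tz = "UTC"),
                           confidence = integer(), depth_code = character(),
                           peat_class = character(), stringsAsFactors = FALSE)
  } else {
    hotspots <- hotspots[order(hotspots$year, hotspots$datetime), ]
  }
  hotspots <- cbind(id = sprintf("H%06d", seq_len(nrow(hotspots))), hotspots,
                    stringsAsFactors = FALSE)
  rownames(hotspots) <- NULL

  # villages
  villages <- make_tile_villages(region, config$n_villages)
  w <- stats::rlnorm(nrow(villages), meanlog = 0, sdlog = 1.1)
  villages$population <- round_to_total(w, config$total_population)
  villages$children_u5 <- round(config$children_u5_fraction * villages$population)
  villages$adults_30plus <- round(config$adults_30plus_fraction * villages$population)

  # daily met: constant over the region, varying day to day
  met <- do.call(rbind, lapply(config$years, function(yr) {
    dates <- seq(as.Date(sprintf("%d-01-01", yr)), as.Date(sprintf("%d-12-31", yr)), by = "day")
    speed <- pmax(0.05, stats::rnorm(length(dates), config$wind$mean_speed, config$wind$speed_sd))
    theta <- (config$wind$mean_direction +
                stats::rnorm(length(dates), 0, config$wind$direction_sd)) * pi / 180
    data.frame(date = dates, u = speed * cos(theta), v = speed * sin(theta),
               mixing_height = pmax(100, stats::rnorm(length(dates), 800, 150)))
  }))

  # station series: seasonal profile scaled to the exact observed annual mean
  series <- do.call(rbind, lapply(config$years, function(yr) {
    simulate_station_year(config$station_annual_means[[as.character(yr)]], yr,
                          config$dry_season_weight, config$station_noise_sd)
  }))

  structure(list(
    peat_map = peat_map, hotspots = hotspots, villages = villages, met = met,
    station = list(location = config$station_location,
                   annual_means = config$station_annual_means, series = series),
    config = config
  ), class = "peat_scenario")
}

#' @export
print.peat_scenario <- function(x, ...) {
  cat(sprintf("<peat_scenario> seed %d: %d hotspots over %s, %d villages, %s people\n",
              x$config$seed, nrow(x$hotspots),
              paste(range(x$config$years), collapse = "-"),
              nrow(x$villages), format(sum(x$villages$population), big.mark = ",")))
  invisible(x)
}

# One year of daily station PM2.5: dry-season-weighted seasonal profile plus
# noise, rescaled so the annual mean equals `annual_mean` exactly.
simulate_station_year <- function(annual_mean, year, dry_season_weight, noise_sd) {
  dates <- seq(as.Date(sprintf("%d-01-01", year)), as.Date(sprintf("%d-12-31", year)), by = "day")
  mw <- month_weights(dry_season_weight)
  prof <- mw[as.integer(format(dates, "%m"))]
  prof <- prof / mean(prof)
  vals <- pmax(0, annual_mean * prof + stats::rnorm(length(dates), 0, noise_sd))
  if (mean(vals) > 0) vals <- vals * annual_mean / mean(vals)
  data.frame(date = dates, pm25_ugm3 = vals)
}

#' Simulate a daily station series from a concentration field
#'
#' Daily values are the field value at the station cell plus independent
#' Gaussian noise, truncated at zero. With `noise_sd = 0` every value equals
#' the field value exactly.
#'
#' @param true_field a [conc_field] regarded as the true annual-mean surface.
#' @param station_location `c(x, y)` km; must lie inside the grid.
#' @param noise_sd daily noise standard deviation (ug/m3).
#' @param n_days series length (default 365).
#' @return data frame with columns `day` and `pm25_ugm3`.
#' @export
generate_station_series <- function(true_field, station_location, noise_sd,
                                    n_days = 365L) {
  truth <- field_value_at(true_field, station_location[1], station_location[2])
  vals <- pmax(0, truth + stats::rnorm(n_days, 0, noise_sd))
  data.frame(day = seq_len(n_days), pm25_ugm3 = vals)
}

# ---------------------------------------------------------------------------
# Plain-text writers

#' Write scenario inputs to a directory
#'
#' Emits `hotspots.csv`, `villages.geojson`, `peat.geojson`,
#' `station.csv` and `met.csv`; the seed is recorded in a comment header of
#' each CSV.
#'
#' @param scenario a `peat_scenario`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seed_line <- sprintf("# seed=%d", scenario$config$seed)
  hs <- scenario$hotspots
  hs$datetime <- format(hs$datetime, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  write_csv_with_header(hs[, c("id", "x", "y", "datetime", "confidence", "depth_code")],
                        file.path(dir, "hotspots.csv"), seed_line)
  write_csv_with_header(scenario$station$series, file.path(dir, "station.csv"), seed_line)
  write_csv_with_header(scenario$met, file.path(dir, "met.csv"), seed_line)
  write_rect_geojson(scenario$peat_map, file.path(dir, "peat.geojson"),
                     props = "depth_code")
  write_rect_geojson(scenario$villages, file.path(dir, "villages.geojson"),
                     props = c("village_id", "population", "children_u5", "adults_30plus"))
  invisible(dir)
}

write_csv_with_header <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(df, con, row.names = FALSE)
}

#' Read a hotspot CSV written by [write_scenario()]
#'
#' @param path CSV path.
#' @return data frame of hotspot records with parsed datetimes and derived
#'   `peat_class` and `year` columns.
#' @export
read_hotspot_csv <- function(path) {
  first <- readLines(path, n = 1)
  df <- utils::read.csv(path, skip = if (startsWith(first, "#")) 1L else 0L,
                        stringsAsFactors = FALSE)
  needed <- c("id", "x", "y", "datetime", "confidence", "depth_code")
  missing <- setdiff(needed, names(df))
  if (length(missing)) stop("hotspot CSV missing columns: ", paste(missing, collapse = ", "))
  df$datetime <- as.POSIXct(df$datetime, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  df$peat_class <- peat_class_of(df$depth_code)
  df$year <- as.integer(format(df$datetime, "%Y"))
  df
}

# rectangles (xmin/xmax/ymin/ymax) as a GeoJSON FeatureCollection
write_rect_geojson <- function(df, path, props) {
  features <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    ring <- list(c(r$xmin, r$ymin), c(r$xmax, r$ymin), c(r$xmax, r$ymax),
                 c(r$xmin, r$ymax), c(r$xmin, r$ymin))
    list(type = "Feature",
         properties = as.list(r[props]),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
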