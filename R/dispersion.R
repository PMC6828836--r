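#' Dispersion surrogate parameters
#'
#' Parameters of the Gaussian-puff surrogate used in place of a full
#' Lagrangian transport model. Defaults follow the assessment's runtime and
#' deposition assumptions: pollutant transported for 24 h downwind, 24-h
#' concentration averaging, plume vertically averaged over the lowest 100 m
#' AGL, dry deposition velocity 0.001 m/s and first-order wet scavenging
#' 8.0e-5 1/s. The emission rate is in arbitrary mass units per second:
#' the station calibration step makes the final fields invariant to it.
#'
#' @param release_duration hours of continuous release (default 24).
#' @param averaging_period hours over which concentrations are averaged
#'   (default 24).
#' @param plume_layer_top m AGL; concentrations are averaged over this layer
#'   (default 100).
#' @param dry_deposition_velocity m/s (default 0.001).
#' @param wet_scavenging_rate 1/s (default 8.0e-5).
#' @param emission_rate mass/s per hotspot, arbitrary units (default 1).
#' @param horizontal_diffusivity m^2/s controlling horizontal puff growth
#'   sigma^2 = sigma0^2 + 2 K t (default 8000, an effective mesoscale value
#'   that also absorbs sub-daily wind meander).
#' @param initial_sigma_m initial horizontal puff spread, roughly the 1-km
#'   detection footprint (default 400 m).
#' @param timestep_h puff release/evaluation timestep in hours (default 1).
#' @return A `dispersion_params` list.
#' @export
dispersion_params <- function(release_duration = 24,
                              averaging_period = 24,
                              plume_layer_top = 100,
                              dry_deposition_velocity = 0.001,
                              wet_scavenging_rate = 8.0e-5,
                              emission_rate = 1,
                              horizontal_diffusivity = 8000,
                              initial_sigma_m = 400,
                              timestep_h = 1) {
  p <- list(release_duration = release_duration,
            averaging_period = averaging_period,
            plume_layer_top = plume_layer_top,
            dry_deposition_velocity = dry_deposition_velocity,
            wet_scavenging_rate = wet_scavenging_rate,
            emission_rate = emission_rate,
            horizontal_diffusivity = horizontal_diffusivity,
            initial_sigma_m = initial_sigma_m,
            timestep_h = timestep_h)
  if (any(unlist(p) < 0)) stop("dispersion parameters must be non-negative")
  if (p$plume_layer_top <= 0) stop("plume_layer_top must be > 0")
  if (p$timestep_h <= 0) stop("timestep_h must be > 0")
  class(p) <- "dispersion_params"
  p
}

# first-order loss rate (1/s): dry deposition over the plume layer plus wet
# scavenging, applied unconditionally
decay_rate <- function(params) {
  params$dry_deposition_velocity / params$plume_layer_top + params$wet_scavenging_rate
}

#' Filter hotspot records by detection confidence
#'
#' Retains exactly the records whose confidence is greater than or equal to
#' `min_confidence` (the 80-100 band marks high-likelihood real fires), in
#' their original order.
#'
#' @param records data frame with a `confidence` column (percent, 0-100).
#' @param min_confidence retention threshold (default 80); the boundary value
#'   is retained.
#' @return The retained subset of `records`.
#' @export
filter_hotspots <- function(records, min_confidence = 80) {
  if (!"confidence" %in% names(records)) {
    stop("hotspot records have no 'confidence' column")
  }
  records[records$confidence >= min_confidence, , drop = FALSE]
}

#' Classify hotspots by peat depth
#'
#' Looks each point up in the peat map: depth codes D1/D2 give shallow peat,
#' D3/D4 deep peat; points outside every peat polygon get `NA` (off-peat,
#' excluded from the peat-fire analysis). Overlapping peat polygons at a
#' point are an error.
#'
#' @param x,y point coordinates (km), equal length.
#' @param peat_map a peat map (data frame of rectangles with `depth_code`).
#' @return character vector: `"shallow"`, `"deep"` or `NA`.
#' @export
classify_peat <- function(x, y, peat_map) {
  n_hit <- integer(length(x))
  cls <- rep(NA_character_, length(x))
  for (k in seq_len(nrow(peat_map))) {
    inside <- x >= peat_map$xmin[k] & x < peat_map$xmax[k] &
      y >= peat_map$ymin[k] & y < peat_map$ymax[k]
    n_hit <- n_hit + inside
    cls[inside] <- peat_class_of(peat_map$depth_code[k])
  }
  if (any(n_hit > 1L)) {
    stop("ambiguous peat classification: ", sum(n_hit > 1L),
         " point(s) fall in overlapping peat polygons")
  }
  cls
}

#' Drop off-peat hotspot records
#'
#' Convenience wrapper around [classify_peat()]: re-derives `peat_class` from
#' the map and removes records outside all peat polygons, reporting how many
#' were excluded.
#'
#' @param records hotspot data frame with `x`, `y`.
#' @param peat_map the peat map.
#' @return `records` restricted to on-peat points, with a fresh `peat_class`
#'   column.
#' @export
keep_on_peat <- function(records, peat_map) {
  cls <- classify_peat(records$x, records$y, peat_map)
  off <- is.na(cls)
  if (any(off)) message(sum(off), " hotspot(s) outside the peat map excluded")
  records$peat_class <- cls
  records[!off, , drop = FALSE]
}

#' Randomly sample hotspots per peat class
#'
#' Uniform sampling without replacement of `n_per_class` records from each of
#' the shallow and deep classes (optionally within one year), emulating the
#' "analyse a random subset per class and year" workflow. If a class holds
#' fewer records than requested, all of them are taken with a warning.
#'
#' @param records hotspot data frame with `peat_class` (and `year` if `year`
#'   is given).
#' @param n_per_class records to draw per class; must be positive.
#' @param year optional year to restrict to.
#' @param seed optional RNG seed for reproducible draws.
#' @return The sampled records.
#' @export
sample_hotspots <- function(records, n_per_class, year = NULL, seed = NULL) {
  if (n_per_class <= 0) stop("n_per_class must be positive")
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(year)) records <- records[records$year == year, , drop = FALSE]
  picks <- lapply(c("shallow", "deep"), function(cls) {
    idx <- which(records$peat_class == cls)
    if (length(idx) < n_per_class) {
      warning(sprintf("only %d %s-peat hotspot(s) available; requested %d, taking all",
                      length(idx), cls, n_per_class))
      idx
    } else {
      sample(idx, n_per_class)
    }
  })
  records[sort(unlist(picks)), , drop = FALSE]
}

# ---------------------------------------------------------------------------
# Gaussian puff kernel

# Contribution of one puff of age `age_s` seconds to the concentration field:
# a radially symmetric Gaussian (vertically uniform over the plume layer),
# centred `age_s * wind / 1000` km downwind of the source, with horizontal
# variance sigma0^2 + 2 K age and mass decayed by exp(-decay_rate * age).
# `mass` is the mass carried by the puff at release. Returns a matrix on the
# grid's cells (mass units / m^3).
puff_contribution <- function(mass, age_s, x0, y0, wind, params, xs_km, ys_km) {
  k_dec <- decay_rate(params)
  sigma2 <- params$initial_sigma_m^2 + 2 * params$horizontal_diffusivity * age_s
  cx <- x0 + wind[1] * age_s / 1000
  cy <- y0 + wind[2] * age_s / 1000
  coef <- mass * exp(-k_dec * age_s) / (2 * pi * sigma2 * params$plume_layer_top)
  gx <- exp(-((xs_km - cx) * 1000)^2 / (2 * sigma2))
  gy <- exp(-((ys_km - cy) * 1000)^2 / (2 * sigma2))
  coef * (gx %o% gy)
}

# release times (s) of the puff train and the mass each carries
puff_release_times <- function(params) {
  dt <- params$timestep_h * 3600
  n_rel <- max(1L, as.integer(round(params$release_duration / params$timestep_h)))
  list(times = dt * (seq_len(n_rel) - 1L), mass = params$emission_rate * dt,
       dt = dt, n_rel = n_rel)
}

#' Instantaneous puff-train concentration field
#'
#' Concentration snapshot at `t_hours` after the start of a continuous
#' release, summing all puffs released so far. Mainly useful for checking
#' mass conservation and decay; [puff_field()] gives the time-averaged field
#' the pipeline uses.
#'
#' @param x0,y0 source location (km).
#' @param wind `c(u, v)` m/s, constant over the run.
#' @param params [dispersion_params()].
#' @param grid a [conc_field] supplying the grid (values ignored).
#' @param t_hours evaluation time, hours since release start.
#' @return A [conc_field] of instantaneous concentrations.
#' @export
puff_snapshot <- function(x0, y0, wind, params, grid, t_hours) {
  rel <- puff_release_times(params)
  t_s <- t_hours * 3600
  xs <- field_xs(grid); ys <- field_ys(grid)
  vals <- matrix(0, grid$nx, grid$ny)
  for (tr in rel$times[rel$times < t_s]) {
    vals <- vals + puff_contribution(rel$mass, t_s - tr, x0, y0, wind, params, xs, ys)
  }
  conc_field(vals, grid$xmin, grid$ymin, grid$res,
             label = sprintf("snapshot t=%gh", t_hours))
}

#' 24-h mean concentration field of one hotspot
#'
#' Releases a train of Gaussian puffs over `release_duration` hours, advects
#' each with the (daily-constant) wind, grows it horizontally as
#' sigma^2 = sigma0^2 + 2 K t, spreads it uniformly over the plume layer, and
#' decays its mass by exp(-(v_d / H + Lambda) t). The returned field is the
#' arithmetic mean of hourly concentration snapshots over the averaging
#' period. Because the wind is constant within a run, puff contributions
#' depend only on puff age, which the implementation exploits by grouping the
#' (release, evaluation) pairs by age.
#'
#' @inheritParams puff_snapshot
#' @return A [conc_field] of time-averaged concentrations.
#' @export
puff_field <- function(x0, y0, wind, params, grid) {
  stopifnot(inherits(params, "dispersion_params"))
  if (params$plume_layer_top <= 0) stop("plume_layer_top must be > 0")
  ij <- cell_index(grid, x0, y0)  # errors if the source is outside the grid
  rel <- puff_release_times(params)
  n_avg <- max(1L, as.integer(round(params$averaging_period / params$timestep_h)))
  xs <- field_xs(grid); ys <- field_ys(grid)
  vals <- matrix(0, grid$nx, grid$ny)
  # age k*dt occurs for release index i in 0..n_rel-1 and evaluation index
  # j = i + k in 1..n_avg; multiplicity = #feasible i
  for (k in seq_len(n_avg)) {
    mult <- min(rel$n_rel - 1L, n_avg - k) + 1L
    if (mult <= 0L) next
    vals <- vals + mult *
      puff_contribution(rel$mass, k * rel$dt, x0, y0, wind, params, xs, ys)
  }
  conc_field(vals / n_avg, grid$xmin, grid$ymin, grid$res,
             label = sprintf("%g-h mean", params$averaging_period))
}

# ---------------------------------------------------------------------------
# Class-mean plumes and annual scale-up

# kernel grid radius (km): worst-case drift plus 4 sigma, on 1-km cells
kernel_radius_km <- function(winds_ms, params) {
  t_max <- params$averaging_period * 3600
  drift <- max(sqrt(winds_ms$u^2 + winds_ms$v^2)) * t_max / 1000
  sigma <- sqrt(params$initial_sigma_m^2 + 2 * params$horizontal_diffusivity * t_max) / 1000
  ceiling(drift + 4 * sigma + 1)
}

#' Average source-relative plume per peat class
#'
#' Computes each sampled hotspot's 24-h mean plume on a source-centred grid
#' (so plumes from different locations are comparable) using the wind of its
#' detection day, then takes the cell-wise arithmetic mean within each peat
#' class. An "average plume of a peat-fire hotspot" is only meaningful in
#' source-relative coordinates; [scale_up()] re-places it spatially. Plumes
#' are cached per detection day since the daily-constant met makes all
#' same-day plumes identical in relative coordinates.
#'
#' @param sampled hotspot data frame (needs `datetime`, `peat_class`).
#' @param met daily met data frame (`date`, `u`, `v`, `mixing_height`).
#' @param params [dispersion_params()].
#' @param radius_km optional kernel half-width (km); computed from the worst
#'   drift among the sampled days when omitted.
#' @param classes peat classes to average (default both); an empty class is
#'   an error naming the class.
#' @return Named list of [conc_field]s (`shallow`, `deep`) on the common
#'   source-centred grid, each carrying attributes `n_hotspots` and
#'   `recentered = TRUE`.
#' @export
mean_plume_per_class <- function(sampled, met, params, radius_km = NULL,
                                 classes = c("shallow", "deep")) {
  for (cls in classes) {
    if (!any(sampled$peat_class == cls)) {
      stop("no sampled hotspots in class '", cls, "'")
    }
  }
  days <- as.Date(sampled$datetime)
  mrows <- match(days, met$date)
  if (anyNA(mrows)) stop("met data missing for ", sum(is.na(mrows)), " hotspot day(s)")
  if (any(met$mixing_height[mrows] <= 0)) stop("non-positive mixing height in met data")
  winds <- data.frame(u = met$u[mrows], v = met$v[mrows])
  if (is.null(radius_km)) radius_km <- kernel_radius_km(winds, params)
  n <- 2L * as.integer(radius_km) + 1L
  kgrid <- conc_field(matrix(0, n, n), xmin = -radius_km - 0.5, ymin = -radius_km - 0.5)

  cache <- new.env(parent = emptyenv())
  day_plume <- function(i) {
    key <- as.character(days[i])
    if (is.null(cache[[key]])) {
      cache[[key]] <- puff_field(0, 0, c(winds$u[i], winds$v[i]), params, kgrid)$values
    }
    cache[[key]]
  }
  out <- lapply(classes, function(cls) {
    idx <- which(sampled$peat_class == cls)
    acc <- matrix(0, n, n)
    for (i in idx) acc <- acc + day_plume(i)
    f <- conc_field(acc / length(idx), kgrid$xmin, kgrid$ymin, kgrid$res,
                    label = paste("mean plume,", cls, "peat"))
    attr(f, "n_hotspots") <- length(idx)
    attr(f, "recentered") <- TRUE
    f
  })
  names(out) <- classes
  out
}

#' Spatial density of hotspots on a grid
#'
#' Cell counts normalised to sum to one; used to re-place the class-mean
#' plume at the locations where that class's fires actually occurred.
#'
#' @param records hotspot data frame with `x`, `y` (km).
#' @param grid a [conc_field] supplying the grid.
#' @return A [conc_field] whose values sum to 1 (all zero if no records).
#' @export
hotspot_density <- function(records, grid) {
  vals <- matrix(0, grid$nx, grid$ny)
  if (nrow(records) > 0) {
    ix <- pmin(pmax(floor((records$x - grid$xmin) / grid$res) + 1L, 1L), grid$nx)
    iy <- pmin(pmax(floor((records$y - grid$ymin) / grid$res) + 1L, 1L), grid$ny)
    for (i in seq_along(ix)) vals[ix[i], iy[i]] <- vals[ix[i], iy[i]] + 1
    vals <- vals / sum(vals)
  }
  conc_field(vals, grid$xmin, grid$ymin, grid$res, label = "hotspot density")
}

#' Scale class-mean plumes up to an annual field
#'
#' The annual (uncalibrated) surface is the sum over peat classes of
#' `count_class` times the class-mean plume convolved with the class's
#' hotspot spatial density — i.e. the average plume is placed wherever that
#' class's hotspots occurred and multiplied by how many there were. Linear in
#' the counts; zero counts give a zero field.
#'
#' @param mean_fields named list from [mean_plume_per_class()] (source-centred
#'   kernels).
#' @param class_counts named numeric, hotspot counts per class
#'   (e.g. `c(shallow = 1500, deep = 1650)`).
#' @param density_maps named list of [hotspot_density()] fields per class on
#'   the region grid.
#' @param grid region grid ([conc_field]).
#' @return A [conc_field] on the region grid.
#' @export
scale_up <- function(mean_fields, class_counts, density_maps, grid) {
  if (any(class_counts < 0)) stop("class counts must be non-negative")
  vals <- matrix(0, grid$nx, grid$ny)
  for (cls in names(class_counts)) {
    n <- class_counts[[cls]]
    if (n == 0) next
    kern <- mean_fields[[cls]]
    if (is.null(kern)) stop("no mean field for class '", cls, "'")
    if (!isTRUE(attr(kern, "recentered"))) {
      # absolute-coordinate mean plume: already a regional surface per hotspot
      vals <- vals + n * kern$values
    } else {
      vals <- vals + n * fft_convolve2d(density_maps[[cls]]$values, kern$values)
    }
  }
  vals[vals < 0] <- 0
  conc_field(vals, grid$xmin, grid$ymin, grid$res, label = "annual, uncalibrated")
}

#' Calibrate a modeled field to the monitoring station
#'
#' Multiplies every cell by `k = station_annual_mean / modeled value at the
#' station cell`, so the calibrated field reproduces the observed annual mean
#' at the station exactly. This single multiplicative factor (one station is
#' all that exists) also absorbs the arbitrary emission-rate units of the
#' dispersion surrogate.
#'
#' @param field modeled [conc_field].
#' @param station_annual_mean observed annual-mean PM2.5 at the station
#'   (ug/m3).
#' @param station_location `c(x, y)` km.
#' @return The calibrated [conc_field], with the factor in attribute
#'   `calibration_factor`.
#' @export
calibrate <- function(field, station_annual_mean, station_location) {
  modeled <- field_value_at(field, station_location[1], station_location[2])
  if (!is.finite(modeled) || modeled <= 0) {
    stop("modeled concentration at the station cell is ", modeled,
         "; calibration impossible (re-site the station or raise the emission rate)")
  }
  k <- station_annual_mean / modeled
  out <- conc_field(field$values * k, field$xmin, field$ymin, field$res,
                    label = paste(field$label, "(calibrated)"))
  attr(out, "calibration_factor") <- k
  out
}
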