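# Shared fixtures and independent oracles for the test suite.

# small square grid centred so that (0, 0) is the centre of the middle cell
centred_grid <- function(radius_km, res = 1) {
  n <- 2L * as.integer(radius_km) + 1L
  conc_field(matrix(0, n, n), xmin = -radius_km - res / 2,
             ymin = -radius_km - res / 2, res = res)
}

# a quick two-year scenario small enough for repeated pipeline runs
small_scenario <- function(seed = 7, n_villages = 25L) {
  synthetic_scenario(
    seed = seed, years = 2014:2015,
    hotspot_counts = data.frame(year = 2014:2015, deep = c(150L, 300L),
                                shallow = c(140L, 280L)),
    region = list(nx = 40L, ny = 40L, res = 1),
    n_villages = n_villages, total_population = 60000,
    station_location = c(23, 27),
    station_annual_means = c("2014" = 45, "2015" = 65)
  )
}

# Brute-force Gaussian puff oracle: direct double loop over every
# (release time, evaluation time) pair at a single point. Deliberately
# unoptimised and independent of the package's age-grouped implementation.
oracle_puff_mean <- function(x_km, y_km, x0, y0, wind, params) {
  dt <- params$timestep_h * 3600
  n_rel <- round(params$release_duration / params$timestep_h)
  n_avg <- round(params$averaging_period / params$timestep_h)
  k_dec <- params$dry_deposition_velocity / params$plume_layer_top +
    params$wet_scavenging_rate
  total <- 0
  for (j in seq_len(n_avg)) {
    t_eval <- j * dt
    for (i in seq_len(n_rel) - 1L) {
      age <- t_eval - i * dt
      if (age <= 0) next
      sigma2 <- params$initial_sigma_m^2 + 2 * params$horizontal_diffusivity * age
      cx <- x0 + wind[1] * age / 1000
      cy <- y0 + wind[2] * age / 1000
      r2 <- ((x_km - cx) * 1000)^2 + ((y_km - cy) * 1000)^2
      total <- total + params$emission_rate * dt * exp(-k_dec * age) /
        (2 * pi * sigma2 * params$plume_layer_top) * exp(-r2 / (2 * sigma2))
    }
  }
  total / n_avg
}

# Spreadsheet-style recomputation of the regional all-ages impact table,
# written as plain per-village loops independent of run_hia's vectorised path.
oracle_hia_totals <- function(villages, cases, cdr, x_o) {
  out <- numeric(nrow(cases))
  names(out) <- cases$name
  for (ci in seq_len(nrow(cases))) {
    beta <- cases$beta[ci]
    acc <- 0
    for (vi in seq_len(nrow(villages))) {
      x <- villages$mean_pm25[vi]
      rr <- if (cases$form[ci] == "log_linear") {
        ((x + 1) / (x_o + 1))^beta
      } else {
        exp(beta * (x - x_o))
      }
      if (rr < 1) rr <- 1
      acc <- acc + (rr - 1) * cdr * cases$percent_of_deaths[ci] *
        villages$population[vi]
    }
    out[ci] <- acc
  }
  out
}

# Exact zonal-mean oracle by fine-grid sampling: village edges are drawn on a
# 0.05-km lattice, so sampling the (piecewise-constant) field at the centres
# of 0.05-km subcells inside the village reproduces the area-weighted mean
# exactly up to floating point.
oracle_zonal_mean <- function(field, vxmin, vxmax, vymin, vymax, step = 0.05) {
  xs <- seq(vxmin + step / 2, vxmax - step / 2, by = step)
  ys <- seq(vymin + step / 2, vymax - step / 2, by = step)
  total <- 0
  for (y in ys) {
    ix <- floor((xs - field$xmin) / field$res) + 1L
    iy <- floor((y - field$ymin) / field$res) + 1L
    total <- total + sum(field$values[cbind(ix, iy)])
  }
  total / (length(xs) * length(ys))
}

suppress_af_warnings <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("attributable fraction", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}
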