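test_that("confidence filtering keeps exactly the records at or above the threshold", {
  rec <- data.frame(id = 1:5, confidence = c(79, 80, 95, 100, 50))
  kept <- filter_hotspots(rec, 80)
  expect_equal(nrow(kept), 3L)
  expect_equal(kept$id, c(2L, 3L, 4L))  # order preserved, boundary retained
  expect_equal(filter_hotspots(rec, 0), rec)
  expect_equal(nrow(filter_hotspots(rec, 101)), 0L)
  expect_error(filter_hotspots(data.frame(id = 1)), "confidence")
})

test_that("peat classification maps D1/D2 to shallow, D3/D4 to deep, off-peat to NA", {
  pm <- data.frame(depth_code = c("D2", "D4"),
                   xmin = c(0, 10), xmax = c(5, 15), ymin = c(0, 0), ymax = c(5, 5))
  expect_equal(classify_peat(2, 2, pm), "shallow")
  expect_equal(classify_peat(12, 2, pm), "deep")
  expect_true(is.na(classify_peat(7, 2, pm)))
  expect_equal(peat_class_of(c("D1", "D2", "D3", "D4")),
               c("shallow", "shallow", "deep", "deep"))
  expect_error(peat_class_of("D9"), "unknown")
  # off-peat records are excluded with a report of how many
  rec <- data.frame(x = c(2, 7, 12), y = c(2, 2, 2))
  expect_message(out <- keep_on_peat(rec, pm), "1 hotspot")
  expect_equal(nrow(out), 2L)
  # overlapping polygons at a point are ambiguous
  pm2 <- data.frame(depth_code = c("D1", "D3"),
                    xmin = c(0, 3), xmax = c(5, 8), ymin = c(0, 0), ymax = c(5, 5))
  expect_error(classify_peat(4, 1, pm2), "ambiguous")
})

test_that("per-class sampling draws the requested number, warns when short, is seed-stable", {
  rec <- data.frame(id = seq_len(300),
                    peat_class = rep(c("deep", "shallow"), each = 150),
                    year = 2015L)
  s <- sample_hotspots(rec, 100, seed = 4)
  expect_equal(sum(s$peat_class == "deep"), 100L)
  expect_equal(sum(s$peat_class == "shallow"), 100L)
  expect_identical(s$id, sample_hotspots(rec, 100, seed = 4)$id)
  # both classes are short, so one warning per class is emitted
  w <- capture_warnings(all_of <- sample_hotspots(rec, 200, seed = 1))
  expect_match(w, "taking all", all = TRUE)
  expect_length(w, 2L)
  expect_equal(nrow(all_of), 300L)
  expect_error(sample_hotspots(rec, 0), "positive")
})

test_that("zero-wind puff field is radially symmetric about the source", {
  grid <- centred_grid(15)
  f <- puff_field(0, 0, c(0, 0), dispersion_params(horizontal_diffusivity = 2000),
                  grid)
  v <- f$values
  m <- max(v)
  expect_lt(max(abs(v - t(v))) / m, 1e-9)                   # mirror across diagonal
  expect_lt(max(abs(v - v[rev(seq_len(nrow(v))), ])) / m, 1e-9)  # x flip
  expect_lt(max(abs(v - v[, rev(seq_len(ncol(v)))])) / m, 1e-9)  # y flip
  expect_true(which.max(v) == (length(v) + 1) %/% 2)        # peak at the source
})

test_that("puff mass is conserved over time without deposition", {
  params <- dispersion_params(release_duration = 1, averaging_period = 1,
                              dry_deposition_velocity = 0, wet_scavenging_rate = 0,
                              horizontal_diffusivity = 2000, timestep_h = 1)
  # the grid must hold the whole puff: worst case drift 12 h * 1.12 m/s = 48 km
  # plus 4 sigma (52 km)
  grid <- centred_grid(110)
  released <- params$emission_rate * 3600  # single puff's mass
  cell_m2 <- (grid$res * 1000)^2
  for (t in c(2, 6, 12)) {
    f <- puff_snapshot(0, 0, c(1, 0.5), params, grid, t)
    mass <- sum(f$values) * cell_m2 * params$plume_layer_top
    expect_lt(abs(mass - released) / released, 0.005)
  }
})

test_that("deposition decay follows exp(-(v_d/H + Lambda) t), checked against an ODE oracle", {
  skip_if_not_installed("deSolve")
  params <- dispersion_params(release_duration = 1, averaging_period = 1,
                              horizontal_diffusivity = 2000)
  k <- params$dry_deposition_velocity / params$plume_layer_top +
    params$wet_scavenging_rate
  # independent numerical integration of dm/dt = -k m over one hour
  sol <- deSolve::ode(y = c(m = 1), times = c(0, 3600),
                      func = function(t, y, p) list(-p * y), parms = k,
                      method = "ode45", atol = 1e-12, rtol = 1e-12)
  oracle_frac <- as.numeric(sol[2, "m"])
  expect_equal(oracle_frac, 0.7233, tolerance = 1e-4)  # e^{-(1e-5 + 8e-5) 3600}

  # measured mass loss of a simulated puff after 1 h matches the oracle
  grid <- centred_grid(40)
  nodep <- dispersion_params(release_duration = 1, averaging_period = 1,
                             dry_deposition_velocity = 0, wet_scavenging_rate = 0,
                             horizontal_diffusivity = 2000)
  m_dep <- sum(puff_snapshot(0, 0, c(0.5, 0), params, grid, 1)$values)
  m_ref <- sum(puff_snapshot(0, 0, c(0.5, 0), nodep, grid, 1)$values)
  expect_equal(m_dep / m_ref, as.numeric(oracle_frac), tolerance = 1e-6)
})

test_that("averaged puff field matches a brute-force pairwise summation oracle", {
  params <- dispersion_params(horizontal_diffusivity = 3000)
  grid <- centred_grid(80, res = 2)
  wind <- c(0.8, -0.4)
  f <- puff_field(3, -2, wind, params, grid)
  set.seed(20)
  xs <- field_xs(grid); ys <- field_ys(grid)
  for (rep in seq_len(20)) {
    ix <- sample.int(grid$nx, 1); iy <- sample.int(grid$ny, 1)
    want <- oracle_puff_mean(xs[ix], ys[iy], 3, -2, wind, params)
    if (want > 0) {
      expect_lt(abs(f$values[ix, iy] - want) / want, 1e-10)
    } else {
      expect_lt(abs(f$values[ix, iy]), 1e-300)
    }
  }
})

test_that("class-mean plumes average same-day plumes to the identity and error on empty classes", {
  met <- data.frame(date = as.Date("2015-08-01") + 0:2,
                    u = c(1, -0.5, 0.2), v = c(0, 0.8, -0.3),
                    mixing_height = 800)
  params <- dispersion_params(horizontal_diffusivity = 3000)
  one <- data.frame(datetime = as.POSIXct("2015-08-01 10:00", tz = "UTC"),
                    peat_class = "deep")
  mp <- mean_plume_per_class(one, met, params, classes = "deep")
  direct <- puff_field(0, 0, c(1, 0), params,
                       centred_grid((mp$deep$nx - 1) / 2))
  expect_equal(mp$deep$values, direct$values, tolerance = 1e-12)
  expect_equal(attr(mp$deep, "n_hotspots"), 1L)

  # two hotspots on the same day: mean equals either one's plume
  two <- data.frame(datetime = as.POSIXct(c("2015-08-02 01:00", "2015-08-02 20:00"),
                                          tz = "UTC"),
                    peat_class = "shallow")
  mp2 <- mean_plume_per_class(two, met, params, classes = "shallow")
  d2 <- puff_field(0, 0, c(-0.5, 0.8), params,
                   centred_grid((mp2$shallow$nx - 1) / 2))
  expect_equal(mp2$shallow$values, d2$values, tolerance = 1e-12)

  expect_error(mean_plume_per_class(one, met, params), "shallow")
})

test_that("cell-wise averaging of plume fields follows hand arithmetic", {
  a <- conc_field(matrix(c(0, 2), 1, 2))
  b <- conc_field(matrix(c(2, 0), 1, 2))
  expect_equal((a$values + b$values) / 2, matrix(c(1, 1), 1, 2))
})

test_that("scale-up is linear in class counts and honours the deep/shallow ratio", {
  grid <- conc_field(matrix(0, 30, 30))
  kern <- conc_field(matrix(stats::dnorm(seq(-3, 3, length.out = 11)) %o%
                              stats::dnorm(seq(-3, 3, length.out = 11)),
                            11, 11), xmin = -5.5, ymin = -5.5)
  attr(kern, "recentered") <- TRUE
  hs <- data.frame(x = c(10.5, 20.5, 15.5), y = c(10.5, 20.5, 12.5))
  dens <- hotspot_density(hs, grid)
  fields <- list(shallow = kern, deep = kern)
  dmaps <- list(shallow = dens, deep = dens)

  zero <- scale_up(fields, c(shallow = 0, deep = 0), dmaps, grid)
  expect_true(all(zero$values == 0))

  f1 <- scale_up(fields, c(shallow = 100, deep = 108), dmaps, grid)
  f2 <- scale_up(fields, c(shallow = 200, deep = 216), dmaps, grid)
  expect_equal(f2$values, 2 * f1$values, tolerance = 1e-12)

  # with equal kernels and densities, the deep contribution is 8% larger
  d_only <- scale_up(fields, c(shallow = 0, deep = 108), dmaps, grid)
  s_only <- scale_up(fields, c(shallow = 100, deep = 0), dmaps, grid)
  nz <- s_only$values > max(s_only$values) * 1e-9
  expect_equal(d_only$values[nz] / s_only$values[nz],
               rep(1.08, sum(nz)), tolerance = 1e-9)

  expect_error(scale_up(fields, c(shallow = -1, deep = 0), dmaps, grid),
               "non-negative")
})

test_that("density-placed scale-up reproduces direct per-source placement", {
  # FFT convolution against naive shifting of the kernel to each source cell
  grid <- conc_field(matrix(0, 25, 25))
  kv <- matrix(stats::runif(81), 9, 9)
  kern <- conc_field(kv, xmin = -4.5, ymin = -4.5)
  attr(kern, "recentered") <- TRUE
  hs <- data.frame(x = c(8.5, 16.5, 12.5, 8.5), y = c(9.5, 15.5, 6.5, 9.5))
  dens <- hotspot_density(hs, grid)
  got <- scale_up(list(deep = kern), c(deep = 4), list(deep = dens), grid)
  want <- matrix(0, 25 + 8, 25 + 8)  # padded accumulation then crop
  for (i in seq_len(nrow(hs))) {
    ix <- floor(hs$x[i]) + 1; iy <- floor(hs$y[i]) + 1
    want[ix:(ix + 8), iy:(iy + 8)] <- want[ix:(ix + 8), iy:(iy + 8)] + kv
  }
  want <- want[5:29, 5:29]
  expect_equal(got$values, want, tolerance = 1e-9)
})

test_that("station calibration rescales exactly, is idempotent, and rejects a zero station cell", {
  vals <- matrix(1, 10, 10); vals[4, 6] <- 10
  f <- conc_field(vals)
  cal <- calibrate(f, 65, c(3.5, 5.5))
  expect_equal(attr(cal, "calibration_factor"), 6.5)
  expect_equal(field_value_at(cal, 3.5, 5.5), 65)
  # observed equals modeled: identity
  same <- calibrate(f, 10, c(3.5, 5.5))
  expect_equal(same$values, f$values)
  # idempotent under the same observation
  twice <- calibrate(cal, 65, c(3.5, 5.5))
  expect_equal(twice$values, cal$values)
  z <- conc_field(matrix(0, 5, 5))
  expect_error(calibrate(z, 65, c(2.5, 2.5)), "calibration impossible")
})

test_that("calibrated fields are invariant to the arbitrary emission rate", {
  met <- data.frame(date = as.Date("2015-08-01"), u = 0.6, v = 0.3,
                    mixing_height = 800)
  hs <- data.frame(datetime = as.POSIXct("2015-08-01 05:00", tz = "UTC"),
                   peat_class = c("deep", "shallow"),
                   x = c(10.5, 14.5), y = c(12.5, 9.5))
  grid <- conc_field(matrix(0, 30, 30))
  run_with_rate <- function(rate) {
    params <- dispersion_params(emission_rate = rate,
                                horizontal_diffusivity = 3000)
    kern <- mean_plume_per_class(hs, met, params)
    dens <- list(deep = hotspot_density(hs[1, ], grid),
                 shallow = hotspot_density(hs[2, ], grid))
    raw <- scale_up(kern, c(deep = 90, shallow = 110), dens, grid)
    calibrate(raw, 48, c(12.5, 11.5))$values
  }
  expect_equal(run_with_rate(1), run_with_rate(7.3), tolerance = 1e-10)
})

test_that("concentration fields round-trip bit-exactly through CSV", {
  set.seed(31)
  f <- conc_field(matrix(stats::runif(48), 6, 8), xmin = 3, ymin = -2, res = 0.5,
                  label = "annual mean, 2015")
  path <- withr::local_tempfile(fileext = ".csv")
  write_field_csv(f, path)
  g <- read_field_csv(path)
  expect_identical(g$values, f$values)
  expect_identical(c(g$xmin, g$ymin, g$res), c(f$xmin, f$ymin, f$res))
  expect_identical(g$label, f$label)
})
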