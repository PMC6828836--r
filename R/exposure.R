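#' Area-weighted village mean of a concentration field
#'
#' Mean of the field over an axis-aligned rectangular village, weighting each
#' cell by its intersection area with the village (exact for the rectangles
#' used here; for cell-aligned tile villages this reduces to the plain mean
#' of the covered cells).
#'
#' @param field a [conc_field].
#' @param village one-row data frame (or list) with `xmin`, `xmax`, `ymin`,
#'   `ymax` in km, and optionally `village_id` for error messages.
#' @return Numeric scalar, ug/m3.
#' @export
village_annual_mean <- function(field, village) {
  wx <- axis_overlap(village$xmin, village$xmax, field$xmin, field$res, field$nx)
  wy <- axis_overlap(village$ymin, village$ymax, field$ymin, field$res, field$ny)
  if (sum(wx) == 0 || sum(wy) == 0) {
    id <- if (!is.null(village$village_id)) village$village_id else "<unnamed>"
    stop("village ", id, " does not intersect the grid")
  }
  sum((wx %o% wy) * field$values) / (sum(wx) * sum(wy))
}

# overlap length of [a, b] with each cell along one axis (in cell units)
axis_overlap <- function(a, b, origin, res, n) {
  lo <- origin + (seq_len(n) - 1) * res
  hi <- lo + res
  pmax(0, (pmin(b, hi) - pmax(a, lo)) / res)
}

#' Annual village exposures for a set of fields
#'
#' @param fields_by_year named list of calibrated annual [conc_field]s
#'   (names = years).
#' @param villages village data frame (rectangles with `village_id`).
#' @return `villages` with one `pm25_<year>` column per year and a
#'   `mean_pm25` column holding the unweighted mean across years (the
#'   period-mean exposure X of each village).
#' @export
village_exposures <- function(fields_by_year, villages) {
  for (yr in names(fields_by_year)) {
    villages[[paste0("pm25_", yr)]] <- vapply(
      seq_len(nrow(villages)),
      function(i) village_annual_mean(fields_by_year[[yr]], villages[i, ]),
      numeric(1))
  }
  cols <- paste0("pm25_", names(fields_by_year))
  villages$mean_pm25 <- rowMeans(villages[, cols, drop = FALSE])
  villages
}

#' Multi-year period mean
#'
#' Unweighted arithmetic mean of annual values over the requested years;
#' every requested year must be present.
#'
#' @param annual named numeric vector of annual means (names = years).
#' @param years years to average over.
#' @return Numeric scalar.
#' @export
period_mean <- function(annual, years) {
  years <- as.character(years)
  missing <- setdiff(years, names(annual))
  if (length(missing)) stop("missing annual value for year(s): ",
                            paste(missing, collapse = ", "))
  mean(annual[years])
}

#' Summarise village exposures
#'
#' Regional summary of village period-mean PM2.5: mean, range, the lowest
#' observed village mean (the reference concentration X_o of the risk
#' functions), and exceedance counts. Threshold semantics follow the
#' guideline phrasing: strictly below 10, at or above 20, strictly above 80
#' ug/m3.
#'
#' @param villages village data frame with `mean_pm25` (and `population`).
#' @param thresholds numeric `c(below, ge, gt)` (default `c(10, 20, 80)`).
#' @return An `exposure_summary` list.
#' @export
summarize_exposure <- function(villages, thresholds = c(10, 20, 80)) {
  if (nrow(villages) == 0) stop("no villages to summarise")
  if (anyNA(villages$mean_pm25)) stop("mean_pm25 missing for some villages")
  x <- villages$mean_pm25
  ge <- x >= thresholds[2]
  out <- list(
    n_villages = nrow(villages),
    mean = mean(x), min = min(x), max = max(x),
    x_o = min(x),
    thresholds = thresholds,
    villages_below_low = sum(x < thresholds[1]),
    villages_ge_mid = sum(ge),
    villages_gt_high = sum(x > thresholds[3]),
    population = sum(villages$population),
    population_ge_mid = sum(villages$population[ge])
  )
  class(out) <- "exposure_summary"
  out
}

#' @export
print.exposure_summary <- function(x, ...) {
  cat(sprintf("<exposure_summary> %d villages, %s people\n", x$n_villages,
              format(x$population, big.mark = ",")))
  cat(sprintf("  period-mean PM2.5: mean %.1f, range %.1f-%.1f ug/m3 (X_o = %.1f)\n",
              x$mean, x$min, x$max, x$x_o))
  cat(sprintf("  villages < %g: %d | >= %g: %d (pop %s) | > %g: %d\n",
              x$thresholds[1], x$villages_below_low,
              x$thresholds[2], x$villages_ge_mid,
              format(x$population_ge_mid, big.mark = ","),
              x$thresholds[3], x$villages_gt_high))
  invisible(x)
}

#' Write village exposures as CSV
#'
#' @param villages output of [village_exposures()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_exposure_csv <- function(villages, path) {
  keep <- c("village_id", "population",
            grep("^pm25_", names(villages), value = TRUE), "mean_pm25")
  utils::write.csv(villages[, keep], path, row.names = FALSE)
  invisible(path)
}
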