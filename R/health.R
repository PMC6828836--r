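#' Default health-case specifications
#'
#' The four mortality categories of the assessment with their
#' concentration-response forms, excess-risk coefficients (beta, per ug/m3
#' PM2.5), shares of all-cause deaths, and age groups:
#'
#' * all-cause premature mortality — linear-exponential, beta = 0.0008 x 48/21
#'   (0.001829), 100% of deaths, all ages;
#' * chronic respiratory — linear-exponential, beta = 0.00166 x 48/21
#'   (0.003794), 4% of deaths, reported for children under 5 (10% of the
#'   population);
#' * cardiovascular — log-linear, beta = 0.15515, 33% of deaths, adults 30+
#'   (44.5%);
#' * lung cancer — log-linear, beta = 0.23218, 2% of deaths, adults 30+
#'   (44.5%).
#'
#' The two linear coefficients are PM10 values renormalised with the 48/21
#' PM10/PM2.5 ratio (see [renormalize_beta()]); full precision is kept
#' internally, 6 decimals are used for display.
#'
#' @param cardiovascular_beta override for the cardiovascular coefficient
#'   (0.1551 is an accepted alternative reading).
#' @return Data frame with one row per category: `name`, `form`, `beta`,
#'   `percent_of_deaths`, `age_group`, `age_fraction`.
#' @export
health_cases <- function(cardiovascular_beta = 0.15515) {
  data.frame(
    name = c("all_cause", "chronic_respiratory", "cardiovascular", "lung_cancer"),
    form = c("linear", "linear", "log_linear", "log_linear"),
    beta = c(renormalize_beta(0.0008), renormalize_beta(0.00166),
             cardiovascular_beta, 0.23218),
    percent_of_deaths = c(1, 0.04, 0.33, 0.02),
    age_group = c("all", "under5", "adults30plus", "adults30plus"),
    age_fraction = c(1, 0.10, 0.445, 0.445),
    stringsAsFactors = FALSE
  )
}

#' Renormalise a PM10 risk coefficient to PM2.5
#'
#' Multiplies a per-ug/m3 PM10 excess-risk coefficient by the PM10/PM2.5
#' concentration ratio (48/21 for Indonesia) to obtain the PM2.5 coefficient.
#' Full precision is retained; use `display = TRUE` for the conventional
#' 6-decimal display value.
#'
#' @param beta_pm10 coefficient per ug/m3 PM10; must be positive.
#' @param ratio PM10/PM2.5 ratio (default the exact rational 48/21).
#' @param display round to 6 decimals for reporting?
#' @return Numeric scalar.
#' @export
renormalize_beta <- function(beta_pm10, ratio = 48 / 21, display = FALSE) {
  if (beta_pm10 <= 0 || ratio <= 0) stop("beta and ratio must be positive")
  out <- beta_pm10 * ratio
  if (display) round(out, 6) else out
}

#' Relative risk of mortality at exposure X
#'
#' Concentration-response functions relative to the reference concentration
#' `x_o` (the lowest observed village period mean):
#' log-linear `RR = ((X + 1) / (X_o + 1))^beta`, defined for `X >= X_o`;
#' linear-exponential `RR = exp(beta * (X - X_o))`. For `X < X_o` the RR is
#' clamped to exactly 1 (no negative attributable burden). Both forms give
#' `RR(X_o) = 1`.
#'
#' @param x exposure(s), ug/m3, non-negative; vectorised.
#' @param x_o reference concentration, ug/m3.
#' @param beta excess risk per ug/m3.
#' @param form `"log_linear"` or `"linear"`.
#' @return Numeric vector of relative risks (>= 1).
#' @export
relative_risk <- function(x, x_o, beta, form = c("log_linear", "linear")) {
  form <- match.arg(form)
  if (any(x < 0) || x_o < 0) stop("concentrations must be non-negative")
  rr <- switch(form,
    log_linear = ((x + 1) / (x_o + 1))^beta,
    linear = exp(beta * (x - x_o))
  )
  pmax(rr, 1)
}

#' Attributable fraction at exposure X
#'
#' `AF = RR(X) - RR(X_o) = RR(X) - 1`; non-negative, and not capped at 1
#' (a warning is emitted if it exceeds 1, which can happen for large X with
#' a large beta).
#'
#' @inheritParams relative_risk
#' @return Numeric vector of attributable fractions.
#' @export
attributable_fraction <- function(x, x_o, beta, form = c("log_linear", "linear")) {
  af <- relative_risk(x, x_o, beta, form) - 1
  if (any(af > 1)) warning("attributable fraction exceeds 1 for some exposures")
  af
}

#' Attributable deaths per year
#'
#' `AF x CDR x percent_of_deaths x (population x age_fraction)`. Returned
#' unrounded; rounding to whole deaths happens only at the reporting stage.
#'
#' @param af attributable fraction(s).
#' @param cdr crude death rate, deaths per person-year.
#' @param population people.
#' @param percent_of_deaths share of all-cause deaths in the category, in
#'   `[0, 1]`.
#' @param age_fraction share of the population in the category's age group,
#'   in `[0, 1]`.
#' @return Numeric, deaths per year.
#' @export
attributable_deaths <- function(af, cdr, population, percent_of_deaths = 1,
                                age_fraction = 1) {
  if (percent_of_deaths < 0 || percent_of_deaths > 1)
    stop("percent_of_deaths must be in [0, 1]")
  if (age_fraction < 0 || age_fraction > 1)
    stop("age_fraction must be in [0, 1]")
  if (any(af < 0) || cdr < 0 || any(population < 0))
    stop("af, cdr and population must be non-negative")
  af * cdr * percent_of_deaths * population * age_fraction
}

#' Mortality rate per 100,000 population
#'
#' @param deaths deaths per year.
#' @param population people (> 0).
#' @return Integer-rounded cases per 100,000 per year.
#' @export
rate_per_100k <- function(deaths, population) {
  if (any(population <= 0)) stop("population must be positive")
  round_half_up(deaths / population * 1e5)
}

# commercial rounding: .5 always rounds up (R's round() halves to even)
round_half_up <- function(x) floor(x + 0.5)

#' Run the village-level health impact assessment
#'
#' For every village and health category, evaluates the attributable fraction
#' at the village's period-mean exposure against the regional reference
#' concentration, converts it to attributable deaths via the crude death
#' rate, the category's share of deaths and its age-group population, and
#' aggregates to a regional report with, per category, an all-ages row and —
#' where the category targets an age group — an age-group row (the age-group
#' row is the all-ages burden scaled by the age fraction). Aggregation uses
#' unrounded village values; rounding to whole deaths happens only in the
#' printed/exported table.
#'
#' @param villages data frame with `village_id`, `population`, `mean_pm25`.
#' @param cases health-case data frame, see [health_cases()].
#' @param cdr crude death rate (default 0.0058 deaths per person-year).
#' @param x_o reference concentration; defaults to the minimum village
#'   period-mean exposure across the region.
#' @return An `impact_result` list: `region` (the report table), `villages`
#'   (per-village AF and attributable deaths per category), `x_o`, `cdr`,
#'   `cases`.
#' @export
run_hia <- function(villages, cases = health_cases(), cdr = 0.0058, x_o = NULL) {
  if (!"mean_pm25" %in% names(villages) || anyNA(villages$mean_pm25)) {
    bad <- if ("mean_pm25" %in% names(villages))
      villages$village_id[is.na(villages$mean_pm25)] else villages$village_id
    stop("villages missing exposure: ", paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ..." else "")
  }
  if (cdr < 0) stop("cdr must be non-negative")
  if (is.null(x_o)) x_o <- min(villages$mean_pm25)

  vill <- villages[, c("village_id", "population", "mean_pm25")]
  region <- list()
  total_pop <- sum(villages$population)
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    af <- attributable_fraction(villages$mean_pm25, x_o, cs$beta, cs$form)
    d_all <- attributable_deaths(af, cdr, villages$population, cs$percent_of_deaths, 1)
    vill[[paste0("af_", cs$name)]] <- af
    vill[[paste0("deaths_", cs$name)]] <- d_all
    base_all <- cdr * total_pop * cs$percent_of_deaths
    region[[length(region) + 1L]] <- data.frame(
      category = cs$name, age_group = "all", population = total_pop,
      baseline_deaths = base_all, attributable_deaths = sum(d_all),
      per_100k = rate_per_100k(sum(d_all), total_pop),
      stringsAsFactors = FALSE
    )
    if (cs$age_group != "all") {
      pop_age <- total_pop * cs$age_fraction
      region[[length(region) + 1L]] <- data.frame(
        category = cs$name, age_group = cs$age_group, population = pop_age,
        baseline_deaths = base_all * cs$age_fraction,
        attributable_deaths = sum(d_all) * cs$age_fraction,
        per_100k = rate_per_100k(sum(d_all) * cs$age_fraction, pop_age),
        stringsAsFactors = FALSE
      )
    }
  }
  structure(list(region = do.call(rbind, region), villages = vill,
                 x_o = x_o, cdr = cdr, cases = cases),
            class = "impact_result")
}

#' @export
print.impact_result <- function(x, ...) {
  cat(sprintf("<impact_result> X_o = %.2f ug/m3, CDR = %g, %d villages\n",
              x$x_o, x$cdr, nrow(x$villages)))
  print(format_impact_table(x), row.names = FALSE)
  invisible(x)
}

#' Report table with whole-number death counts
#'
#' @param result an `impact_result`.
#' @return The regional table with `baseline_deaths` and
#'   `attributable_deaths` rounded half-up to integers.
#' @export
format_impact_table <- function(result) {
  tab <- result$region
  tab$baseline_deaths <- round_half_up(tab$baseline_deaths)
  tab$attributable_deaths <- round_half_up(tab$attributable_deaths)
  tab
}

#' Sensitivity analysis of the attributable-mortality estimates
#'
#' Re-runs the assessment under standard perturbations — swapping each
#' category's response form between log-linear and linear-exponential,
#' shifting every village exposure by +/-10 ug/m3 (floored at 0), and fixing
#' the reference concentration at the 10 ug/m3 guideline value — and reports
#' the percent change in each category's all-ages attributable deaths.
#' Percent changes are computed on unrounded totals.
#'
#' @inheritParams run_hia
#' @param deltas exposure shifts in ug/m3 (default `c(10, -10)`).
#' @param x_o_alt alternative reference concentration (default 10).
#' @param swap_forms include the swapped-form variant?
#' @return Data frame: `variant`, `category`, `attributable_deaths`,
#'   `pct_change`.
#' @export
sensitivity_analysis <- function(villages, cases = health_cases(), cdr = 0.0058,
                                 x_o = NULL, deltas = c(10, -10), x_o_alt = 10,
                                 swap_forms = TRUE) {
  if (is.null(x_o)) x_o <- min(villages$mean_pm25)
  base <- run_hia(villages, cases, cdr, x_o)
  base_tot <- subset(base$region, age_group == "all")

  variants <- list()
  if (swap_forms) {
    swapped <- cases
    swapped$form <- ifelse(cases$form == "linear", "log_linear", "linear")
    variants[["swapped_form"]] <- list(v = villages, c = swapped, xo = x_o)
  }
  for (d in deltas) {
    vd <- villages
    vd$mean_pm25 <- pmax(0, vd$mean_pm25 + d)
    variants[[sprintf("X%+g", d)]] <- list(v = vd, c = cases, xo = x_o)
  }
  variants[[sprintf("X_o=%g", x_o_alt)]] <- list(v = villages, c = cases, xo = x_o_alt)

  out <- lapply(names(variants), function(nm) {
    vr <- variants[[nm]]
    tot <- subset(run_hia(vr$v, vr$c, cdr, vr$xo)$region, age_group == "all")
    data.frame(variant = nm, category = tot$category,
               attributable_deaths = tot$attributable_deaths,
               pct_change = ifelse(base_tot$attributable_deaths > 0,
                                   100 * (tot$attributable_deaths /
                                            base_tot$attributable_deaths - 1),
                                   NA_real_),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
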