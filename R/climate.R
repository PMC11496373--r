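#' Registry of annual climate variables
#'
#' The 22 annual climate variables the package recognises, in their
#' canonical order. Variables lacking a direct biological interpretation
#' (degree-days relative to 18 degrees C) are not part of the registry.
#' The `typical` column holds representative boreal-forest magnitudes used
#' as base values by the synthetic landscape generator.
#'
#' @return A data.frame with columns `variable`, `description`, `unit`,
#'   `typical`.
#' @export
climate_variables <- function() {
  data.frame(
    variable = c("AHM", "CMD", "DD_0", "DD5", "Eref", "EMT", "EXT", "FFP",
                 "NFFD", "bFFP", "eFFP", "MAP", "MAT", "MCMT", "MWMT", "MAR",
                 "MSP", "CMI", "PAS", "RH", "SHM", "TD"),
    description = c(
      "Annual heat-moisture index",
      "Hargreaves climatic moisture deficit",
      "Degree-days below 0 C",
      "Degree-days above 5 C",
      "Hargreaves reference evaporation",
      "Extreme minimum temperature over 30 years",
      "Extreme maximum temperature over 30 years",
      "Frost-free period",
      "Number of frost-free days",
      "Day of year on which the frost-free period begins",
      "Day of year on which the frost-free period ends",
      "Mean annual precipitation",
      "Mean annual temperature",
      "Mean coldest month temperature",
      "Mean warmest month temperature",
      "Mean annual solar radiation",
      "Mean summer precipitation",
      "Hogg's climate moisture index",
      "Precipitation as snow",
      "Mean annual relative humidity",
      "Summer heat-moisture index",
      "Temperature difference (continentality; MWMT - MCMT)"),
    unit = c("C/mm", "mm", "C days", "C days", "mm", "C", "C", "days",
             "days", "day", "day", "mm", "C", "C", "C", "MJ/m2/day",
             "mm", "mm", "mm", "%", "C/mm", "C"),
    typical = c(27, 250, 800, 1300, 500, -45, 33, 100,
                160, 150, 250, 450, 2, -14, 16, 12,
                280, 5, 120, 65, 55, 30),
    stringsAsFactors = FALSE)
}

climate_variable_names <- function() climate_variables()$variable

assert_known_variables <- function(vars, where = "climate table") {
  unknown <- setdiff(vars, climate_variable_names())
  if (length(unknown)) {
    stop_domain("%s contains unknown climate variable(s): %s",
                where, paste(unknown, collapse = ", "))
  }
  invisible(vars)
}

#' Annual climate series for one location
#'
#' A container for per-year values of named climate variables at one
#' location, plus the location's climate normals (30-year means) for a named
#' normal period. Years must be contiguous.
#'
#' @param location_id identifier of the location.
#' @param years integer vector of contiguous calendar years.
#' @param values numeric matrix, `length(years)` rows by one column per
#'   climate variable (column names must be registry variables).
#' @param normals named numeric vector of climate normals.
#' @param normal_period label of the normal period (e.g. `"1961-1990"`).
#' @return An object of class `climate_series`.
#' @export
climate_series <- function(location_id, years, values, normals,
                           normal_period = "1961-1990") {
  years <- as.integer(years)
  if (length(years) && !identical(years, seq(years[1], by = 1L,
                                             length.out = length(years)))) {
    stop_domain("climate_series: years must be contiguous and increasing")
  }
  values <- as.matrix(values)
  if (nrow(values) != length(years)) {
    stop_domain("climate_series: values must have one row per year")
  }
  assert_known_variables(colnames(values), "climate_series values")
  assert_known_variables(names(normals), "climate_series normals")
  structure(
    list(location_id = location_id, years = years, values = values,
         normals = normals, normal_period = normal_period),
    class = "climate_series")
}

#' @export
print.climate_series <- function(x, ...) {
  cat(sprintf("<climate_series: %s> %d years (%d-%d), %d variables, normals %s\n",
              x$location_id, length(x$years),
              if (length(x$years)) min(x$years) else NA,
              if (length(x$years)) max(x$years) else NA,
              ncol(x$values), x$normal_period))
  invisible(x)
}

#' Constant climate series replaying a set of normals
#'
#' Builds a [climate_series()] in which every year repeats the normal value
#' of each variable — the "no climate change" scenario, under which the
#' assembled climate-sensitive curve collapses to the static top-height
#' curve.
#'
#' @param normals named numeric vector of climate normals.
#' @param years integer vector of contiguous calendar years to cover.
#' @param location_id identifier for the series.
#' @inheritParams climate_series
#' @return A `climate_series`.
#' @export
constant_series <- function(normals, years, location_id = "constant",
                            normal_period = "1961-1990") {
  values <- matrix(rep(normals, each = length(years)),
                   nrow = length(years),
                   dimnames = list(NULL, names(normals)))
  climate_series(location_id, years, values, normals, normal_period)
}

#' Prune highly correlated climate variables
#'
#' Identifies pairs of variables whose absolute Pearson correlation across
#' locations exceeds the threshold and removes one member of each pair,
#' leaving a set with no remaining above-threshold pair. Removal is
#' iterative and deterministic: at each step the variable involved in the
#' largest number of above-threshold pairs is dropped, ties broken toward
#' the variable appearing later in the registry order. The retained names
#' are returned in registry order.
#'
#' @param table numeric matrix or data.frame, locations in rows and climate
#'   variables in columns (registry names).
#' @param threshold correlation magnitude above which a pair is "highly
#'   correlated" (default 0.9, strict inequality).
#' @return Character vector of retained variable names, in registry order.
#' @export
prune_correlated <- function(table, threshold = 0.9) {
  m <- as.matrix(table)
  if (nrow(m) < 3L) stop_domain("prune_correlated: need at least 3 locations")
  assert_known_variables(colnames(m), "prune_correlated table")
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    stop_domain("prune_correlated: constant column(s): %s",
                paste(colnames(m)[sds == 0], collapse = ", "))
  }
  registry <- climate_variable_names()
  keep <- colnames(m)[order(match(colnames(m), registry))]
  repeat {
    r <- abs(cor(m[, keep, drop = FALSE]))
    diag(r) <- 0
    over <- r > threshold
    if (!any(over)) break
    degree <- rowSums(over)
    worst <- which(degree == max(degree))
    # ties -> later in registry order
    drop_var <- keep[worst[which.max(match(keep[worst], registry))]]
    keep <- setdiff(keep, drop_var)
  }
  keep
}

#' Lifespan-average climate
#'
#' The arithmetic mean of a variable's annual values over a tree's life so
#' far: calendar years `plant_year` through `plant_year + age - 1` (one
#' value per year of life).
#'
#' @param series a [climate_series()].
#' @param variable registry variable name.
#' @param plant_year planting (germination) calendar year.
#' @param age age in years over which to average (>= 1).
#' @return The mean value.
#' @export
lifespan_average <- function(series, variable, plant_year, age) {
  stopifnot(inherits(series, "climate_series"))
  if (!variable %in% colnames(series$values)) {
    stop_domain("lifespan_average: variable '%s' not in series for %s",
                variable, series$location_id)
  }
  wanted <- seq(plant_year, length.out = age)
  idx <- match(wanted, series$years)
  if (anyNA(idx)) {
    stop_domain("lifespan_average: series for %s is missing year(s): %s",
                series$location_id,
                paste(wanted[is.na(idx)], collapse = ", "))
  }
  mean(series$values[idx, variable])
}

#' Smooth a sequence of lifespan averages with a log-age regression
#'
#' Fits `value = c0 + c1 * ln(age)` by ordinary least squares over ages
#' 1..A and returns the fitted values. Used to remove inter-annual
#' fluctuation from lifespan-averaged climates so the assembled top-height
#' curves reflect the long-term climate trend.
#'
#' @param values_by_age numeric vector of values at ages `1..length(values_by_age)`
#'   (length >= 3).
#' @return Numeric vector of fitted values, same length, named by age.
#' @export
smooth_log_regression <- function(values_by_age) {
  a <- length(values_by_age)
  if (a < 3L) stop_domain("smooth_log_regression: need at least 3 ages (got %d)", a)
  age <- seq_len(a)
  fit <- lm(values_by_age ~ log(age))
  setNames(as.numeric(fitted(fit)), age)
}
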