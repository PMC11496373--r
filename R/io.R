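#' Read a provenance-trial tree table
#'
#' Expects a UTF-8 CSV with header columns `site_id`, `population_id`,
#' `block_id`, `tree_id`, `totage`, `height_m`, `health_flag`.
#'
#' @param path CSV path.
#' @return data.frame with a `height` column (m).
#' @export
read_trial_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("site_id", "population_id", "block_id", "tree_id",
            "totage", "height_m", "health_flag")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop_domain("read_trial_csv: %s is missing column(s): %s", path,
                paste(miss, collapse = ", "))
  }
  names(d)[names(d) == "height_m"] <- "height"
  bad <- d$health_flag == "healthy" & (!is.finite(d$height) | d$height <= 0)
  if (any(bad)) {
    stop_domain("read_trial_csv: %d healthy tree(s) with non-positive height", sum(bad))
  }
  d
}

#' Read climate normals from a long-format CSV
#'
#' Columns: `location_id`, `variable`, `period` (normal-period label, e.g.
#' `"1961-1990"`), `value`. Variable names must match the registry.
#'
#' @param path CSV path.
#' @param period which normal period to extract.
#' @return Matrix, locations x variables.
#' @export
read_climate_normals_csv <- function(path, period = "1961-1990") {
  d <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  miss <- setdiff(c("location_id", "variable", "period", "value"), names(d))
  if (length(miss)) {
    stop_domain("read_climate_normals_csv: missing column(s): %s",
                paste(miss, collapse = ", "))
  }
  d <- d[d$period == period, , drop = FALSE]
  if (!nrow(d)) stop_domain("read_climate_normals_csv: no rows for period '%s'", period)
  assert_known_variables(unique(d$variable), path)
  locs <- unique(d$location_id)
  vars <- intersect(climate_variable_names(), unique(d$variable))
  m <- matrix(NA_real_, length(locs), length(vars), dimnames = list(locs, vars))
  m[cbind(match(d$location_id, locs), match(d$variable, vars))] <- d$value
  if (anyNA(m)) stop_domain("read_climate_normals_csv: incomplete location x variable table")
  m
}

#' Read annual climate series from a long-format CSV
#'
#' Columns: `location_id`, `variable`, `year`, `value`. Rows whose `year`
#' parses as an integer form the annual series; a separate normals table
#' (see [read_climate_normals_csv()]) supplies the normals.
#'
#' @param path CSV path.
#' @param normals matrix of normals (locations x variables) to attach.
#' @return Named list of [climate_series()] per location.
#' @export
read_climate_series_csv <- function(path, normals) {
  d <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  miss <- setdiff(c("location_id", "variable", "year", "value"), names(d))
  if (length(miss)) {
    stop_domain("read_climate_series_csv: missing column(s): %s",
                paste(miss, collapse = ", "))
  }
  assert_known_variables(unique(d$variable), path)
  out <- lapply(unique(d$location_id), function(id) {
    di <- d[d$location_id == id, , drop = FALSE]
    years <- sort(unique(as.integer(di$year)))
    vars <- intersect(climate_variable_names(), unique(di$variable))
    m <- matrix(NA_real_, length(years), length(vars),
                dimnames = list(NULL, vars))
    m[cbind(match(as.integer(di$year), years), match(di$variable, vars))] <- di$value
    if (anyNA(m)) {
      stop_domain("read_climate_series_csv: incomplete series for location '%s'", id)
    }
    nr <- if (id %in% rownames(normals)) normals[id, vars] else
      stop_domain("read_climate_series_csv: no normals for location '%s'", id)
    climate_series(id, years, m, nr)
  })
  names(out) <- unique(d$location_id)
  out
}

#' Serialise a fitted URF to JSON
#'
#' Writes the specification, coefficients, fit and cross-validation
#' statistics, package version, and (if supplied) the selection seed.
#'
#' @param fit a `urf_fit`.
#' @param path output path.
#' @param seed optional selection seed to record.
#' @export
write_urf_json <- function(fit, path, seed = NULL) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop_domain("write_urf_json requires the 'jsonlite' package")
  }
  obj <- list(
    spec = list(prov_vars = fit$spec$prov_vars,
                site_vars = fit$spec$site_vars,
                include_intercept = fit$spec$include_intercept),
    coefficients = as.list(fit$coefficients),
    statistics = list(r2 = fit$r2, aic = fit$aic, n = fit$n,
                      ef_cv = fit$ef_cv, rmsep_cv = fit$rmsep_cv,
                      refined = fit$refined),
    software = list(package = "climurf",
                    version = as.character(utils::packageVersion("climurf"))),
    seed = seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a URF back from JSON
#'
#' @param path JSON path written by [write_urf_json()].
#' @return A `urf_fit` (statistics restored; usable for prediction).
#' @export
read_urf_json <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop_domain("read_urf_json requires the 'jsonlite' package")
  }
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- urf_spec(obj$spec$prov_vars, obj$spec$site_vars,
                   obj$spec$include_intercept)
  fit <- urf_model(spec, unlist(obj$coefficients))
  for (f in c("r2", "aic", "ef_cv", "rmsep_cv")) {
    if (!is.null(obj$statistics[[f]])) fit[[f]] <- obj$statistics[[f]]
  }
  if (!is.null(obj$statistics$n)) fit$n <- obj$statistics$n
  fit
}

#' Export site-index map records as GeoJSON
#'
#' Writes a GeoJSON FeatureCollection of points whose properties mirror the
#' record columns, for use in external mapping tools.
#'
#' @param records a record table from [map_local_si()] (optionally after
#'   [map_optimal_si()] / [apply_extrapolation_exclusion()]).
#' @param points data.frame with `point_id`, `lon`, `lat` (e.g.
#'   `landscape$points`).
#' @param path output path.
#' @export
write_si_geojson <- function(records, points, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop_domain("write_si_geojson requires the 'jsonlite' package")
  }
  idx <- match(records$point_id, points$point_id)
  if (anyNA(idx)) stop_domain("write_si_geojson: records reference unknown points")
  features <- lapply(seq_len(nrow(records)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(points$lon[idx[i]], points$lat[idx[i]])),
         properties = as.list(records[i, , drop = FALSE]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
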