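#' Build a population-specific climate-sensitive top-height curve
#'
#' Merges a fitted URF into the species top-height equation by the
#' four-step increment-assembly algorithm:
#' \enumerate{
#'   \item For each age \eqn{i} in 1..A, average the site climate over the
#'     tree's life so far (planting year through age \eqn{i}; optionally
#'     smoothed by a log-age regression) and predict the common-age top
#'     height from the URF under (provenance normals, lifespan-average site
#'     climate).
#'   \item Invert the species top-height equation at the common age to
#'     obtain the site index \eqn{SI_i} implied by that prediction.
#'   \item \eqn{SI_i} indexes a static (climate-non-sensitive) top-height
#'     curve for that age's climate.
#'   \item Assemble the climate-sensitive curve: the height at age 1 is
#'     taken from the \eqn{SI_1} curve; for \eqn{i \ge 2} the annual
#'     increment of the \eqn{SI_i} curve between ages \eqn{i-1} and \eqn{i}
#'     is added to the running height.
#' }
#' Under a constant climate all \eqn{SI_i} coincide and the assembly
#' telescopes exactly back to the static curve — the defining correctness
#' property of the method. If a falling \eqn{SI_i} path ever produces a
#' negative increment, the increment is floored at zero (cumulative height
#' cannot shrink) with a warning.
#'
#' @param params a [species_params()] object.
#' @param urf a `urf_fit` (fitted or ground-truth via [urf_model()]).
#' @param prov_normals named numeric vector: the provenance's 1961–1990
#'   climate normals, covering every provenance variable of the URF.
#' @param site_series a [climate_series()] for the plantation site covering
#'   years `plant_year .. plant_year + ages - 1` for every site variable of
#'   the URF.
#' @param plant_year planting (germination) calendar year.
#' @param ages number of ages to assemble (default 80).
#' @param smooth logical; smooth the lifespan-average climates with
#'   [smooth_log_regression()] before prediction (recommended for
#'   projection runs; leave off to reconstruct the fitting era exactly).
#' @param provenance_id,scenario labels carried into the result.
#' @return An object of class `climsens_curve`: list with `ages` (1..A),
#'   `heights` (m), `si_profile` (the per-age \eqn{SI_i}, m), `ht_common`
#'   (the per-age URF predictions at the common age, m), `si50` (height at
#'   age 50 when A >= 50), plus the identifying labels.
#' @export
build_curve <- function(params, urf, prov_normals, site_series, plant_year,
                        ages = 80L, smooth = FALSE,
                        provenance_id = "prov", scenario = "scenario") {
  stopifnot(inherits(params, "species_params"), inherits(urf, "urf_fit"),
            inherits(site_series, "climate_series"))
  A <- as.integer(ages)
  if (A < 1L) stop_domain("build_curve: 'ages' must be >= 1")
  miss <- setdiff(urf$spec$prov_vars, names(prov_normals))
  if (length(miss)) {
    stop_domain("build_curve: provenance normals missing variable(s): %s",
                paste(miss, collapse = ", "))
  }

  # Step 1: lifespan-average site climate for each age, optionally smoothed.
  site_vars <- urf$spec$site_vars
  avg <- matrix(NA_real_, A, length(site_vars),
                dimnames = list(NULL, site_vars))
  for (v in site_vars) {
    avg[, v] <- vapply(seq_len(A), function(i)
      lifespan_average(site_series, v, plant_year, i), 0)
    if (smooth) avg[, v] <- as.numeric(smooth_log_regression(avg[, v]))
  }
  newdata <- as.data.frame(avg)
  names(newdata) <- paste0(site_vars, ".s")
  for (v in urf$spec$prov_vars) {
    newdata[[paste0(v, ".p")]] <- unname(prov_normals[v])
  }
  ht_common <- predict(urf, newdata)

  # Step 2: solve the top-height equation for the per-age site index.
  si_profile <- vapply(seq_len(A), function(i) {
    tryCatch(invert_site_index(params, ht_common[i], params$common_age),
             error = function(e) {
               stop_domain("build_curve: site-index inversion failed at age %d (predicted common-age height %.3f m): %s",
                           i, ht_common[i], conditionMessage(e))
             })
  }, 0)

  # Steps 3-4: assemble annual increments from the per-age static curves.
  heights <- numeric(A)
  heights[1] <- evaluate_top_height(params, si_profile[1], 1)
  floored <- 0L
  for (i in seq_len(A)[-1]) {
    inc <- annual_increment(params, si_profile[i], i)
    if (inc < 0) {
      floored <- floored + 1L
      inc <- 0
    }
    heights[i] <- heights[i - 1] + inc
  }
  if (floored > 0L) {
    warning(sprintf("build_curve: %d negative increment(s) floored at 0", floored),
            call. = FALSE)
  }

  structure(
    list(species_code = params$species_code,
         provenance_id = provenance_id,
         site_id = site_series$location_id,
         scenario = scenario,
         plant_year = plant_year,
         ages = seq_len(A),
         heights = heights,
         si_profile = si_profile,
         ht_common = ht_common,
         smooth = smooth,
         si50 = if (A >= 50L) heights[50] else NA_real_),
    class = "climsens_curve")
}

#' @export
print.climsens_curve <- function(x, ...) {
  cat(sprintf("<climsens_curve: %s, prov %s at site %s [%s]>\n",
              x$species_code, x$provenance_id, x$site_id, x$scenario))
  cat(sprintf("  ages 1..%d; height at max age %.2f m; SI(50) %s\n",
              max(x$ages), x$heights[length(x$heights)],
              if (is.na(x$si50)) "n/a" else sprintf("%.2f m", x$si50)))
  invisible(x)
}

#' @export
as.data.frame.climsens_curve <- function(x, ...) {
  data.frame(age = x$ages, si_i = x$si_profile, ht_common = x$ht_common,
             height_m = x$heights)
}

#' Site index at age 50 of an assembled curve
#'
#' The assembled curve's height at total age 50 — the climate-sensitive
#' site index used for productivity mapping.
#'
#' @param curve a `climsens_curve` assembled over at least 50 ages.
#' @return Height (m) at age 50.
#' @export
site_index_at_50 <- function(curve) {
  stopifnot(inherits(curve, "climsens_curve"))
  if (max(curve$ages) < 50L) {
    stop_domain("site_index_at_50: curve covers only %d ages (need >= 50)",
                max(curve$ages))
  }
  curve$heights[50]
}
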