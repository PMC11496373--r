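#' Map local-population site index across a landscape
#'
#' For every in-range landscape point, builds the climate-sensitive curve
#' of the geographically local population (provenance normals = the point's
#' own 1961–1990 normals) under the point's scenario climate series, and
#' under a no-change replay of its normals, then records the age-50 site
#' index and its change.
#'
#' @param landscape a [make_climate_landscape()] result (or any object of
#'   the same shape) whose `series` hold the scenario's annual climates.
#' @param urf the selected `urf_fit`.
#' @param params a [species_params()] object.
#' @param scenario label recorded on the output rows.
#' @param ages curve length (>= 50; default 50).
#' @param smooth passed to [build_curve()].
#' @return data.frame with one row per in-range point: `point_id`,
#'   `scenario`, `si_local` (m, age-50 under the scenario), `si_ncc` (m,
#'   no climate change), `si_dif` (= si_local - si_ncc), and placeholder
#'   columns `si_opt`, `si_imp`, `excluded` filled by
#'   [map_optimal_si()] / [apply_extrapolation_exclusion()]. Out-of-range
#'   points are skipped with a message.
#' @export
map_local_si <- function(landscape, urf, params, scenario = "scenario",
                         ages = 50L, smooth = FALSE) {
  pts <- landscape$points
  skipped <- sum(!pts$in_range)
  if (skipped > 0L) {
    message(sprintf("map_local_si: skipping %d point(s) outside the species range",
                    skipped))
  }
  use <- pts$point_id[pts$in_range]
  rows <- lapply(use, function(id) {
    normals <- point_normals(landscape, id)
    ser <- landscape$series[[id]]
    cc <- build_curve(params, urf, normals, ser, landscape$start_year,
                      ages = ages, smooth = smooth,
                      provenance_id = id, scenario = scenario)
    ncc <- build_curve(params, urf, normals,
                       constant_series(normals, ser$years, id),
                       landscape$start_year, ages = ages, smooth = FALSE,
                       provenance_id = id, scenario = "no_change")
    data.frame(point_id = id, scenario = scenario,
               si_local = site_index_at_50(cc),
               si_ncc = site_index_at_50(ncc),
               si_dif = site_index_at_50(cc) - site_index_at_50(ncc),
               si_opt = NA_real_, si_imp = NA_real_, excluded = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Select the optimal population for one planting site
#'
#' Evaluates the age-50 height of every candidate provenance climate at the
#' site's scenario climate through the climate-sensitive curve, and returns
#' the candidate expected to grow tallest (ties broken toward the first
#' candidate in order), along with the improvement over the local
#' population.
#'
#' @param local_normals named numeric: the site's own 1961–1990 normals
#'   (the local population's provenance climate).
#' @param site_series [climate_series()] of the site's scenario climate.
#' @param candidates matrix of candidate provenance climate normals (one
#'   row per candidate, registry variable columns), or a list of named
#'   vectors.
#' @param urf the selected `urf_fit`.
#' @param params a [species_params()] object.
#' @param plant_year planting year.
#' @param ages curve length (>= 50).
#' @param smooth passed to [build_curve()].
#' @return list with `best` (candidate index), `best_climate` (its normals),
#'   `si_opt` (m), `si_local` (m), `si_imp` (= si_opt - si_local, m).
#' @export
select_optimal_population <- function(local_normals, site_series, candidates,
                                      urf, params, plant_year, ages = 50L,
                                      smooth = FALSE) {
  if (is.matrix(candidates)) {
    cn <- colnames(candidates)
    candidates <- lapply(seq_len(nrow(candidates)), function(i)
      setNames(as.vector(candidates[i, ]), cn))
  }
  if (!length(candidates)) {
    stop_domain("select_optimal_population: no candidate provenances")
  }
  si50 <- vapply(candidates, function(cl) {
    site_index_at_50(build_curve(params, urf, cl, site_series, plant_year,
                                 ages = ages, smooth = smooth))
  }, 0)
  best <- which.max(si50)  # ties -> first in candidate order
  si_local <- site_index_at_50(
    build_curve(params, urf, local_normals, site_series, plant_year,
                ages = ages, smooth = smooth))
  list(best = best, best_climate = candidates[[best]],
       si_opt = si50[best], si_local = si_local,
       si_imp = si50[best] - si_local)
}

#' Scan optimal populations over a mapped landscape
#'
#' Samples a fixed candidate set of provenance climates from the in-range
#' landscape points (default 100, uniform with a fixed seed) and runs
#' [select_optimal_population()] at every mapped point, filling the
#' `si_opt` and `si_imp` columns of a [map_local_si()] record table.
#'
#' @param records output of [map_local_si()].
#' @param landscape the same landscape object.
#' @param urf,params as in [map_local_si()].
#' @param n_candidates number of candidate provenances to sample (capped at
#'   the number of in-range points).
#' @param seed sampling seed.
#' @param ages,smooth passed to the curve builder.
#' @return `records` with `si_opt`, `si_imp` filled and the chosen
#'   candidate's point id in `optimal_point`.
#' @export
map_optimal_si <- function(records, landscape, urf, params,
                           n_candidates = 100L, seed = 20240513L,
                           ages = 50L, smooth = FALSE) {
  in_range <- landscape$points$point_id[landscape$points$in_range]
  n_candidates <- min(n_candidates, length(in_range))
  cand_ids <- local_seed(seed, sample(in_range, n_candidates))
  cand <- landscape$normals[cand_ids, , drop = FALSE]
  records$optimal_point <- NA_character_
  for (i in seq_len(nrow(records))) {
    id <- records$point_id[i]
    sel <- select_optimal_population(
      point_normals(landscape, id), landscape$series[[id]], cand, urf, params,
      landscape$start_year, ages = ages, smooth = smooth)
    records$si_opt[i] <- sel$si_opt
    records$si_imp[i] <- sel$si_opt - records$si_local[i]
    records$optimal_point[i] <- cand_ids[sel$best]
  }
  records
}

#' Flag records at risk of extrapolation
#'
#' Marks records whose optimal-population site index strictly exceeds the
#' threshold (default 25 m) as excluded — these correspond to climates
#' outside the range sampled by the provenance trials, where URF
#' predictions extrapolate. No records are deleted.
#'
#' @param records record table with an `si_opt` column.
#' @param threshold exclusion threshold, metres (strict `>`).
#' @return `records` with the `excluded` column set.
#' @export
apply_extrapolation_exclusion <- function(records, threshold = 25) {
  if (!"si_opt" %in% names(records)) {
    stop_domain("apply_extrapolation_exclusion: records lack an 'si_opt' column")
  }
  records$excluded <- !is.na(records$si_opt) & records$si_opt > threshold
  records
}
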