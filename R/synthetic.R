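#' Ground-truth configuration for synthetic provenance trials
#'
#' Bundles the known true URF, the species curve parameters, the trial
#' design (sites, populations, blocks, trees per plot), and the noise
#' structure used by [make_trial_dataset()]. Tree-level noise is
#' multiplicative lognormal (matching the log-scale screening fit); block
#' effects are additive Gaussian shifts; health flags are Bernoulli.
#'
#' @param true_urf a `urf_fit` (typically from [urf_model()]) defining the
#'   data-generating response.
#' @param species_params a [species_params()] object.
#' @param n_sites,n_populations,n_blocks,trees_per_plot trial design counts
#'   (all >= 1).
#' @param noise_sd_log sd of the lognormal tree-level noise (log scale).
#' @param block_sd sd of the additive block shifts, metres.
#' @param unhealthy_rate probability a tree is flagged unhealthy.
#' @param seed integer seed; every generated table records it.
#' @return An object of class `truth_config`.
#' @export
truth_config <- function(true_urf, species_params,
                         n_sites = 10L, n_populations = 15L, n_blocks = 5L,
                         trees_per_plot = 5L, noise_sd_log = 0.05,
                         block_sd = 0.3, unhealthy_rate = 0.1, seed = 1L) {
  stopifnot(inherits(true_urf, "urf_fit"), inherits(species_params, "species_params"))
  counts <- c(n_sites, n_populations, n_blocks, trees_per_plot)
  if (any(counts < 1L)) stop_domain("truth_config: all design counts must be >= 1")
  if (unhealthy_rate < 0 || unhealthy_rate > 1) {
    stop_domain("truth_config: unhealthy_rate must be in [0, 1]")
  }
  structure(
    list(true_urf = true_urf, species_params = species_params,
         n_sites = as.integer(n_sites), n_populations = as.integer(n_populations),
         n_blocks = as.integer(n_blocks), trees_per_plot = as.integer(trees_per_plot),
         noise_sd_log = noise_sd_log, block_sd = block_sd,
         unhealthy_rate = unhealthy_rate, seed = as.integer(seed)),
    class = "truth_config")
}

#' Generate a synthetic climate landscape
#'
#' Draws point locations over an Alberta-like longitude/latitude box and
#' generates, for each point and each named registry variable, a 1961–1990
#' normal (linear latitudinal gradient plus point-level noise around a
#' typical boreal magnitude) and an annual series (normal plus an optional
#' linear warming trend plus inter-annual noise). Deterministic given the
#' seed.
#'
#' @param n_points number of landscape points (>= 1).
#' @param variable_names registry climate variables to generate.
#' @param seed integer seed.
#' @param n_years length of the annual series.
#' @param start_year first calendar year of the series (also the default
#'   planting year); the trend is zero in this year.
#' @param warming named numeric: per-year linear trend added to the series
#'   (units of the variable per year); variables not named get 0.
#' @param base,gradient,noise_sd,annual_sd optional named numeric overrides
#'   of the per-variable normal base value, per-degree-latitude gradient,
#'   point-level noise sd, and inter-annual noise sd. Defaults scale with
#'   each variable's typical magnitude.
#' @param in_range_prob probability a point lies inside the species' natural
#'   range (default 1).
#' @param lon_range,lat_range sampling box, degrees.
#' @return An object of class `climate_landscape`: list with `points`
#'   (data.frame `point_id`, `lon`, `lat`, `in_range`), `variables`,
#'   `normals` (points x variables matrix), and `series` (named list of
#'   [climate_series()] per point).
#' @export
make_climate_landscape <- function(n_points, variable_names, seed,
                                   n_years = 80L, start_year = 2006L,
                                   warming = NULL, base = NULL,
                                   gradient = NULL, noise_sd = NULL,
                                   annual_sd = NULL, in_range_prob = 1,
                                   lon_range = c(-120, -110),
                                   lat_range = c(49, 60)) {
  if (n_points < 1L) stop_domain("make_climate_landscape: n_points must be >= 1")
  assert_known_variables(variable_names, "make_climate_landscape")
  reg <- climate_variables()
  typical <- setNames(reg$typical, reg$variable)[variable_names]
  scale <- pmax(abs(typical), 1)

  fill <- function(override, default) {
    out <- default
    if (!is.null(override)) out[names(override)] <- override
    out[variable_names]
  }
  base <- fill(base, typical)
  gradient <- fill(gradient, setNames(0.08 * scale, variable_names))
  noise_sd <- fill(noise_sd, setNames(0.03 * scale, variable_names))
  annual_sd <- fill(annual_sd, setNames(0.05 * scale, variable_names))
  warming <- fill(warming, setNames(rep(0, length(variable_names)), variable_names))

  local_seed(seed, {
    ids <- sprintf("pt%03d", seq_len(n_points))
    points <- data.frame(
      point_id = ids,
      lon = runif(n_points, lon_range[1], lon_range[2]),
      lat = runif(n_points, lat_range[1], lat_range[2]),
      in_range = runif(n_points) < in_range_prob,
      stringsAsFactors = FALSE)

    normals <- matrix(NA_real_, n_points, length(variable_names),
                      dimnames = list(ids, variable_names))
    for (v in variable_names) {
      normals[, v] <- base[v] + gradient[v] * (points$lat - mean(lat_range)) +
        rnorm(n_points, 0, noise_sd[v])
    }

    years <- seq(start_year, length.out = n_years)
    series <- lapply(ids, function(id) {
      vals <- matrix(NA_real_, n_years, length(variable_names),
                     dimnames = list(NULL, variable_names))
      for (v in variable_names) {
        vals[, v] <- normals[id, v] + warming[v] * (years - start_year) +
          rnorm(n_years, 0, annual_sd[v])
      }
      climate_series(id, years, vals, normals[id, ])
    })
    names(series) <- ids

    structure(
      list(points = points, variables = variable_names,
           normals = normals, series = series,
           start_year = start_year, seed = seed),
      class = "climate_landscape")
  })
}

#' @export
print.climate_landscape <- function(x, ...) {
  cat(sprintf("<climate_landscape> %d points, %d variables, years %d-%d (seed %s)\n",
              nrow(x$points), length(x$variables), x$start_year,
              x$start_year + length(x$series[[1]]$years) - 1L, x$seed))
  invisible(x)
}

#' Climate normals of one landscape point
#'
#' Row extraction that keeps variable names even when the landscape holds a
#' single climate variable.
#'
#' @param landscape a [make_climate_landscape()] result.
#' @param point_id the point to extract.
#' @return Named numeric vector of the point's 1961–1990 normals.
#' @export
point_normals <- function(landscape, point_id) {
  setNames(as.vector(landscape$normals[point_id, ]),
           colnames(landscape$normals))
}

#' Lifespan-average site climates for all landscape points
#'
#' Convenience matrix of [lifespan_average()] values (planting year through
#' the given age) for every point and every landscape variable — the site
#' climate summary URF fitting consumes.
#'
#' @param landscape a [make_climate_landscape()] result.
#' @param age averaging window length, years.
#' @param point_ids subset of points (default all).
#' @return Matrix, points x variables.
#' @export
landscape_lifespan_averages <- function(landscape, age, point_ids = NULL) {
  ids <- if (is.null(point_ids)) landscape$points$point_id else point_ids
  out <- matrix(NA_real_, length(ids), length(landscape$variables),
                dimnames = list(ids, landscape$variables))
  for (id in ids) {
    for (v in landscape$variables) {
      out[id, v] <- lifespan_average(landscape$series[[id]], v,
                                     landscape$start_year, age)
    }
  }
  out
}

#' Generate a synthetic provenance-trial dataset with known truth
#'
#' Assigns the first `n_sites` landscape points as test sites and the next
#' `n_populations` points as provenances. The expected common-age top
#' height of each population at each site comes from the true URF applied
#' to the provenance normals and the site lifespan-average climate; per-age
#' expected heights are back-computed through the species curve (invert to
#' site index, evaluate at the measurement age). Tree records add
#' multiplicative lognormal noise and additive block shifts, and receive
#' Bernoulli health flags.
#'
#' @param truth a [truth_config()].
#' @param landscape a [make_climate_landscape()] covering at least
#'   `n_sites + n_populations` points and all variables the true URF
#'   references.
#' @param measurement_ages integer vector of ages at which trees are
#'   measured (default: the species' common age only).
#' @return A list with `trials` (tree-level data.frame: `site_id`,
#'   `population_id`, `block_id`, `tree_id`, `totage`, `height`,
#'   `health_flag`), `truth` (noiseless common-age population-by-site top
#'   heights), `prov_normals` and `site_climate` (matrices keyed by the
#'   generated population/site ids), and `seed`.
#' @export
make_trial_dataset <- function(truth, landscape, measurement_ages = NULL) {
  stopifnot(inherits(truth, "truth_config"), inherits(landscape, "climate_landscape"))
  params <- truth$species_params
  if (is.null(measurement_ages)) measurement_ages <- params$common_age
  need <- truth$n_sites + truth$n_populations
  if (nrow(landscape$points) < need) {
    stop_domain("make_trial_dataset: landscape has %d points but the design needs %d",
                nrow(landscape$points), need)
  }
  site_pts <- landscape$points$point_id[seq_len(truth$n_sites)]
  pop_pts <- landscape$points$point_id[truth$n_sites + seq_len(truth$n_populations)]
  site_ids <- sprintf("S%02d", seq_len(truth$n_sites))
  pop_ids <- sprintf("P%03d", seq_len(truth$n_populations))

  prov_normals <- landscape$normals[pop_pts, , drop = FALSE]
  rownames(prov_normals) <- pop_ids
  site_climate <- landscape_lifespan_averages(landscape, params$common_age, site_pts)
  rownames(site_climate) <- site_ids

  grid <- expand.grid(population_id = pop_ids, site_id = site_ids,
                      stringsAsFactors = FALSE)
  truth_tab <- urf_training_table(
    data.frame(grid, top_height = NA_real_), prov_normals, site_climate)
  truth_tab$top_height <- predict(truth$true_urf, truth_tab)
  truth_tab$totage <- params$common_age

  si <- invert_site_index(params, truth_tab$top_height,
                          rep(params$common_age, nrow(truth_tab)))

  unhealthy_pool <- c("dead", "crooked", "browsed", "diseased")
  local_seed(truth$seed, {
    block_shift <- array(
      rnorm(truth$n_sites * truth$n_blocks, 0, truth$block_sd),
      dim = c(truth$n_sites, truth$n_blocks),
      dimnames = list(site_ids, NULL))
    rows <- vector("list", nrow(truth_tab) * length(measurement_ages))
    ri <- 0L
    for (k in seq_len(nrow(truth_tab))) {
      for (am in measurement_ages) {
        mean_h <- evaluate_top_height(params, si[k], am)
        n_tree <- truth$n_blocks * truth$trees_per_plot
        noise <- exp(rnorm(n_tree, 0, truth$noise_sd_log))
        blocks <- rep(seq_len(truth$n_blocks), each = truth$trees_per_plot)
        h <- pmax(mean_h * noise + block_shift[truth_tab$site_id[k], blocks], 0.01)
        sick <- runif(n_tree) < truth$unhealthy_rate
        flag <- ifelse(sick, sample(unhealthy_pool, n_tree, replace = TRUE),
                       "healthy")
        ri <- ri + 1L
        rows[[ri]] <- data.frame(
          site_id = truth_tab$site_id[k],
          population_id = truth_tab$population_id[k],
          block_id = sprintf("B%d", blocks),
          tree_id = sprintf("%s_%s_a%d_t%02d", truth_tab$site_id[k],
                            truth_tab$population_id[k], am, seq_len(n_tree)),
          totage = am,
          height = h,
          health_flag = flag,
          stringsAsFactors = FALSE)
      }
    }
    trials <- do.call(rbind, rows[seq_len(ri)])
    rownames(trials) <- NULL
    list(trials = trials,
         truth = truth_tab[, c("site_id", "population_id", "totage", "top_height")],
         prov_normals = prov_normals,
         site_climate = site_climate,
         site_points = setNames(site_pts, site_ids),
         population_points = setNames(pop_pts, pop_ids),
         seed = truth$seed)
  })
}
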