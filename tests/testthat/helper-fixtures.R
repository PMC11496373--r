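# Shared fixtures, built in code at test time.

sw <- default_species_params("white_spruce")
pl <- default_species_params("lodgepole_pine")

# A simple one-provenance/one-site ground-truth URF on MAT, increasing in
# site MAT around typical boreal values (used wherever curve direction or
# constant-climate identities are exercised).
simple_true_urf <- function(alpha_site = 0.10, gamma_site = -0.02,
                            alpha_prov = 0.08, gamma_prov = -0.04) {
  standardized_true_urf(
    "MAT", "MAT",
    center = c(MAT = 2), scale = c(MAT = 1.2),
    alpha_prov = alpha_prov, gamma_prov = gamma_prov,
    alpha_site = alpha_site, gamma_site = gamma_site,
    log_center = log(9))
}

# Landscape with independent (gradient-free) climate fields so that pool
# variables are mutually uncorrelated across points and the true variables
# are identifiable.
independent_landscape <- function(n_points, vars, seed, n_years = 40L,
                                  warming = NULL, annual_sd = NULL) {
  reg <- climate_variables()
  typ <- setNames(reg$typical, reg$variable)[vars]
  make_climate_landscape(
    n_points, vars, seed = seed, n_years = n_years,
    warming = warming,
    gradient = setNames(rep(0, length(vars)), vars),
    noise_sd = setNames(pmax(abs(typ), 1) * 0.15, vars),
    annual_sd = annual_sd)
}

# Four-variable-per-side recovery setting: true 2-prov/2-site URF inside
# 4x4 pools, observations = population x site common-age heights with
# multiplicative lognormal noise.
recovery_setting <- function(seed, n_sites = 25L, n_pops = 20L,
                             noise_sd_log = 0.05) {
  prov_pool <- c("MAT", "TD", "CMD", "Eref")
  site_pool <- c("MAT", "MAP", "DD5", "AHM")
  vars <- union(prov_pool, site_pool)
  land <- independent_landscape(n_sites + n_pops, vars, seed = seed,
                                n_years = sw$common_age + 1L)
  reg <- climate_variables()
  typ <- setNames(reg$typical, reg$variable)[vars]
  ctr <- typ
  scl <- pmax(abs(typ), 1) * 0.15
  tru <- standardized_true_urf(
    c("MAT", "TD"), c("MAT", "MAP"), ctr, scl,
    alpha_prov = c(0.10, 0.08), gamma_prov = c(-0.04, -0.03),
    alpha_site = c(0.12, 0.09), gamma_site = c(-0.05, -0.04),
    delta = matrix(c(0.03, 0, 0, 0.02), 2, 2),
    log_center = log(9))
  tc <- truth_config(tru, sw, n_sites = n_sites, n_populations = n_pops,
                     n_blocks = 2L, trees_per_plot = 1L,
                     noise_sd_log = 0, block_sd = 0, unhealthy_rate = 0,
                     seed = seed)
  dat <- make_trial_dataset(tc, land)
  tab <- urf_training_table(dat$truth, dat$prov_normals, dat$site_climate)
  # observation-level lognormal noise on the population x site heights
  tab$true_height <- tab$top_height
  tab$top_height <- local_noise(tab$top_height, noise_sd_log, seed + 1000L)
  list(tab = tab, true_urf = tru, prov_pool = prov_pool,
       site_pool = site_pool, landscape = land)
}

local_noise <- function(x, sd_log, seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  x * exp(rnorm(length(x), 0, sd_log))
}

# Tiny balanced trial table with known structure.
balanced_trial <- function(pop_means, block_shifts, site_id = "S1", age = 16,
                           noise = 0) {
  rows <- expand.grid(population_id = names(pop_means),
                      block_id = names(block_shifts),
                      tree = 1:2, stringsAsFactors = FALSE)
  rows$site_id <- site_id
  rows$totage <- age
  rows$tree_id <- sprintf("t%03d", seq_len(nrow(rows)))
  rows$height <- pop_means[rows$population_id] +
    block_shifts[rows$block_id] +
    if (noise > 0) rnorm(nrow(rows), 0, noise) else 0
  rows$health_flag <- "healthy"
  rows
}
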