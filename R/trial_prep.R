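#' Filter provenance-trial trees by health flag
#'
#' Keeps only healthy trees; records flagged dead, crooked, browsed, or
#' diseased are dropped. Input row order is preserved.
#'
#' @param observations data.frame of tree observations with at least a
#'   `health_flag` column (values among `healthy`, `dead`, `crooked`,
#'   `browsed`, `diseased`).
#' @return The healthy subset, same columns and order.
#' @export
filter_trees <- function(observations) {
  flags <- c("healthy", "dead", "crooked", "browsed", "diseased")
  bad <- setdiff(unique(observations$health_flag), flags)
  if (length(bad)) {
    stop_domain("filter_trees: unknown health flag(s): %s",
                paste(bad, collapse = ", "))
  }
  observations[observations$health_flag == "healthy", , drop = FALSE]
}

#' Block-adjusted population mean heights at one site and age
#'
#' Estimates population mean heights from a linear mixed model with
#' population as a fixed effect and block as a random intercept, fitted to
#' the (already health-filtered) trees measured at one site and one age.
#' When the block variance component is estimated at zero the adjusted
#' means equal the raw population means; in balanced designs additive block
#' shifts cancel either way. If the mixed-model fit is singular in a way
#' that prevents estimation, the function falls back to a fixed-effect
#' block adjustment (ordinary least squares on population + block) with a
#' notice.
#'
#' @param observations data.frame with columns `site_id`, `population_id`,
#'   `block_id`, `totage`, `height`; all rows must share one site and age.
#' @param age the measurement age the rows correspond to (checked).
#' @param site_id the site the rows correspond to (checked).
#' @return data.frame with columns `site_id`, `population_id`, `totage`,
#'   `top_height`, `n_trees` — one row per population, sorted by
#'   `population_id`.
#' @export
estimate_population_heights <- function(observations, age, site_id) {
  d <- observations
  if (!nrow(d)) stop_domain("estimate_population_heights: no observations")
  if (!all(d$site_id == site_id) || !all(d$totage == age)) {
    stop_domain("estimate_population_heights: rows must all be from site '%s' at age %s",
                site_id, age)
  }
  d$population_id <- factor(d$population_id)
  d$block_id <- factor(d$block_id)
  n_blocks <- nlevels(d$block_id)
  if (n_blocks < 2L) {
    stop_domain("estimate_population_heights: need >= 2 blocks at site '%s' (got %d)",
                site_id, n_blocks)
  }
  means <- tryCatch({
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(height ~ 0 + population_id + (1 | block_id), data = d,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))))
    b <- lme4::fixef(fit)
    setNames(as.numeric(b), sub("^population_id", "", names(b)))
  }, error = function(e) {
    message("estimate_population_heights: mixed-model fit failed (",
            conditionMessage(e), "); using fixed-effect block adjustment")
    fit <- lm(height ~ 0 + population_id + block_id,
              data = d, contrasts = list(block_id = "contr.sum"))
    b <- coef(fit)
    pop <- b[grepl("^population_id", names(b))]
    setNames(as.numeric(pop), sub("^population_id", "", names(pop)))
  })
  counts <- table(d$population_id)
  out <- data.frame(
    site_id = site_id,
    population_id = names(means),
    totage = age,
    top_height = as.numeric(means),
    n_trees = as.integer(counts[names(means)]),
    stringsAsFactors = FALSE)
  out <- out[order(out$population_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Convert a height to the species' common age
#'
#' Inverts the species top-height equation at the measured age to obtain
#' the implied site index, then evaluates the curve of that site index at
#' the common age. Heights already measured at the common age are returned
#' unchanged.
#'
#' @param params a [species_params()] object.
#' @param height top height (m) at `measured_age`.
#' @param measured_age total age of the measurement, years.
#' @return Height (m) at `params$common_age`.
#' @export
convert_to_common_age <- function(params, height, measured_age) {
  if (length(height) > 1L || length(measured_age) > 1L) {
    return(mapply(function(h, a) convert_to_common_age(params, h, a),
                  height, measured_age))
  }
  if (measured_age == params$common_age) return(height)
  si <- invert_site_index(params, height, measured_age)
  evaluate_top_height(params, si, params$common_age)
}

#' Pick the measurement age closest to the common age
#'
#' @param available_ages integer vector of ages at which a site was
#'   measured (non-empty).
#' @param common_age the species' common age.
#' @return The age minimising the distance to `common_age`; ties are
#'   broken toward the older age (later measurements integrate more growth
#'   signal).
#' @export
select_nearest_age <- function(available_ages, common_age) {
  if (!length(available_ages)) {
    stop_domain("select_nearest_age: no available ages")
  }
  d <- abs(available_ages - common_age)
  cand <- available_ages[d == min(d)]
  max(cand)
}

#' Prepare common-age population top heights from a raw trial table
#'
#' The full trial-preparation pipeline: filter unhealthy trees; per site,
#' select the measurement age nearest the species' common age; fit the
#' block-adjusted population means at that site and age; convert them to
#' the common age through the top-height equation.
#'
#' @param trials data.frame of tree observations (columns `site_id`,
#'   `population_id`, `block_id`, `tree_id`, `totage`, `height`,
#'   `health_flag`).
#' @param params a [species_params()] object.
#' @return data.frame with columns `site_id`, `population_id`, `totage`
#'   (the common age), `measured_age`, `top_height` (m, common age),
#'   `n_trees`.
#' @export
prepare_trial_heights <- function(trials, params) {
  healthy <- filter_trees(trials)
  out <- list()
  for (s in sort(unique(healthy$site_id))) {
    site_rows <- healthy[healthy$site_id == s, , drop = FALSE]
    age <- select_nearest_age(sort(unique(site_rows$totage)), params$common_age)
    means <- estimate_population_heights(
      site_rows[site_rows$totage == age, , drop = FALSE], age, s)
    means$measured_age <- age
    means$top_height <- convert_to_common_age(params, means$top_height, age)
    means$totage <- params$common_age
    out[[length(out) + 1L]] <- means
  }
  res <- do.call(rbind, out)
  res <- res[, c("site_id", "population_id", "totage", "measured_age",
                 "top_height", "n_trees")]
  rownames(res) <- NULL
  res
}
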