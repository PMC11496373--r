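#' Construct a ground-truth URF on standardized climate scales
#'
#' Builds a `urf_fit` whose log-height response is specified on
#' standardized variables \eqn{z_v = (x_v - center_v)/scale_v}:
#' \deqn{\ln HT = c_0 + \sum_p (\alpha_p z_p + \gamma_p z_p^2)
#'   + \sum_s (\alpha_s z_s + \gamma_s z_s^2)
#'   + \sum_{p,s} \delta_{ps} z_p z_s,}
#' expanded exactly into the raw-scale term list of [build_terms()]. This
#' makes effect sizes interpretable (log-height change per standard
#' deviation of climate) independently of the widely differing natural
#' units of climate variables, which is how ground truths for simulation
#' studies are most naturally stated.
#'
#' @param prov_vars,site_vars climate variable names (1–3 each).
#' @param center,scale named numeric: standardization constants covering
#'   all variables (e.g. landscape means and sds).
#' @param alpha_prov,gamma_prov numeric, linear and quadratic standardized
#'   effects per provenance variable (recycled).
#' @param alpha_site,gamma_site same for site variables.
#' @param delta matrix of standardized provenance-by-site interaction
#'   effects (`length(prov_vars)` x `length(site_vars)`; default 0).
#' @param log_center log height at the standardization centre (default
#'   `log(9)`, i.e. 9 m at the common age).
#' @return A `urf_fit` from [urf_model()] with the expanded raw-scale
#'   coefficients.
#' @export
standardized_true_urf <- function(prov_vars, site_vars, center, scale,
                                  alpha_prov = 0.1, gamma_prov = -0.05,
                                  alpha_site = 0.1, gamma_site = -0.05,
                                  delta = NULL, log_center = log(9)) {
  spec <- urf_spec(prov_vars, site_vars, include_intercept = TRUE)
  np <- length(prov_vars); ns <- length(site_vars)
  alpha_prov <- rep_len(alpha_prov, np); gamma_prov <- rep_len(gamma_prov, np)
  alpha_site <- rep_len(alpha_site, ns); gamma_site <- rep_len(gamma_site, ns)
  if (is.null(delta)) delta <- matrix(0, np, ns)
  delta <- matrix(delta, np, ns)
  vars <- c(prov_vars, site_vars)
  if (!all(vars %in% names(center)) || !all(vars %in% names(scale))) {
    stop_domain("standardized_true_urf: center/scale must cover all variables")
  }

  beta <- setNames(numeric(length(build_terms(spec))), build_terms(spec))
  c0 <- log_center
  add_quad <- function(beta, c0, lab, m, s, a, g) {
    beta[lab] <- beta[lab] + a / s - 2 * g * m / s^2
    beta[paste0(lab, "^2")] <- beta[paste0(lab, "^2")] + g / s^2
    list(beta = beta, c0 = c0 - a * m / s + g * m^2 / s^2)
  }
  for (i in seq_len(np)) {
    r <- add_quad(beta, c0, paste0(prov_vars[i], ".p"),
                  center[prov_vars[i]], scale[prov_vars[i]],
                  alpha_prov[i], gamma_prov[i])
    beta <- r$beta; c0 <- r$c0
  }
  for (j in seq_len(ns)) {
    r <- add_quad(beta, c0, paste0(site_vars[j], ".s"),
                  center[site_vars[j]], scale[site_vars[j]],
                  alpha_site[j], gamma_site[j])
    beta <- r$beta; c0 <- r$c0
  }
  for (i in seq_len(np)) {
    for (j in seq_len(ns)) {
      d <- delta[i, j]
      if (d == 0) next
      mp <- center[prov_vars[i]]; sp <- scale[prov_vars[i]]
      ms <- center[site_vars[j]]; ss <- scale[site_vars[j]]
      lab_p <- paste0(prov_vars[i], ".p"); lab_s <- paste0(site_vars[j], ".s")
      beta[paste0(lab_p, ":", lab_s)] <- beta[paste0(lab_p, ":", lab_s)] + d / (sp * ss)
      beta[lab_p] <- beta[lab_p] - d * ms / (sp * ss)
      beta[lab_s] <- beta[lab_s] - d * mp / (sp * ss)
      c0 <- c0 + d * mp * ms / (sp * ss)
    }
  }
  beta["(Intercept)"] <- c0
  urf_model(spec, beta)
}
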