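#' Specify a Universal Response Function
#'
#' A URF specification names 1–3 provenance climate variables and 1–3 site
#' climate variables. The model is an exponentiated quadratic: linear and
#' quadratic terms for every variable plus every provenance-by-site cross
#' term (no provenance-by-provenance or site-by-site crosses). With one
#' variable per side and no intercept this is exactly the canonical
#' five-coefficient URF
#' \deqn{HT = \exp(a_1 x_j + a_2 x_t + a_3 x_j^2 + a_4 x_t^2 + a_5 x_j x_t) + \varepsilon.}
#'
#' @param prov_vars character, 1–3 provenance climate variable names.
#' @param site_vars character, 1–3 site climate variable names.
#' @param include_intercept logical; include an intercept term (default
#'   `TRUE` — without it, a zero-climate input forces a height of 1 m).
#' @return An object of class `urf_spec`.
#' @export
urf_spec <- function(prov_vars, site_vars, include_intercept = TRUE) {
  if (!length(prov_vars) || length(prov_vars) > 3L ||
      !length(site_vars) || length(site_vars) > 3L) {
    stop_domain("urf_spec: need 1-3 provenance and 1-3 site variables")
  }
  if (anyDuplicated(prov_vars) || anyDuplicated(site_vars)) {
    stop_domain("urf_spec: duplicated variable names")
  }
  structure(
    list(prov_vars = as.character(prov_vars),
         site_vars = as.character(site_vars),
         include_intercept = isTRUE(include_intercept)),
    class = "urf_spec")
}

#' @export
print.urf_spec <- function(x, ...) {
  cat(sprintf("<urf_spec> prov: %s | site: %s%s\n",
              paste(x$prov_vars, collapse = ", "),
              paste(x$site_vars, collapse = ", "),
              if (x$include_intercept) " (+intercept)" else ""))
  invisible(x)
}

#' Count candidate URFs for given variable pools
#'
#' The number of candidate models formed by choosing 1 to `max_per_side`
#' provenance variables and 1 to `max_per_side` site variables:
#' \eqn{[\sum_{p} \binom{n_{prov}}{p}] \times [\sum_{s} \binom{n_{site}}{s}]}.
#' With the pruned pools of 14 provenance and 17 site variables this yields
#' 390,677 candidates; with 11 and 11, 53,361.
#'
#' @param n_prov_vars size of the provenance variable pool.
#' @param n_site_vars size of the site variable pool.
#' @param max_per_side maximum variables per side (default 3).
#' @return Integer count of candidate specifications.
#' @examples
#' count_candidates(14, 17)  # 390677
#' count_candidates(11, 11)  # 53361
#' @export
count_candidates <- function(n_prov_vars, n_site_vars, max_per_side = 3L) {
  stopifnot(n_prov_vars >= max_per_side, n_site_vars >= max_per_side)
  side <- function(n) sum(choose(n, seq_len(max_per_side)))
  side(n_prov_vars) * side(n_site_vars)
}

#' Enumerate all candidate URF specifications
#'
#' Generates every [urf_spec()] drawing 1..`max_per_side` variables per side
#' from the given pools, in a deterministic order: categories (number of
#' provenance variables, number of site variables) in row-major order, and
#' lexicographic combination order (by pool position) within a category.
#' With pools of at least `max_per_side` variables per side this partitions
#' the candidates into `max_per_side^2` categories (nine for the default).
#'
#' @param prov_pool character vector of retained provenance variables.
#' @param site_pool character vector of retained site variables.
#' @param max_per_side maximum variables per side (default 3).
#' @param include_intercept passed to each [urf_spec()].
#' @return List of `urf_spec` objects; each carries attributes `category`
#'   (e.g. `"2p3s"`) and `index` (position in the stream).
#' @export
enumerate_urf_specs <- function(prov_pool, site_pool, max_per_side = 3L,
                                include_intercept = TRUE) {
  specs <- list()
  idx <- 0L
  for (p in seq_len(min(max_per_side, length(prov_pool)))) {
    prov_sets <- combn(prov_pool, p, simplify = FALSE)
    for (s in seq_len(min(max_per_side, length(site_pool)))) {
      site_sets <- combn(site_pool, s, simplify = FALSE)
      for (pv in prov_sets) {
        for (sv in site_sets) {
          idx <- idx + 1L
          sp <- urf_spec(pv, sv, include_intercept)
          attr(sp, "category") <- sprintf("%dp%ds", p, s)
          attr(sp, "index") <- idx
          specs[[idx]] <- sp
        }
      }
    }
  }
  specs
}

#' Term list of a URF specification
#'
#' The ordered model terms: optional intercept, then linear provenance
#' terms, linear site terms, quadratic provenance terms, quadratic site
#' terms, and all provenance-by-site cross terms (provenance-major order).
#' Provenance variables are labelled `<var>.p`, site variables `<var>.s`.
#'
#' @param spec an [urf_spec()].
#' @return Character vector of term labels.
#' @export
build_terms <- function(spec) {
  p <- paste0(spec$prov_vars, ".p")
  s <- paste0(spec$site_vars, ".s")
  cross <- as.vector(t(outer(p, s, paste, sep = ":")))
  c(if (spec$include_intercept) "(Intercept)",
    p, s, paste0(p, "^2"), paste0(s, "^2"), cross)
}

# Design matrix for a spec from a data.frame holding <var>.p / <var>.s columns.
urf_design <- function(spec, data) {
  terms <- build_terms(spec)
  need <- c(paste0(spec$prov_vars, ".p"), paste0(spec$site_vars, ".s"))
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop_domain("urf design: data is missing column(s): %s",
                paste(missing_cols, collapse = ", "))
  }
  n <- nrow(data)
  X <- matrix(NA_real_, n, length(terms), dimnames = list(NULL, terms))
  for (tm in terms) {
    X[, tm] <- if (tm == "(Intercept)") {
      1
    } else if (grepl(":", tm, fixed = TRUE)) {
      parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
      data[[parts[1]]] * data[[parts[2]]]
    } else if (grepl("^2", tm, fixed = TRUE)) {
      data[[sub("\\^2$", "", tm)]]^2
    } else {
      data[[tm]]
    }
  }
  X
}
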