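new_urf_fit <- function(spec, coefficients, r2 = NA_real_, aic = NA_real_,
                        n = NA_integer_, collinear = FALSE, refined = FALSE,
                        ef_cv = NA_real_, rmsep_cv = NA_real_) {
  structure(
    list(spec = spec, coefficients = coefficients, r2 = r2, aic = aic,
         n = n, collinear = collinear, refined = refined,
         ef_cv = ef_cv, rmsep_cv = rmsep_cv),
    class = "urf_fit")
}

#' Construct a URF with known coefficients
#'
#' Builds a `urf_fit` object directly from a specification and a full
#' named coefficient vector (one entry per term of [build_terms()]), with
#' no data involved. This is how a ground-truth URF is defined for
#' simulation studies, and how a fitted model is reconstructed from a
#' serialised file.
#'
#' @param spec an [urf_spec()].
#' @param coefficients named numeric vector covering every term of
#'   `build_terms(spec)`.
#' @return An object of class `urf_fit`.
#' @export
urf_model <- function(spec, coefficients) {
  terms <- build_terms(spec)
  if (!all(terms %in% names(coefficients))) {
    stop_domain("urf_model: coefficients missing term(s): %s",
                paste(setdiff(terms, names(coefficients)), collapse = ", "))
  }
  new_urf_fit(spec, coefficients[terms])
}

#' Fit one URF to common-age top heights
#'
#' The screening fit is ordinary least squares of `ln(top_height)` on the
#' term list of the specification — deterministic and cheap enough to run
#' over hundreds of thousands of candidates. The reported R-squared is
#' computed on the original height scale from back-transformed predictions;
#' AIC comes from the log-scale Gaussian likelihood. Optionally a
#' Gauss-Newton nonlinear least-squares refinement on the original scale
#' (additive error on height) is run, initialised at the screening
#' estimates; if it fails to converge the screening estimates are kept with
#' a notice.
#'
#' @param spec an [urf_spec()].
#' @param data data.frame with a `top_height` column (m, > 0) and one
#'   column per referenced climate variable, named `<var>.p` for provenance
#'   normals and `<var>.s` for site lifespan-average climates.
#' @param refine logical; run the nonlinear refinement stage.
#' @return A `urf_fit`; if the design matrix is rank deficient the fit is
#'   flagged `collinear` and carries no statistics (such fits are excluded
#'   from model selection).
#' @export
fit_urf <- function(spec, data, refine = FALSE) {
  if (any(data$top_height <= 0)) {
    stop_domain("fit_urf: top heights must be positive")
  }
  X <- urf_design(spec, data)
  n <- nrow(X)
  k <- ncol(X)
  if (n < k + 2L) {
    stop_domain("fit_urf: need at least %d observations for %d terms (got %d)",
                k + 2L, k, n)
  }
  y <- log(data$top_height)
  ols <- lm.fit(X, y)
  if (ols$rank < k) {
    return(new_urf_fit(spec, setNames(rep(NA_real_, k), colnames(X)),
                       n = n, collinear = TRUE))
  }
  beta <- setNames(coef(ols), colnames(X))
  refined <- FALSE
  if (refine) {
    h <- data$top_height
    refined_beta <- tryCatch({
      fit_nls <- suppressWarnings(
        nls(h ~ as.vector(exp(X %*% b)),
            start = list(b = as.numeric(beta)),
            control = stats::nls.control(maxiter = 200, tol = 1e-10,
                                         minFactor = 1e-12, scaleOffset = 1,
                                         warnOnly = TRUE)))
      setNames(as.numeric(coef(fit_nls)), colnames(X))
    }, error = function(e) {
      message("fit_urf: nonlinear refinement did not converge (",
              conditionMessage(e), "); keeping screening estimates")
      NULL
    })
    if (!is.null(refined_beta)) {
      # accept only if the Gauss-Newton path did not worsen the
      # original-scale objective (a stalled line search keeps the start)
      sse <- function(b) sum((h - as.vector(exp(X %*% b)))^2)
      if (sse(refined_beta) <= sse(beta)) {
        beta <- refined_beta
        refined <- TRUE
      } else {
        message("fit_urf: nonlinear refinement did not improve the fit; keeping screening estimates")
      }
    }
  }
  pred <- as.vector(exp(X %*% beta))
  ss_tot <- sum((data$top_height - mean(data$top_height))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - sum((data$top_height - pred)^2) / ss_tot
  rss_log <- sum((y - as.vector(X %*% setNames(coef(ols), colnames(X))))^2)
  aic <- n * log(2 * pi) + n * log(rss_log / n) + n + 2 * (k + 1)
  new_urf_fit(spec, beta, r2 = r2, aic = aic, n = n, refined = refined)
}

#' @export
print.urf_fit <- function(x, ...) {
  cat(sprintf("<urf_fit> prov: %s | site: %s\n",
              paste(x$spec$prov_vars, collapse = ", "),
              paste(x$spec$site_vars, collapse = ", ")))
  if (isTRUE(x$collinear)) {
    cat("  rank deficient (collinear terms); excluded from selection\n")
  } else {
    cat(sprintf("  n = %s, R2 = %.3f, AIC = %.1f%s\n", x$n, x$r2, x$aic,
                if (isTRUE(x$refined)) " (NLS refined)" else ""))
    if (is.finite(x$rmsep_cv)) {
      cat(sprintf("  CV: RMSEP = %.3f m, EF = %.3f\n", x$rmsep_cv, x$ef_cv))
    }
  }
  invisible(x)
}

#' Predict common-age top height from a URF
#'
#' @param object a `urf_fit`.
#' @param newdata data.frame with the `<var>.p` / `<var>.s` columns the
#'   specification references.
#' @param ... unused.
#' @return Predicted top heights (m).
#' @export
predict.urf_fit <- function(object, newdata, ...) {
  if (isTRUE(object$collinear)) {
    stop_domain("predict.urf_fit: cannot predict from a collinear fit")
  }
  X <- urf_design(object$spec, newdata)
  as.vector(exp(X %*% object$coefficients[colnames(X)]))
}

#' Prediction efficiency
#'
#' \eqn{EF = 1 - \sum(Y - \hat Y)^2 / \sum(Y - \bar Y)^2}: 1 for perfect
#' prediction, 0 for predicting the observed mean, negative when worse
#' than the mean.
#'
#' @param observed,predicted numeric vectors of equal length (>= 2);
#'   the observed values must not all be identical.
#' @return The efficiency (unitless, <= 1).
#' @export
prediction_efficiency <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2L) {
    stop_domain("prediction_efficiency: need equal-length vectors of length >= 2")
  }
  denom <- sum((observed - mean(observed))^2)
  if (denom == 0) {
    stop_domain("prediction_efficiency: observed values are all identical")
  }
  1 - sum((observed - predicted)^2) / denom
}

#' Root mean square error of prediction
#'
#' \eqn{RMSEP = \sqrt{\sum(Y - \hat Y)^2 / n}}.
#'
#' @param observed,predicted numeric vectors of equal length (>= 1).
#' @return RMSEP, in the units of the inputs (metres for heights).
#' @export
rmsep <- function(observed, predicted) {
  if (length(observed) != length(predicted) || !length(observed)) {
    stop_domain("rmsep: need equal-length non-empty vectors")
  }
  sqrt(sum((observed - predicted)^2) / length(observed))
}

#' Exhaustive URF selection with k-fold cross-validation
#'
#' Fits every candidate specification drawn from the pools (screening OLS
#' on the log scale), keeps the highest-R-squared fit within each
#' (provenance count, site count) category, cross-validates the retained
#' category winners, and returns the one with the lowest RMSEP (ties broken
#' by higher EF, then enumeration order).
#'
#' Fold assignment is random over observations with a fixed seed, keyed to
#' a stable observation identifier (`site_id` x `population_id` when those
#' columns are present, otherwise row order), so results do not depend on
#' the row order of the input table.
#'
#' @param data training table as for [fit_urf()]; columns `site_id` and
#'   `population_id` are used as the stable observation key if present.
#' @param prov_pool,site_pool retained (pruned) climate variable names.
#' @param k_folds number of cross-validation folds (default 10).
#' @param seed fold-assignment seed (default 20240513).
#' @param max_per_side maximum variables per side (default 3).
#' @param include_intercept passed to the enumeration.
#' @param refine logical; run nonlinear refinement on the category winners.
#' @return A list with elements `final` (the selected `urf_fit`, carrying
#'   `ef_cv` and `rmsep_cv`), `category_best` (named list of the category
#'   winners with their CV statistics), and `summary` (data.frame of
#'   per-category results).
#' @export
select_urf <- function(data, prov_pool, site_pool, k_folds = 10L,
                       seed = 20240513L, max_per_side = 3L,
                       include_intercept = TRUE, refine = FALSE) {
  specs <- enumerate_urf_specs(prov_pool, site_pool, max_per_side,
                               include_intercept)
  fits <- lapply(specs, fit_urf, data = data)
  cats <- vapply(specs, function(s) attr(s, "category"), "")
  cat_levels <- unique(cats)

  best <- list()
  empty <- character()
  for (cl in cat_levels) {
    in_cat <- which(cats == cl)
    valid <- in_cat[!vapply(fits[in_cat], function(f) isTRUE(f$collinear), TRUE)]
    if (!length(valid)) {
      empty <- c(empty, cl)
      next
    }
    r2s <- vapply(fits[valid], function(f) f$r2, 0)
    win <- valid[which.max(r2s)]  # ties -> first in enumeration order
    best[[cl]] <- fits[[win]]
    attr(best[[cl]], "index") <- win
  }
  if (length(empty)) {
    stop_domain("select_urf: no valid (full-rank) fit in category(ies): %s",
                paste(empty, collapse = ", "))
  }

  # Stable observation key, then seeded random fold assignment.
  key <- if (all(c("site_id", "population_id") %in% names(data))) {
    order(data$site_id, data$population_id)
  } else {
    seq_len(nrow(data))
  }
  d <- data[key, , drop = FALSE]
  n <- nrow(d)
  folds <- local_seed(seed, sample(rep_len(seq_len(k_folds), n)))

  for (cl in names(best)) {
    spec <- best[[cl]]$spec
    pred <- rep(NA_real_, n)
    for (f in seq_len(k_folds)) {
      test <- folds == f
      if (!any(test)) next
      fit_f <- fit_urf(spec, d[!test, , drop = FALSE])
      if (isTRUE(fit_f$collinear)) {
        stop_domain("select_urf: fold %d refit is collinear for category %s", f, cl)
      }
      pred[test] <- predict(fit_f, d[test, , drop = FALSE])
    }
    best[[cl]]$ef_cv <- prediction_efficiency(d$top_height, pred)
    best[[cl]]$rmsep_cv <- rmsep(d$top_height, pred)
    if (refine) {
      ref <- fit_urf(spec, data, refine = TRUE)
      ref$ef_cv <- best[[cl]]$ef_cv
      ref$rmsep_cv <- best[[cl]]$rmsep_cv
      attr(ref, "index") <- attr(best[[cl]], "index")
      best[[cl]] <- ref
    }
  }

  ord <- order(vapply(best, function(f) f$rmsep_cv, 0),
               -vapply(best, function(f) f$ef_cv, 0),
               vapply(best, function(f) attr(f, "index"), 0L))
  final <- best[[ord[1]]]

  summary <- data.frame(
    category = names(best),
    prov_vars = vapply(best, function(f) paste(f$spec$prov_vars, collapse = ";"), ""),
    site_vars = vapply(best, function(f) paste(f$spec$site_vars, collapse = ";"), ""),
    r2 = vapply(best, function(f) f$r2, 0),
    aic = vapply(best, function(f) f$aic, 0),
    rmsep_cv = vapply(best, function(f) f$rmsep_cv, 0),
    ef_cv = vapply(best, function(f) f$ef_cv, 0),
    stringsAsFactors = FALSE)
  rownames(summary) <- NULL

  list(final = final, category_best = best, summary = summary)
}

#' Assemble the URF training table
#'
#' Joins common-age population top heights to the provenance climate
#' normals and the site lifespan-average climates, producing the `<var>.p`
#' / `<var>.s` columns [fit_urf()] expects.
#'
#' @param heights data.frame with `site_id`, `population_id`, `top_height`.
#' @param prov_normals numeric matrix of provenance normals, rownames =
#'   population ids, colnames = climate variables.
#' @param site_climate numeric matrix of site lifespan-average climates,
#'   rownames = site ids, colnames = climate variables.
#' @return The joined data.frame.
#' @export
urf_training_table <- function(heights, prov_normals, site_climate) {
  miss_p <- setdiff(unique(heights$population_id), rownames(prov_normals))
  miss_s <- setdiff(unique(heights$site_id), rownames(site_climate))
  if (length(miss_p) || length(miss_s)) {
    stop_domain("urf_training_table: missing climate for %s",
                paste(c(miss_p, miss_s), collapse = ", "))
  }
  out <- heights
  for (v in colnames(prov_normals)) {
    out[[paste0(v, ".p")]] <- prov_normals[as.character(heights$population_id), v]
  }
  for (v in colnames(site_climate)) {
    out[[paste0(v, ".s")]] <- site_climate[as.character(heights$site_id), v]
  }
  out
}
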