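#' Evaluate the species top-height equation
#'
#' Computes top height (m) at a given total age for a stand of the given
#' site index, using the species' equation form stored in `params`. At the
#' reference age (50 years) the result equals `si` exactly, because the
#' numerator and denominator of the equation coincide there.
#'
#' @param params a [species_params()] object.
#' @param si site index, metres (top height at 50 years total age); must be
#'   positive.
#' @param totage total age from germination, years (>= 1). `si` and `totage`
#'   are recycled against each other.
#' @return Top height in metres.
#' @examples
#' p <- default_species_params("white_spruce")
#' evaluate_top_height(p, si = 18, totage = 50)  # exactly 18
#' evaluate_top_height(p, si = 18, totage = 25)  # below 18
#' @export
evaluate_top_height <- function(params, si, totage) {
  stopifnot(inherits(params, "species_params"))
  if (any(!is.finite(si)) || any(si <= 0)) {
    stop_domain("evaluate_top_height: 'si' must be positive and finite (got %s)",
                paste(utils::head(si[!is.finite(si) | si <= 0], 3), collapse = ", "))
  }
  if (any(!is.finite(totage)) || any(totage < 1)) {
    stop_domain("evaluate_top_height: 'totage' must be >= 1 (got %s)",
                paste(utils::head(totage[!is.finite(totage) | totage < 1], 3), collapse = ", "))
  }
  k <- params$constants
  # The fourth constant multiplies sqrt(50) in both numerator and denominator.
  fixed <- k[3] * ht_si_term(params, si) + k[4] * sqrt(50)
  num <- 1 + exp(k[1] + k[2] * ht_age_term(params, params$reference_age) + fixed)
  den <- 1 + exp(k[1] + k[2] * ht_age_term(params, totage) + fixed)
  ht <- si * num / den
  if (any(!is.finite(ht))) {
    stop_domain("evaluate_top_height: non-finite result (si = %s, totage = %s)",
                paste(utils::head(si, 3), collapse = ","),
                paste(utils::head(totage, 3), collapse = ","))
  }
  ht
}

#' Solve the top-height equation for site index
#'
#' Finds the site index whose top-height curve passes through the given
#' height at the given total age, by bracketed (Brent) root finding on
#' si in [0.05, 80] m. Because the curve is validated to be strictly
#' increasing in site index, the root is unique when it exists.
#'
#' @param params a [species_params()] object.
#' @param height observed top height, metres (> 0).
#' @param totage total age, years (>= 1).
#' @param lower,upper search bracket for site index, metres.
#' @return The site index (m) such that
#'   `evaluate_top_height(params, si, totage)` reproduces `height` to within
#'   1e-8 m.
#' @examples
#' p <- default_species_params("lodgepole_pine")
#' h <- evaluate_top_height(p, si = 18, totage = 32)
#' invert_site_index(p, h, 32)  # 18
#' @export
invert_site_index <- function(params, height, totage, lower = 0.05, upper = 80) {
  stopifnot(inherits(params, "species_params"))
  if (length(height) > 1L || length(totage) > 1L) {
    return(mapply(function(h, a) invert_site_index(params, h, a, lower, upper),
                  height, totage))
  }
  if (!is.finite(height) || height <= 0) {
    stop_domain("invert_site_index: 'height' must be positive (got %s)", format(height))
  }
  if (!is.finite(totage) || totage < 1) {
    stop_domain("invert_site_index: 'totage' must be >= 1 (got %s)", format(totage))
  }
  f <- function(si) evaluate_top_height(params, si, totage) - height
  flo <- f(lower)
  fhi <- f(upper)
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0) {
    stop_domain(
      "invert_site_index: height outside representable range (height = %g m at totage = %g; curve spans [%g, %g] m over si in [%g, %g])",
      height, totage, height + flo, height + fhi, lower, upper)
  }
  root <- uniroot(f, lower = lower, upper = upper,
                  f.lower = flo, f.upper = fhi, tol = 1e-10)$root
  root
}

#' Annual top-height increment
#'
#' The height grown between total ages `age - 1` and `age` on the static
#' curve of the given site index. Strictly positive for any validated
#' parameter set. Summing increments from age 2 to A and adding the height
#' at age 1 telescopes back to the height at age A.
#'
#' @param params a [species_params()] object.
#' @param si site index, metres.
#' @param age total age, years (>= 2).
#' @return Increment in metres.
#' @export
annual_increment <- function(params, si, age) {
  if (any(age < 2)) {
    stop_domain("annual_increment: 'age' must be >= 2 (got %s)",
                paste(utils::head(age[age < 2], 3), collapse = ", "))
  }
  evaluate_top_height(params, si, age) - evaluate_top_height(params, si, age - 1)
}
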