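#' Species parameters for the top-height equations
#'
#' Container for the four constants of a species' stand-level top-height
#' equation, together with the species' common measurement age and the
#' reference age (50 years total age) at which top height equals site index
#' by construction. Two equation forms are supported, one per species:
#'
#' \describe{
#'   \item{white_spruce}{the age term is \eqn{\sqrt{\ln(1 + totage^2)}} and
#'     the site-index term is \eqn{[\ln(SI)]^2};}
#'   \item{lodgepole_pine}{the age term is \eqn{\sqrt{\ln(1 + totage)}} and
#'     the site-index term is \eqn{\ln(SI)}.}
#' }
#'
#' In both forms the predicted top height is
#' \deqn{HT(SI, a) = SI \cdot \frac{1 + \exp(c_1 + c_2 A(50) + c_3 G(SI) + c_4 \sqrt{50})}
#'                            {1 + \exp(c_1 + c_2 A(a)  + c_3 G(SI) + c_4 \sqrt{50})}}
#' where \eqn{A()} is the form's age term and \eqn{G()} its site-index term.
#' The numerator and denominator coincide at total age 50, so
#' \eqn{HT(SI, 50) = SI} identically. The constants have no biological
#' interpretation; any set is accepted provided the induced curve is strictly
#' increasing in total age over 1..80 and in site index, which is validated
#' at construction.
#'
#' @param species_code `"white_spruce"` or `"lodgepole_pine"`; selects the
#'   equation form.
#' @param constants numeric vector of length 4 (the equation constants, in
#'   order; names are ignored).
#' @param common_age integer, the common measurement age trials are converted
#'   to (16 for white spruce, 32 for lodgepole pine by convention).
#' @param reference_age integer, fixed at 50 (total age at which top height
#'   defines site index).
#' @param validate logical; check monotonicity of the induced curve.
#' @return An object of class `species_params`.
#' @seealso [evaluate_top_height()], [invert_site_index()],
#'   [default_species_params()]
#' @export
species_params <- function(species_code = c("white_spruce", "lodgepole_pine"),
                           constants,
                           common_age = NULL,
                           reference_age = 50L,
                           validate = TRUE) {
  species_code <- match.arg(species_code)
  constants <- as.numeric(constants)
  if (length(constants) != 4L || !all(is.finite(constants))) {
    stop_domain("'constants' must be 4 finite numbers (got %s)",
                paste(constants, collapse = ", "))
  }
  if (is.null(common_age)) {
    common_age <- switch(species_code, white_spruce = 16L, lodgepole_pine = 32L)
  }
  common_age <- as.integer(common_age)
  if (common_age <= 0L) stop_domain("'common_age' must be a positive integer")
  if (as.integer(reference_age) != 50L) {
    stop_domain("'reference_age' is fixed at 50 years total age")
  }
  obj <- structure(
    list(species_code = species_code,
         constants = constants,
         common_age = common_age,
         reference_age = 50L),
    class = "species_params")
  if (validate) validate_species_params(obj)
  obj
}

# Age and site-index transforms per equation form.
ht_age_term <- function(params, totage) {
  switch(params$species_code,
         white_spruce   = sqrt(log(1 + totage^2)),
         lodgepole_pine = sqrt(log(1 + totage)))
}

ht_si_term <- function(params, si) {
  switch(params$species_code,
         white_spruce   = log(si)^2,
         lodgepole_pine = log(si))
}

validate_species_params <- function(params) {
  ages <- 1:80
  for (si in c(2, 5, 10, 20, 40)) {
    ht <- evaluate_top_height(params, si, ages)
    if (!all(is.finite(ht)) || any(diff(ht) <= 0)) {
      stop_domain(
        "invalid species constants for %s: induced curve is not strictly increasing in totage over 1..80 at si = %g",
        params$species_code, si)
    }
  }
  si_grid <- seq(1, 60, by = 0.5)
  for (a in c(1, 10, 25, 50, 80)) {
    ht <- evaluate_top_height(params, si_grid, a)
    if (any(diff(ht) <= 0)) {
      stop_domain(
        "invalid species constants for %s: top height is not strictly increasing in site index at totage = %d",
        params$species_code, a)
    }
  }
  invisible(params)
}

#' @export
print.species_params <- function(x, ...) {
  cat(sprintf("<species_params: %s>\n", x$species_code))
  cat(sprintf("  constants:     %s\n", paste(signif(x$constants, 6), collapse = ", ")))
  cat(sprintf("  common age:    %d  reference age: %d\n", x$common_age, x$reference_age))
  invisible(x)
}

#' Load species parameters shipped with the package
#'
#' Reads the default species parameter file
#' (`inst/extdata/species_params_synthetic.yaml`). The constants in that
#' file are \emph{synthetic}: they are a calibration chosen to produce
#' realistic monotone sigmoid top-height curves with the correct algebraic
#' structure (site index recovered exactly at total age 50), not the
#' published operational constants of any jurisdiction's growth-and-yield
#' system. All package logic is agnostic to the specific constants; users
#' fitting operational curves should supply their own parameter file via
#' [read_species_params()].
#'
#' @param species_code `"white_spruce"` or `"lodgepole_pine"`.
#' @return A validated `species_params` object.
#' @export
default_species_params <- function(species_code = c("white_spruce", "lodgepole_pine")) {
  species_code <- match.arg(species_code)
  path <- system.file("extdata", "species_params_synthetic.yaml",
                      package = "climurf", mustWork = TRUE)
  read_species_params(path, species_code)
}

#' Read a species parameter file
#'
#' Parameter files are YAML with one top-level entry per species code, each
#' holding `constants` (list of 4 numbers) and `common_age`. The file is
#' schema-validated and the induced curve's monotonicity is checked on load.
#'
#' @param path path to the YAML parameter file.
#' @param species_code which species entry to load.
#' @return A validated `species_params` object.
#' @export
read_species_params <- function(path, species_code) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg[[species_code]])) {
    stop_domain("species '%s' not found in parameter file %s", species_code, path)
  }
  entry <- cfg[[species_code]]
  for (field in c("constants", "common_age")) {
    if (is.null(entry[[field]])) {
      stop_domain("parameter file %s: species '%s' is missing field '%s'",
                  path, species_code, field)
    }
  }
  species_params(species_code,
                 constants = unlist(entry$constants),
                 common_age = entry$common_age)
}
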