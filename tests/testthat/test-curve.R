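# The defining oracle of the merging algorithm: under a constant climate the
# per-age site indices coincide, the increments telescope, and the assembled
# curve must reproduce the static top-height curve exactly.
test_that("constant climate reproduces the static curve at every age", {
  tru <- simple_true_urf()
  for (p in list(sw, pl)) {
    normals <- c(MAT = 2.6)
    ser <- constant_series(normals, 2000:2079)
    cv <- build_curve(p, tru, normals, ser, 2000, ages = 80)
    ht_c <- predict(tru, data.frame(MAT.p = 2.6, MAT.s = 2.6))
    si <- invert_site_index(p, ht_c, p$common_age)
    static <- evaluate_top_height(p, si, 1:80)
    expect_lt(max(abs(cv$heights - static)), 1e-9)
    expect_equal(unique(round(cv$si_profile, 9)), round(si, 9))
    expect_equal(site_index_at_50(cv), si, tolerance = 1e-9)
  }
})

warming_landscape_series <- function(trend, seed = 77, years = 2000:2079) {
  set.seed(seed)
  vals <- matrix(2 + trend * (years - years[1]), length(years), 1,
                 dimnames = list(NULL, "MAT"))
  climate_series("site", years, vals, c(MAT = 2))
}

test_that("warming shifts the curve in the direction of the URF's site response", {
  normals <- c(MAT = 2)
  warm <- warming_landscape_series(0.04)
  ncc <- constant_series(normals, 2000:2079)
  up <- simple_true_urf(alpha_site = 0.12, gamma_site = -0.01)
  down <- simple_true_urf(alpha_site = -0.12, gamma_site = -0.01)
  for (p in list(sw, pl)) {
    base_up <- build_curve(p, up, normals, ncc, 2000, ages = 80)$heights
    warm_up <- build_curve(p, up, normals, warm, 2000, ages = 80)$heights
    expect_true(all(warm_up >= base_up - 1e-12))
    base_dn <- build_curve(p, down, normals, ncc, 2000, ages = 80)$heights
    warm_dn <- suppressWarnings(
      build_curve(p, down, normals, warm, 2000, ages = 80)$heights)
    expect_true(all(warm_dn <= base_dn + 1e-12))
  }
})

test_that("curves are non-decreasing, bounded by the best static curve, and deterministic", {
  tru <- simple_true_urf()
  land <- independent_landscape(3, "MAT", seed = 19, n_years = 80,
                                warming = c(MAT = 0.03))
  ser <- land$series[[1]]
  normals <- point_normals(land, land$points$point_id[1])
  c1 <- build_curve(sw, tru, normals, ser, land$start_year, ages = 80)
  c2 <- build_curve(sw, tru, normals, ser, land$start_year, ages = 80)
  expect_identical(c1$heights, c2$heights)
  expect_true(all(diff(c1$heights) >= 0))
  bound <- evaluate_top_height(sw, max(c1$si_profile), 1:80)
  expect_true(all(c1$heights <= bound + 1e-9))
})

test_that("heights depend on site climate only through the running averages", {
  tru <- simple_true_urf()
  years <- 2000:2059
  set.seed(8)
  v <- 2 + rnorm(60, 0, 0.5)
  s_orig <- climate_series("s", years, matrix(v, ncol = 1,
                                              dimnames = list(NULL, "MAT")),
                           c(MAT = 2))
  # permuting years 1..30 leaves every lifespan average for ages >= 30
  # unchanged and changes earlier ones; ages beyond 30 must agree
  v2 <- c(v[30:1], v[31:60])
  s_perm <- climate_series("s", years, matrix(v2, ncol = 1,
                                              dimnames = list(NULL, "MAT")),
                           c(MAT = 2))
  a <- build_curve(sw, tru, c(MAT = 2), s_orig, 2000, ages = 60)
  b <- build_curve(sw, tru, c(MAT = 2), s_perm, 2000, ages = 60)
  expect_equal(a$si_profile[30:60], b$si_profile[30:60], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(a$si_profile[1:10], b$si_profile[1:10])))
})

test_that("later climate cannot affect the age-50 site index", {
  tru <- simple_true_urf()
  years <- 2000:2079
  base <- 2 + 0.02 * (years - 2000)
  mk <- function(tail_shift) {
    v <- base
    v[52:80] <- v[52:80] + tail_shift
    climate_series("s", years, matrix(v, ncol = 1,
                                      dimnames = list(NULL, "MAT")),
                   c(MAT = 2))
  }
  a <- build_curve(sw, tru, c(MAT = 2), mk(0), 2000, ages = 80)
  b <- build_curve(sw, tru, c(MAT = 2), mk(1.5), 2000, ages = 80)
  expect_identical(site_index_at_50(a), site_index_at_50(b))
  expect_identical(a$heights[1:50], b$heights[1:50])
})

test_that("inversion failures and short curves raise informative errors", {
  tru <- simple_true_urf()
  huge <- urf_model(tru$spec, setNames(c(20, 0, 0, 0, 0, 0),
                                       build_terms(tru$spec)))
  ser <- constant_series(c(MAT = 2), 2000:2039)
  expect_error(build_curve(sw, huge, c(MAT = 2), ser, 2000, ages = 10),
               "inversion failed at age")
  short <- build_curve(sw, tru, c(MAT = 2), ser, 2000, ages = 20)
  expect_error(site_index_at_50(short), ">= 50")
  expect_error(build_curve(sw, tru, c(MAP = 400), ser, 2000, ages = 5),
               "missing variable")
})

test_that("smoothing produces monotone-trend climates inside the curve", {
  tru <- simple_true_urf()
  land <- independent_landscape(2, "MAT", seed = 23, n_years = 80,
                                warming = c(MAT = 0.04))
  ser <- land$series[[1]]
  cs <- build_curve(sw, tru, point_normals(land, land$points$point_id[1]), ser, land$start_year,
                    ages = 80, smooth = TRUE)
  cr <- build_curve(sw, tru, point_normals(land, land$points$point_id[1]), ser, land$start_year,
                    ages = 80, smooth = FALSE)
  # smoothed per-age site indices follow a monotone path; raw ones fluctuate
  expect_true(all(diff(cs$si_profile) > -1e-9))
  expect_gt(max(abs(cs$si_profile - cr$si_profile)), 0)
  expect_equal(cs$heights[80], cr$heights[80], tolerance = 0.5)
})
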