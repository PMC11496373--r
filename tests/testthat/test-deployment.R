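deploy_fixture <- function(seed = 55, n = 8, warming = c(MAT = 0.03),
                           annual_sd = c(MAT = 0), in_range_prob = 1) {
  land <- independent_landscape(n, "MAT", seed = seed, n_years = 60,
                                warming = warming, annual_sd = annual_sd)
  if (in_range_prob < 1) {
    set.seed(seed + 1)
    land$points$in_range <- runif(n) < in_range_prob
  }
  land
}

test_that("a no-change scenario yields exactly zero site-index difference", {
  land <- deploy_fixture(warming = c(MAT = 0), annual_sd = c(MAT = 0))
  tru <- simple_true_urf()
  rec <- map_local_si(land, tru, sw, scenario = "ncc")
  expect_true(all(rec$si_dif == 0))
  expect_identical(nrow(rec), 8L)
})

test_that("warming raises local site index when the URF increases in site climate", {
  land <- deploy_fixture()
  up <- simple_true_urf(alpha_site = 0.12, gamma_site = -0.01)
  rec <- map_local_si(land, up, sw, scenario = "warm")
  expect_true(all(rec$si_dif > 0))
})

test_that("out-of-range points are skipped and ordering does not matter", {
  land <- deploy_fixture(in_range_prob = 0.6)
  tru <- simple_true_urf()
  expect_message(rec <- map_local_si(land, tru, sw), "skipping")
  expect_identical(sort(rec$point_id),
                   sort(land$points$point_id[land$points$in_range]))
  land_rev <- land
  land_rev$points <- land$points[rev(seq_len(nrow(land$points))), ]
  rec_rev <- suppressMessages(map_local_si(land_rev, tru, sw))
  key <- order(rec$point_id)
  key_rev <- order(rec_rev$point_id)
  expect_equal(rec[key, c("si_local", "si_dif")],
               rec_rev[key_rev, c("si_local", "si_dif")],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("optimal selection matches an independent brute-force loop", {
  land <- deploy_fixture(n = 6)
  tru <- simple_true_urf()
  cand <- lapply(seq(-1, 3, length.out = 20), function(m) c(MAT = m))
  ser <- land$series[[1]]
  local <- point_normals(land, land$points$point_id[1])
  sel <- select_optimal_population(local, ser, cand, tru, sw,
                                   land$start_year)
  # brute force, written independently of the implementation
  si_all <- numeric(20)
  for (i in 1:20) {
    cv <- build_curve(sw, tru, cand[[i]], ser, land$start_year, ages = 50)
    si_all[i] <- cv$heights[50]
  }
  expect_identical(sel$best, which.max(si_all))
  expect_equal(sel$si_opt, max(si_all), tolerance = 1e-12)
  expect_equal(sel$si_imp, max(si_all) - sel$si_local, tolerance = 1e-12)
})

test_that("the local provenance in the candidate set guarantees non-negative improvement", {
  land <- deploy_fixture(n = 5, seed = 91)
  tru <- simple_true_urf()
  for (i in 1:5) {
    id <- land$points$point_id[i]
    cand <- c(list(point_normals(land, id)),
              lapply(c(0.5, 1.5, 2.5), function(m) c(MAT = m)))
    sel <- select_optimal_population(point_normals(land, id), land$series[[id]],
                                     cand, tru, sw, land$start_year)
    expect_gte(sel$si_imp, 0)
  }
  # candidates = {local} only: improvement is exactly zero
  id <- land$points$point_id[1]
  only <- select_optimal_population(point_normals(land, id), land$series[[id]],
                                    list(point_normals(land, id)), tru, sw,
                                    land$start_year)
  expect_identical(only$si_imp, 0)
  expect_identical(only$si_opt, only$si_local)
})

test_that("the chosen candidate sits nearest the analytic provenance optimum", {
  # no interaction: the provenance effect is a pure quadratic in z with
  # argmax z* = alpha / (2 gamma); candidates on a z grid must pick the
  # grid point closest to it
  alpha <- 0.10; gamma <- 0.04
  tru <- standardized_true_urf("MAT", "MAT", c(MAT = 2), c(MAT = 1.2),
                               alpha_prov = alpha, gamma_prov = -gamma,
                               alpha_site = 0.05, gamma_site = -0.02,
                               log_center = log(9))
  z_star <- alpha / (2 * gamma)
  z_grid <- seq(-2, 3, by = 0.25)
  cand <- lapply(z_grid, function(z) c(MAT = 2 + 1.2 * z))
  ser <- constant_series(c(MAT = 2.3), 2000:2059)
  sel <- select_optimal_population(c(MAT = 2), ser, cand, tru, sw, 2000)
  expect_identical(sel$best, which.min(abs(z_grid - z_star)))
})

test_that("scanning a mapped landscape fills improvements and flags extrapolation", {
  land <- deploy_fixture(n = 10, seed = 13)
  tru <- simple_true_urf()
  rec <- map_local_si(land, tru, sw, scenario = "warm")
  rec <- map_optimal_si(rec, land, tru, sw, n_candidates = 10, seed = 2)
  # every in-range candidate pool contains the local provenance, so
  # improvement is non-negative everywhere
  expect_true(all(rec$si_imp >= -1e-12))
  expect_true(all(!is.na(rec$si_opt)))
  out <- apply_extrapolation_exclusion(rec)
  expect_true(all(out$excluded == (out$si_opt > 25)))
  # strict threshold boundary
  fake <- data.frame(si_opt = c(25, 25.01, 10), excluded = FALSE)
  flagged <- apply_extrapolation_exclusion(fake)
  expect_identical(flagged$excluded, c(FALSE, TRUE, FALSE))
  expect_identical(nrow(flagged), 3L)
  expect_error(apply_extrapolation_exclusion(data.frame(x = 1)), "si_opt")
})
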