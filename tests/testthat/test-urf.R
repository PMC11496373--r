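test_that("candidate counts reproduce the published pool combinatorics", {
  expect_identical(count_candidates(14, 17), 390677)
  expect_identical(count_candidates(11, 11), 53361)
  expect_identical(count_candidates(1, 1, max_per_side = 1), 1)
})

test_that("enumeration length matches the count for all pool sizes up to six", {
  for (np in 3:6) {
    for (ns in 3:6) {
      specs <- enumerate_urf_specs(paste0("p", 1:np), paste0("s", 1:ns))
      # pool labels are placeholders, so bypass the registry via counting only
      expect_identical(length(specs), as.integer(count_candidates(np, ns)))
      cats <- vapply(specs, function(s) attr(s, "category"), "")
      expect_identical(length(unique(cats)), 9L)
    }
  }
  # pools of size 3 per side: (C(3,1)+C(3,2)+C(3,3))^2 = 49
  expect_identical(length(enumerate_urf_specs(letters[1:3], letters[4:6])), 49L)
})

test_that("enumeration order is deterministic", {
  a <- enumerate_urf_specs(c("MAT", "TD", "CMD"), c("MAP", "DD5"))
  b <- enumerate_urf_specs(c("MAT", "TD", "CMD"), c("MAP", "DD5"))
  expect_identical(a, b)
  expect_identical(a[[1]]$prov_vars, "MAT")
  expect_identical(a[[1]]$site_vars, "MAP")
})

test_that("term lists follow the exponentiated-quadratic structure", {
  t5 <- build_terms(urf_spec("MAT", "DD5", include_intercept = FALSE))
  expect_identical(t5, c("MAT.p", "DD5.s", "MAT.p^2", "DD5.s^2", "MAT.p:DD5.s"))
  t22 <- build_terms(urf_spec(c("a", "b", "c"), c("d", "e", "f")))
  expect_identical(length(t22), 22L)  # 1 + 6 + 6 + 9
  t8 <- build_terms(urf_spec(c("a", "b"), "d", include_intercept = FALSE))
  expect_identical(length(t8), 8L)   # 2 + 1 + 2 + 1 + 2
  expect_false(any(grepl("\\.p:[^ ]*\\.p|\\.s:[^ ]*\\.s", t22)))
  expect_error(urf_spec(c("a", "a"), "b"), "duplicated")
  expect_error(urf_spec(character(0), "b"), "1-3")
})

make_fit_data <- function(n, beta, spec, seed = 3, sd_log = 0) {
  set.seed(seed)
  d <- data.frame(MAT.p = rnorm(n, 2, 1.2), DD5.s = rnorm(n, 1300, 150))
  X <- climurf:::urf_design(spec, d)
  d$top_height <- exp(as.vector(X %*% beta[colnames(X)]) +
                        rnorm(n, 0, sd_log))
  d
}

test_that("noiseless data are fitted exactly; degenerate heights get r2 = 0", {
  spec <- urf_spec("MAT", "DD5")
  beta <- setNames(c(1.2, 0.1, 0.002, -0.02, -8e-7, -1e-5), build_terms(spec))
  d <- make_fit_data(100, beta, spec)
  fit <- fit_urf(spec, d)
  expect_lt(max(abs(fit$coefficients - beta[names(fit$coefficients)])), 1e-6)
  expect_equal(fit$r2, 1.0, tolerance = 1e-9)
  expect_equal(predict(fit, d), d$top_height, tolerance = 1e-6)

  d$top_height <- 7.5
  fit0 <- fit_urf(spec, d)
  expect_identical(fit0$r2, 0)
  expect_equal(predict(fit0, d[1, ]), 7.5, tolerance = 1e-8)

  d2 <- make_fit_data(50, beta, spec)
  d2$MAT.p <- 1  # constant provenance column -> collinear with intercept
  fitc <- fit_urf(spec, d2)
  expect_true(fitc$collinear)
  expect_error(predict(fitc, d2), "collinear")
})

test_that("nonlinear refinement converges to the screening optimum on clean data", {
  spec <- urf_spec("MAT", "DD5")
  beta <- setNames(c(1.2, 0.1, 0.002, -0.02, -8e-7, -1e-5), build_terms(spec))
  d <- make_fit_data(200, beta, spec, seed = 8, sd_log = 0.02)
  fit <- fit_urf(spec, d, refine = TRUE)
  expect_true(fit$refined)
  scr <- fit_urf(spec, d)
  # refinement minimises original-scale SSE, so it cannot do worse there
  sse <- function(f) sum((d$top_height - predict(f, d))^2)
  expect_lte(sse(fit), sse(scr) + 1e-8)
})

test_that("coefficient bias stays within Monte-Carlo error over replicates", {
  spec <- urf_spec("MAT", "DD5")
  beta <- setNames(c(1.2, 0.1, 0.002, -0.02, -8e-7, -1e-5), build_terms(spec))
  base <- make_fit_data(500, beta, spec, seed = 12)
  true_h <- base$top_height
  reps <- 50
  est <- matrix(NA_real_, reps, length(beta), dimnames = list(NULL, names(beta)))
  set.seed(99)
  for (r in seq_len(reps)) {
    base$top_height <- true_h * exp(rnorm(nrow(base), 0, 0.05))
    est[r, ] <- fit_urf(spec, base)$coefficients[names(beta)]
  }
  bias <- colMeans(est) - beta
  mcse <- apply(est, 2, sd) / sqrt(reps)
  expect_true(all(abs(bias) < 2 * mcse + 1e-12))
})

test_that("EF and RMSEP reproduce their closed forms", {
  expect_identical(prediction_efficiency(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_identical(prediction_efficiency(c(1, 2, 3), rep(2, 3)), 0)
  expect_equal(prediction_efficiency(c(1, 2, 3), c(1, 2, 5)), -1.0,
               tolerance = 1e-12)
  expect_error(prediction_efficiency(c(2, 2), c(1, 2)), "identical")
  expect_error(prediction_efficiency(1, 1), "length")
  expect_identical(rmsep(c(1, 2), c(1, 2)), 0)
  expect_equal(rmsep(c(3, 4), c(0, 0)), sqrt(25 / 2), tolerance = 1e-12)
  r <- c(0.3, -0.8, 1.1)
  expect_equal(rmsep(2 * r, rep(0, 3)), 2 * rmsep(r, rep(0, 3)),
               tolerance = 1e-12)
})

test_that("selection is deterministic, fold-complete, and row-order invariant", {
  st <- recovery_setting(seed = 301, n_sites = 12, n_pops = 10)
  s1 <- select_urf(st$tab, st$prov_pool, st$site_pool, seed = 5)
  s2 <- select_urf(st$tab, st$prov_pool, st$site_pool, seed = 5)
  expect_identical(s1$summary, s2$summary)
  shuffled <- st$tab[sample(nrow(st$tab)), ]
  s3 <- select_urf(shuffled, st$prov_pool, st$site_pool, seed = 5)
  expect_equal(s3$summary, s1$summary, tolerance = 1e-12)
  expect_identical(nrow(s1$summary), 9L)
  # single-variable pools collapse to one category and that spec is final
  one <- select_urf(st$tab, "MAT", "MAT", seed = 5)
  expect_identical(nrow(one$summary), 1L)
  expect_identical(one$final$spec$prov_vars, "MAT")
})

test_that("selection recovers the true variables under small noise", {
  hits <- 0L
  for (seed in 1:5) {
    st <- recovery_setting(seed = 400 + seed)
    sel <- select_urf(st$tab, st$prov_pool, st$site_pool, seed = seed)
    ok <- all(c("MAT", "TD") %in% sel$final$spec$prov_vars) &&
      all(c("MAT", "MAP") %in% sel$final$spec$site_vars)
    hits <- hits + ok
  }
  expect_gte(hits, 3L)
})
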