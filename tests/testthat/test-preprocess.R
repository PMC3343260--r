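test_that("residualisation solves the normal equations", {
  # hand-derived: regressing (1,2,3,4) on x = (0,0,1,1) leaves +-1/2
  r <- residualize(c(1, 2, 3, 4), data.frame(x = c(0, 0, 1, 1)))
  expect_equal(r$residuals, c(-0.5, 0.5, -0.5, 0.5))
  expect_equal(unname(r$coefficients), c(1.5, 2.0))
  # intercept-only = centring
  r0 <- residualize(c(3, 1, 5, 7), NULL)
  expect_equal(r0$residuals, c(3, 1, 5, 7) - 4)
  # residuals orthogonal to covariates, mean zero
  set.seed(8)
  X <- data.frame(a = rnorm(50), b = runif(50), c = rbinom(50, 1, .3))
  y <- rnorm(50)
  rr <- residualize(y, X)
  expect_lt(abs(mean(rr$residuals)), 1e-12)
  for (cl in X) expect_lt(abs(sum(rr$residuals * cl)), 1e-8 * sd(y) * 50)
})

test_that("rank-deficient designs are rejected with the offending columns", {
  X <- data.frame(a = 1:6, b = 2 * (1:6))
  expect_error(residualize(rnorm(6), X), "collinear.*b")
  expect_error(residualize(rnorm(3), data.frame(a = rnorm(3))),
               "at least")
})

test_that("quantile binning splits distinct values evenly", {
  qb <- quantile_bin(sample(10), 5)
  expect_identical(qb$spec$counts, rep(2L, 5))
  expect_identical(sort(unique(qb$category)), 1:5)
  expect_identical(length(qb$spec$cutpoints), 4L)
  expect_error(quantile_bin(rep(c(1, 2), 10), 5), "degenerate")
})

test_that("ties at a cutpoint all fall in the lower class, deterministically", {
  # mass point at 5 straddles the middle quintile boundary; enumerating the
  # tie rule by hand: cutpoints are the type-1 quantiles (2, 4, 5, 8) and all
  # three 5s drop into class 3, giving counts (2, 2, 3, 1, 2)
  x <- c(1, 2, 3, 4, 5, 5, 5, 8, 9, 10)
  qb <- quantile_bin(x, 5)
  expect_identical(qb$spec$cutpoints, c(2, 4, 5, 8))
  expect_identical(qb$category, c(1L, 1L, 2L, 2L, 3L, 3L, 3L, 4L, 5L, 5L))
  expect_identical(qb$spec$counts, c(2L, 2L, 3L, 1L, 2L))
  # a mass point swallowing two quantile boundaries cannot give k classes
  expect_error(quantile_bin(c(1, 2, rep(5, 7), 9), 5), "degenerate")
})

test_that("binning is monotone and affine-invariant", {
  set.seed(5)
  x <- rnorm(500)
  qb <- quantile_bin(x, 5)
  o <- order(x)
  expect_true(all(diff(qb$category[o]) >= 0))
  qb2 <- quantile_bin(3.7 * x - 11, 5)
  expect_identical(qb$category, qb2$category)
})

test_that("with no confounding, raw and residualised categories almost always agree", {
  # regressing on unrelated covariates is a near no-op: the only perturbation
  # is OLS estimation noise (five fitted parameters, two covariates constant
  # within pairs), which relocates ~1-2% of records across a quintile
  # boundary at this sample size
  d <- simulate_twins(cerebrum_paths(), 5000, 0, seed = 61)
  raw <- quantile_bin(d$bv, 5)$category
  prep <- prep_bv(d, k = 5)
  expect_gte(mean(raw == prep$bv_cat), 0.98)
  # with the no-op exact (zero coefficients), agreement is total
  res0 <- residualize(d$bv, NULL)
  expect_identical(quantile_bin(res0$residuals, 5)$category, raw)
})

test_that("real confounding is removed by residualisation", {
  d <- simulate_twins(cerebrum_paths(), 4000, 0, seed = 62,
                      covariate_effects = c(icv = 0.8, site = -0.5))
  prep <- prep_bv(d, k = 5)
  res <- residualize(d$bv, data.frame(icv = d$icv,
                                      site = d$site == "Helsinki"))
  expect_gt(cor(res$residuals, d$lat_bv), 0.99)
  # residualised categories track the latent volume better than raw ones
  raw_cat <- quantile_bin(d$bv, 5)$category
  lat_cat <- quantile_bin(d$lat_bv, 5)$category
  expect_gt(mean(prep$bv_cat == lat_cat), mean(raw_cat == lat_cat))
})
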