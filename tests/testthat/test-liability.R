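test_that("prevalence threshold matches the inverse normal", {
  expect_identical(threshold_from_prevalence(0.5), 0)
  expect_equal(threshold_from_prevalence(0.01), 2.3263, tolerance = 1e-4)
  expect_equal(threshold_from_prevalence(0.1587), 1.00, tolerance = 1e-3)
  expect_error(threshold_from_prevalence(0), "strictly in")
  expect_error(threshold_from_prevalence(1), "strictly in")
})

test_that("bivariate rectangle probabilities match closed forms and quadrature", {
  expect_equal(bvn_rect(0, c(0, 0), c(Inf, Inf)), 0.25, tolerance = 1e-14)
  expect_equal(bvn_rect(0.5, c(0, 0), c(Inf, Inf)),
               0.25 + asin(0.5) / (2 * pi), tolerance = 1e-12)
  expect_equal(bvn_rect(0.9, c(-Inf, -Inf), c(Inf, Inf)), 1)
  expect_error(bvn_rect(0, c(1, 0), c(0, 1)), "lower bounds")
  # against the independent integrate-based oracle, incl. near-singular r
  for (r in c(-0.99, -0.95, -0.6, 0, 0.3, 0.75, 0.92, 0.99)) {
    for (b in list(c(-1.2, 0.4, -0.5, 2.0), c(0.5, 3, -4, -0.5),
                   c(-Inf, 1.1, 0.2, Inf))) {
      expect_equal(bvn_rect(r, b[c(1, 3)], b[c(2, 4)]),
                   bvn_rect_oracle(r, b[c(1, 3)], b[c(2, 4)]),
                   tolerance = 1e-10)
    }
  }
})

test_that("4-D rectangle probabilities match independence, products and a grid oracle", {
  expect_equal(mvn_rect(diag(4), rep(0, 4), rep(Inf, 4)), 0.0625,
               tolerance = 1e-12)
  # two independent bivariate blocks multiply
  Rb <- diag(4); Rb[1, 2] <- Rb[2, 1] <- 0.5; Rb[3, 4] <- Rb[4, 3] <- 0.5
  expect_equal(mvn_rect(Rb, rep(0, 4), rep(Inf, 4)),
               (0.25 + asin(0.5) / (2 * pi))^2, tolerance = 1e-10)
  expect_equal(mvn_rect(Rb, rep(-Inf, 4), rep(Inf, 4)), 1)
  # dense correlation, finite box, brute-force tensor-grid oracle
  R <- matrix(c(1, -.22, .92, -.17,
                -.22, 1, -.17, .76,
                .92, -.17, 1, -.22,
                -.17, .76, -.22, 1), 4, 4)
  lo <- c(-1, -1.5, -0.8, -2); hi <- c(1.5, 0.5, 2, 0.3)
  expect_equal(mvn_rect(R, lo, hi), mvn_rect_grid_oracle(R, lo, hi),
               tolerance = 1e-6)
  # half-infinite case via the bivariate-conditioning oracle route:
  # P(all > 0) for exchangeable r = .3 has a known series value; compare
  # instead to the oracle grid on the complementary finite box
  expect_error(mvn_rect(matrix(c(1, 2, 2, 1), 2), c(0, 0), c(1, 1)),
               "positive semi-definite")
  expect_error(mvn_rect(diag(4), rep(1, 4), rep(0, 4)), "lower bounds")
})

test_that("pair likelihood factorises under independence", {
  # all correlations zero: each pair cell probability is the product of four
  # marginal masses
  s <- correlation_structure(0, 0, 0, 0, 0, r_sz_mz = 0, r_sz_dz = 0)
  th <- threshold_set(0.3, qnorm(c(.25, .5, .75)))
  d <- small_cohort(60, 60, seed = 77, k = 4)
  d$affected <- as.integer(d$lat_sz > threshold_from_prevalence(0.3))
  ll <- pair_table_loglik(s, th, d)
  t_sz <- th$sz_threshold
  psz <- function(a) if (a == 1) pnorm(-t_sz) else pnorm(t_sz)
  brk <- c(-Inf, th$bv_thresholds, Inf)
  pbv <- function(k) pnorm(brk[k + 1]) - pnorm(brk[k])
  ll_ref <- sum(log(vapply(seq_len(nrow(d)), function(i)
    psz(d$affected[i]) * pbv(d$bv_cat[i]), numeric(1))))
  expect_equal(ll, ll_ref, tolerance = 1e-9)
})

test_that("pair likelihood is invariant to member relabelling", {
  d <- small_cohort(150, 150, seed = 78)
  s <- correlation_structure(-0.2, 0.7, 0.4, -0.15, -0.08)
  th <- threshold_set(0.01, qnorm(c(.2, .4, .6, .8)))
  swapped <- d
  swapped$member <- ifelse(d$member == 1, 2, 1)
  expect_equal(pair_table_loglik(s, th, d),
               pair_table_loglik(s, th, swapped), tolerance = 1e-10)
})

test_that("singletons contribute the marginal bivariate cell probability", {
  d <- small_cohort(80, 80, seed = 79)
  # drop member 2 of half the pairs
  drop <- d$member == 2 & d$pair_id <= 40
  dd <- d[!drop, ]
  s <- correlation_structure(-0.2, 0.7, 0.4, -0.15, -0.08)
  th <- threshold_set(0.01, qnorm(c(.2, .4, .6, .8)))
  ll_all <- pair_table_loglik(s, th, dd)
  ll_pairs <- pair_table_loglik(s, th, dd[dd$pair_id > 40, ])
  singles <- dd[dd$pair_id <= 40, ]
  t_sz <- th$sz_threshold
  brk <- c(-Inf, th$bv_thresholds, Inf)
  ll_singles <- sum(log(vapply(seq_len(nrow(singles)), function(i) {
    a <- singles$affected[i]; k <- singles$bv_cat[i]
    bvn_rect(s$r_within,
             c(if (a == 1) t_sz else -Inf, brk[k]),
             c(if (a == 1) Inf else t_sz, brk[k + 1]))
  }, numeric(1))))
  expect_equal(ll_all, ll_pairs + ll_singles, tolerance = 1e-8)
})

test_that("the binary-trait likelihood peaks where the tetrachoric grid oracle peaks", {
  # bivariate binary data as singleton records; only r_within is involved
  set.seed(55)
  n <- 1500
  r_true <- 0.45
  z1 <- rnorm(n); z2 <- r_true * z1 + sqrt(1 - r_true^2) * rnorm(n)
  t1 <- qnorm(0.7); t2 <- 0
  d <- data.frame(pair_id = seq_len(n), zygosity = rep(c("MZ", "DZ"), n / 2),
                  member = 1L, affected = as.integer(z1 > t1),
                  bv_cat = 1L + as.integer(z2 > t2))
  th <- threshold_set(0.3, t2)
  ll_pkg <- function(r) pair_table_loglik(
    correlation_structure(r, 0, 0, 0, 0), th, d)
  counts <- c(sum(d$affected == 0 & d$bv_cat == 1),
              sum(d$affected == 0 & d$bv_cat == 2),
              sum(d$affected == 1 & d$bv_cat == 1),
              sum(d$affected == 1 & d$bv_cat == 2))
  grid_peak <- function(f) {
    coarse <- seq(-0.95, 0.95, by = 0.01)
    v <- vapply(coarse, f, numeric(1))
    r0 <- coarse[which.max(v)]
    fine <- seq(r0 - 0.02, r0 + 0.02, by = 0.001)
    fine[which.max(vapply(fine, f, numeric(1)))]
  }
  r_pkg <- grid_peak(ll_pkg)
  r_oracle <- grid_peak(function(r) tetrachoric_ll_oracle(r, counts, t1, t2))
  expect_equal(r_pkg, r_oracle, tolerance = 1e-9)  # same grid, same peak
  expect_equal(r_pkg, r_true, tolerance = 0.1)     # sanity, not precision
})

test_that("the fixed disorder correlations never move", {
  d <- small_cohort(400, 400, seed = 81)
  fit <- twin_polychoric(d, control = fast_control)
  expect_identical(fit$structure$r_sz_mz, 0.92)
  expect_identical(fit$structure$r_sz_dz, 0.515)
  # and with overridden constants, those are preserved instead
  fit2 <- twin_polychoric(d, fix_sz_mz = 0.9, fix_sz_dz = 0.5,
                          control = fast_control)
  expect_identical(fit2$structure$r_sz_mz, 0.9)
  expect_identical(fit2$structure$r_sz_dz, 0.5)
})

test_that("profile CI endpoints sit at the chi-squared cutoff and bracket the estimate", {
  d <- small_cohort(700, 700, seed = 82)
  fit <- twin_polychoric(d)
  ci <- confint(fit, parm = "r_bv_mz")
  est <- fit$estimate["r_bv_mz"]
  expect_lt(ci[1, "lower"], est)
  expect_gt(ci[1, "upper"], est)
  # verify -2 delta lnL at the endpoints
  llmax <- fit$loglik
  for (v in ci[1, ]) {
    zfix <- atanh(v)
    inner <- function(q) fit$negll(append(q, zfix, after = 1))
    o <- optim(fit$par[-2], inner, method = "Nelder-Mead",
               control = list(maxit = 600, reltol = 1e-10))
    expect_equal(2 * (fit$negll(fit$par) * -1 - -o$value), qchisq(.95, 1),
                 tolerance = 0.01)
  }
})

test_that("estimates are stable under coarsening of the ordinal scale", {
  paths <- cerebrum_paths()
  d <- simulate_twins(paths, 10000, 10000, seed = 83)
  d5 <- prep_bv(d, k = 5, covariates = character(0))
  d2 <- prep_bv(d, k = 2, covariates = character(0))
  f5 <- twin_polychoric(d5, control = fast_control)
  f2 <- twin_polychoric(d2, control = fast_control)
  expect_lt(abs(f5$estimate["r_within"] - f2$estimate["r_within"]), 0.05)
})

test_that("null within-person correlation is covered by its interval", {
  paths <- twin_paths_from_components(0.76, 0, 0.24)   # r_g = r_e = 0
  hits <- 0
  for (i in 1:5) {
    d <- simulate_twins(paths, 700, 700, seed = 9000 + i)
    d <- prep_bv(d, k = 5, covariates = character(0))
    fit <- twin_polychoric(d, control = fast_control)
    ci <- confint(fit, parm = "r_within")
    if (ci[1, 1] <= 0 && 0 <= ci[1, 2]) hits <- hits + 1
  }
  expect_gte(hits, 4)
})
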