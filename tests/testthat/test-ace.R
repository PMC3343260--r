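test_that("standardisation identities hold for arbitrary paths", {
  set.seed(12)
  for (i in 1:25) {
    raw_sz <- rnorm(3); raw_bv <- rnorm(6)
    sz <- raw_sz / sqrt(sum(raw_sz^2)); bv <- raw_bv / sqrt(sum(raw_bv^2))
    p <- twin_paths(sz[1], sz[2], sz[3], bv[1], bv[2], bv[3],
                    bv[4], bv[5], bv[6])
    sol <- standardize(p)
    expect_equal(sol$h2_bv + sol$c2_bv + sol$e2_bv, 1, tolerance = 1e-8)
    expect_equal(sol$r_ph, sol$r_ph_a + sol$r_ph_c + sol$r_ph_e,
                 tolerance = 1e-8)
    expect_equal(sol$r_ph_a, sqrt(sol$h2_sz) * sol$r_g * sqrt(sol$h2_bv),
                 tolerance = 1e-8)
    expect_equal(sol$r_ph_c, sqrt(sol$c2_sz) * sol$r_c * sqrt(sol$c2_bv),
                 tolerance = 1e-8)
    expect_equal(sol$r_ph_e, sqrt(sol$e2_sz) * sol$r_e * sqrt(sol$e2_bv),
                 tolerance = 1e-8)
  }
})

test_that("degenerate components yield undefined correlations, zero contributions", {
  p <- twin_paths_from_components(0.5, 0, 0.5, r_g = 0, r_e = 0.3)
  sol <- standardize(p)
  expect_true(is.na(sol$r_c))
  expect_identical(sol$r_ph_c, 0)
  expect_identical(sol$r_g, 0)       # a_pc = 0 with a_s > 0
  expect_identical(sol$r_ph_a, 0)
})

test_that("worked decomposition arithmetic matches hand evaluation", {
  # direct evaluation of sqrt(h2_sz) * r_g * sqrt(h2_bv)
  expect_identical(round(sqrt(0.81) * (-0.21) * sqrt(0.76), 4), -0.1648)
  sol <- structure(list(r_ph = -0.22, r_ph_a = -0.17, r_ph_c = 0,
                        r_ph_e = -0.05), class = "twin_ace_solution")
  pr <- decompose_rph(sol)
  expect_equal(round(100 * pr[["genetic"]]), 77)
  expect_equal(sum(pr), 1, tolerance = 1e-8)
  sol2 <- structure(list(r_ph = 0.18, r_ph_a = 0.15, r_ph_c = 0,
                         r_ph_e = 0.03), class = "twin_ace_solution")
  expect_equal(round(100 * decompose_rph(sol2)[["genetic"]]), 83)
  # parts of opposite sign may exceed 1 / go negative, unclamped
  sol3 <- structure(list(r_ph = 0.1, r_ph_a = 0.3, r_ph_c = -0.25,
                         r_ph_e = 0.05), class = "twin_ace_solution")
  expect_equal(unname(decompose_rph(sol3)), c(3, -2.5, 0.5))
  sol0 <- structure(list(r_ph = 0, r_ph_a = 0, r_ph_c = 0, r_ph_e = 0),
                    class = "twin_ace_solution")
  expect_error(decompose_rph(sol0), "undefined")
})

test_that("variance explained is 100 r^2", {
  expect_equal(variance_explained(-0.22), 4.84)
  expect_identical(variance_explained(0), 0)
  expect_identical(variance_explained(1), 100)
  expect_error(variance_explained(1.2))
})

test_that("the ACE fit is invariant to swapping pair members", {
  d <- small_cohort(300, 300, seed = 201)
  swapped <- d
  swapped$member <- ifelse(d$member == 1, 2, 1)
  # the likelihood function itself is exactly member-symmetric (asserted in
  # the likelihood tests); the fitted optima agree to optimiser tolerance
  f1 <- twin_ace(d, control = fast_control)
  f2 <- twin_ace(swapped, control = fast_control)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-5)
  expect_lt(abs(pair_table_loglik(f1$structure, f1$thresholds, d) -
                  pair_table_loglik(f1$structure, f1$thresholds, swapped)),
            1e-6)
})

test_that("submodels nest and the self-comparison LRT is zero", {
  d <- small_cohort(500, 500, seed = 202)
  full <- twin_ace(d, control = fast_control)
  self <- fit_submodel(full, drop = character(0))
  expect_identical(self$df, 0L)
  expect_lt(abs(self$lrt), 1e-4)
  ae <- fit_submodel(full, drop = c("C_common", "C_specific"))
  expect_identical(ae$df, 2L)
  expect_lte(ae$fit$loglik, full$loglik + 1e-6)
  expect_error(twin_ace(d, model = "E", drop = c("A_common", "A_specific",
                                                 "C_common", "C_specific",
                                                 "E_common")),
               "not identified")
  expect_error(ace_ok <- fit_submodel(full, drop = "E_specific"),
               "never droppable")
})

test_that("AE is not rejected when the generating model has no C", {
  # generating c2 = 0: the AE restriction should rarely produce a large LRT
  ok <- 0
  for (i in 1:5) {
    d <- small_cohort(500, 500, seed = 300 + i)
    full <- twin_ace(d, control = fast_control)
    ae <- fit_submodel(full, drop = c("C_common", "C_specific"))
    if (ae$lrt < qchisq(0.95, 2)) ok <- ok + 1
  }
  expect_gte(ok, 4)
})

test_that("the genetic-correlation sign is recovered under the AE model", {
  ok <- 0
  for (i in 1:5) {
    d <- small_cohort(1200, 1200, seed = 400 + i)
    ae <- twin_ace(d, model = "AE", control = fast_control)
    if (ae$solution$r_g < 0) ok <- ok + 1
  }
  expect_gte(ok, 4)
})

test_that("null cross-trait paths are covered by their profile intervals", {
  paths <- twin_paths_from_components(0.76, 0, 0.24)   # no shared aetiology
  hits_g <- hits_e <- 0
  for (i in 1:4) {
    d <- simulate_twins(paths, 700, 700, seed = 500 + i)
    d <- prep_bv(d, k = 5, covariates = character(0))
    fit <- twin_ace(d, model = "AE", control = fast_control)
    ci <- confint(fit, parm = c("r_g", "r_e"))
    if (ci["r_g", 1] <= 0 && 0 <= ci["r_g", 2]) hits_g <- hits_g + 1
    if (ci["r_e", 1] <= 0 && 0 <= ci["r_e", 2]) hits_e <- hits_e + 1
  }
  expect_gte(hits_g, 3)
  expect_gte(hits_e, 3)
})

test_that("binary-endophenotype A-only fit agrees with the tetrachoric grid oracle", {
  # pure-A generating model, k = 2: the within-person correlation from the
  # constrained Cholesky fit should sit at the tetrachoric ML of the pooled
  # within-person table (computed by an independent grid search).  Member 2 is
  # dropped so both estimators see exactly the same information.
  paths <- twin_paths_from_components(0.76, 0, 0.24, r_g = -0.3, r_e = 0)
  d <- simulate_twins(paths, 4000, 4000, seed = 601)
  d <- prep_bv(d, k = 2, covariates = character(0))
  d <- d[d$member == 1, ]
  fit <- twin_ace(d, drop = c("C_common", "C_specific", "E_common"),
                  control = fast_control)
  t1 <- threshold_from_prevalence(0.01)
  t2 <- fit$thresholds$bv_thresholds[1]
  counts <- c(sum(d$affected == 0 & d$bv_cat == 1),
              sum(d$affected == 0 & d$bv_cat == 2),
              sum(d$affected == 1 & d$bv_cat == 1),
              sum(d$affected == 1 & d$bv_cat == 2))
  coarse <- seq(-0.9, 0.9, by = 0.01)
  v <- vapply(coarse, tetrachoric_ll_oracle, numeric(1), counts, t1, t2)
  r0 <- coarse[which.max(v)]
  fine <- seq(r0 - 0.02, r0 + 0.02, by = 0.001)
  r_grid <- fine[which.max(vapply(fine, tetrachoric_ll_oracle, numeric(1),
                                  counts, t1, t2))]
  expect_lt(abs(fit$structure$r_within - r_grid), 1e-2)
})

test_that("simulate() round-trips a fitted model", {
  d <- small_cohort(400, 400, seed = 202)
  fit <- twin_ace(d, control = fast_control)
  sim <- simulate(fit, seed = 1, n_mz = 200, n_dz = 100)
  expect_identical(sum(sim$zygosity == "MZ"), 400L)
  expect_identical(sum(sim$zygosity == "DZ"), 200L)
  sim2 <- simulate(fit, seed = 1, n_mz = 200, n_dz = 100)
  expect_identical(sim, sim2)
})
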