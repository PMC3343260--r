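test_that("zero pairs give an empty dataset", {
  p <- twin_paths(0, 0, 1, 0, 0, 0, 0, 0, 1)
  d <- simulate_twins(p, 0, 0, seed = 1)
  expect_s3_class(d, "data.frame")
  expect_identical(nrow(d), 0L)
})

test_that("simulation is deterministic given a seed and leaves the RNG alone", {
  p <- cerebrum_paths()
  set.seed(999)
  before <- runif(1)
  set.seed(999)
  d1 <- simulate_twins(p, 50, 50, seed = 7)
  after <- runif(1)
  d2 <- simulate_twins(p, 50, 50, seed = 7)
  expect_identical(d1, d2)
  expect_identical(before, after)  # caller RNG state restored
})

test_that("empirical moments match the implied covariance", {
  p <- cerebrum_paths()
  d <- simulate_twins(p, 50000, 0, seed = 31)
  m1 <- d[d$member == 1, ]; m2 <- d[d$member == 2, ]
  expect_lt(abs(cor(m1$lat_bv, m2$lat_bv) - 0.76), 0.01)
  expect_lt(abs(cor(m1$lat_sz, m1$lat_bv) - -0.22), 0.01)
  expect_lt(abs(cor(m1$lat_sz, m2$lat_sz) - 0.92), 0.01)
  expect_lt(abs(sd(d$lat_bv) - 1), 0.01)
  # DZ sharing halves the A-driven part
  d2 <- simulate_twins(p, 0, 50000, seed = 32)
  m1 <- d2[d2$member == 1, ]; m2 <- d2[d2$member == 2, ]
  expect_lt(abs(cor(m1$lat_bv, m2$lat_bv) - 0.38), 0.01)
})

test_that("affected fraction matches the prevalence threshold", {
  p <- cerebrum_paths()
  d <- simulate_twins(p, 25000, 25000, prevalence = 0.01, seed = 17)
  expect_lt(abs(mean(d$affected) - 0.01), 0.002)
})

test_that("the bundled ascertainment frame reproduces the cohort margins", {
  f <- table1_frame()
  expect_identical(sum(f$n), 684L)
  expect_identical(sum(f$n[f$zygosity == "MZ"]), 410L)
  expect_identical(sum(f$n[f$zygosity == "DZ"]), 274L)
  expect_identical(sum(f$n_affected), 142L)
  # per-group affected splits
  expect_identical(sum(f$n_affected[f$group == "concordant"]), 51L)
  expect_identical(sum(f$n_affected[f$group == "discordant" &
                                      f$zygosity == "MZ"]), 52L)
  expect_identical(sum(f$n_affected[f$group == "discordant" &
                                      f$zygosity == "DZ"]), 39L)
  # spot cells
  expect_identical(f$n_unaffected[f$site == "Utrecht" & f$zygosity == "MZ" &
                                    f$group == "control"], 134L)
  expect_identical(f$n_affected[f$site == "London" & f$zygosity == "DZ" &
                                  f$group == "discordant"], 3L)
})

test_that("frame-based ascertainment fills every cell and is count-invariant across seeds", {
  p <- cerebrum_paths()
  pop <- simulate_twins(p, 40000, 20000, seed = 3)
  sel1 <- ascertain(pop, "table1_frame", seed = 11)
  sel2 <- ascertain(pop, "table1_frame", seed = 12)
  for (sel in list(sel1, sel2)) {
    expect_identical(nrow(sel), 684L)
    expect_identical(sum(sel$zygosity == "MZ"), 410L)
    expect_identical(sum(sel$zygosity == "DZ"), 274L)
    expect_identical(sum(sel$affected), 142L)
  }
  # different draws, same margins
  expect_false(identical(sort(sel1$pair_id), sort(sel2$pair_id)))
  # pairs are never split except into frame singletons: member counts per
  # pair_id at most 2
  expect_true(all(table(sel1$pair_id) <= 2))
})

test_that("proband ascertainment keeps affected pairs plus controls", {
  p <- cerebrum_paths()
  pop <- simulate_twins(p, 5000, 5000, seed = 23)
  sel <- ascertain(pop, "proband_plus_controls", n_control_pairs = 10,
                   seed = 5)
  aff_pairs <- tapply(sel$affected, sel$pair_id, sum)
  expect_identical(sum(aff_pairs == 0), 10L)
  pop_case_pairs <- sum(tapply(pop$affected, pop$pair_id, sum) >= 1)
  expect_identical(sum(aff_pairs >= 1), pop_case_pairs)
  # no affected individuals at all -> empty selection
  none <- pop[rep(tapply(pop$affected, pop$pair_id, sum) == 0, each = 2), ]
  sel0 <- ascertain(none, "proband_plus_controls", n_control_pairs = 0,
                    seed = 5)
  expect_identical(nrow(sel0), 0L)
})

test_that("an unsatisfiable frame names the exhausted cell", {
  p <- cerebrum_paths()
  pop <- simulate_twins(p, 200, 100, seed = 3)   # far too few concordant pairs
  expect_error(ascertain(pop, "table1_frame", seed = 1),
               "frame cell exhausted")
})
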