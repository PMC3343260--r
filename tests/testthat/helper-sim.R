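# Shared fixtures built in code.

# generating model used throughout recovery tests: cerebrum-like volume with
# h2 = .76, c2 = 0, e2 = .24 and factor correlations chosen so the implied
# within-person cross-trait correlation is exactly -.22
cerebrum_paths <- function() {
  r_g <- -0.21
  r_e <- (-0.22 - sqrt(0.81) * r_g * sqrt(0.76)) / (sqrt(0.08) * sqrt(0.24))
  twin_paths_from_components(0.76, 0, 0.24, r_g = r_g, r_e = r_e)
}

# small prepared dataset for fast fitting tests
small_cohort <- function(n_mz = 800, n_dz = 800, seed = 101,
                         paths = cerebrum_paths(), k = 5) {
  d <- simulate_twins(paths, n_mz, n_dz, seed = seed)
  prep_bv(d, k = k, covariates = character(0))
}

fast_control <- list(maxit = 300)
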