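#' Simulate a twin cohort under the bivariate liability model
#'
#' Draws MZ and DZ twin pairs from the 4-variate normal liability distribution
#' implied by a set of Cholesky paths (see [implied_cov()]).  Liabilities are
#' generated from explicit factor draws: one additive-genetic and one
#' common-environmental factor per trait shared within a pair (A shared fully
#' in MZ pairs, with correlation 0.5 in DZ pairs; C shared fully in both), and
#' unique-environmental factors per individual.  The disorder status is the
#' liability dichotomised at the threshold giving the requested population
#' prevalence.
#'
#' Covariates (site, sex, age, intracranial volume) are drawn independently of
#' the liabilities; optional linear `covariate_effects` add confounding to the
#' observed endophenotype so that covariate residualisation can be exercised
#' both as a no-op and as a real correction.  Sites are sampled with
#' probabilities proportional to the bundled ascertainment frame
#' ([table1_frame()]); sex is shared within MZ pairs and independent across DZ
#' co-twins; age is shared within a pair; intracranial volume has a shared and
#' an individual component.
#'
#' @param paths a [twin_paths()] object (or the nine paths in its order).
#' @param n_mz,n_dz numbers of MZ and DZ pairs.
#' @param prevalence population prevalence of the disorder, in (0, 1).
#' @param seed integer seed; the R default generator (Mersenne-Twister) is
#'   seeded once per call and the caller's RNG state is restored on exit.
#' @param covariate_effects named numeric vector with any of `site`, `sex`,
#'   `age`, `icv`: linear effects added to the observed endophenotype.
#'   Default none.
#' @return A `data.frame` with one row per individual: `pair_id`, `zygosity`,
#'   `member`, `affected`, `bv` (observed continuous endophenotype), `bv_cat`
#'   (`NA` until [prep_bv()] is run), covariates `site`, `sex`, `age`, `icv`,
#'   and ground-truth latent values (`lat_sz`, `lat_bv` and the six factor
#'   draws, prefixed `f_`) for parameter-recovery testing.
#' @export
#' @examples
#' p <- twin_paths_from_components(.76, 0, .24, r_g = -.21, r_e = -.40)
#' d <- simulate_twins(p, n_mz = 100, n_dz = 100, seed = 1)
#' mean(d$affected)
simulate_twins <- function(paths, n_mz, n_dz, prevalence = 0.01, seed = NULL,
                           covariate_effects = NULL) {
  if (!inherits(paths, "twin_paths"))
    paths <- do.call(twin_paths, as.list(paths))
  stopifnot(n_mz >= 0, n_dz >= 0, prevalence > 0, prevalence < 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed))
  }
  n_pairs <- n_mz + n_dz
  if (n_pairs == 0) return(empty_twin_frame())
  zyg <- rep(c("MZ", "DZ"), c(n_mz, n_dz))
  alpha <- ifelse(zyg == "MZ", 1, 0.5)
  p <- as.list(paths)
  t_sz <- threshold_from_prevalence(prevalence)

  # pair-level shared factor draws; DZ A-factors: sqrt(.5) shared + sqrt(.5) own
  draw_A <- function() {
    shared <- rnorm(n_pairs)
    own1 <- rnorm(n_pairs); own2 <- rnorm(n_pairs)
    w <- sqrt(alpha)
    cbind(w * shared + sqrt(1 - alpha) * own1,
          w * shared + sqrt(1 - alpha) * own2)
  }
  A1 <- draw_A(); A2 <- draw_A()
  C1 <- rnorm(n_pairs); C2 <- rnorm(n_pairs)      # shared both zygosities
  E1 <- cbind(rnorm(n_pairs), rnorm(n_pairs))
  E2 <- cbind(rnorm(n_pairs), rnorm(n_pairs))

  lat_sz <- p$a_c * A1 + p$c_c * C1 + p$e_c * E1
  lat_bv <- p$a_pc * A1 + p$c_pc * C1 + p$e_pc * E1 +
            p$a_s * A2 + p$c_s * C2 + p$e_s * E2

  # covariates
  sites <- c("Helsinki", "Jena", "London", "Utrecht")
  fr <- table1_frame()
  site_n <- vapply(sites, function(s) sum(fr$n[fr$site == s]), numeric(1))
  site <- sample(sites, n_pairs, replace = TRUE, prob = site_n / sum(site_n))
  sex_pair <- rbinom(n_pairs, 1, 0.5)
  sex2 <- ifelse(zyg == "MZ", sex_pair, rbinom(n_pairs, 1, 0.5))
  age <- rnorm(n_pairs, 38, 11.3)
  icv_sh <- rnorm(n_pairs, 0, sqrt(0.8))
  icv <- cbind(icv_sh + rnorm(n_pairs, 0, sqrt(0.2)),
               icv_sh + rnorm(n_pairs, 0, sqrt(0.2)))

  eff <- c(site = 0, sex = 0, age = 0, icv = 0)
  if (!is.null(covariate_effects)) {
    stopifnot(all(names(covariate_effects) %in% names(eff)))
    eff[names(covariate_effects)] <- covariate_effects
  }
  mk_member <- function(m) {
    sx <- if (m == 1) sex_pair else sex2
    bv_obs <- lat_bv[, m] +
      eff["site"] * (site == "Helsinki") + eff["sex"] * sx +
      eff["age"] * (age - 38) / 11.3 + eff["icv"] * icv[, m]
    data.frame(pair_id = seq_len(n_pairs), zygosity = zyg, member = m,
               affected = as.integer(lat_sz[, m] > t_sz),
               bv = unname(bv_obs), bv_cat = NA_integer_,
               site = site, sex = sx, age = age, icv = icv[, m],
               lat_sz = lat_sz[, m], lat_bv = lat_bv[, m],
               f_a1 = A1[, m], f_c1 = C1, f_e1 = E1[, m],
               f_a2 = A2[, m], f_c2 = C2, f_e2 = E2[, m])
  }
  out <- rbind(mk_member(1), mk_member(2))
  out <- out[order(out$pair_id, out$member), ]
  rownames(out) <- NULL
  out
}

empty_twin_frame <- function() {
  data.frame(pair_id = integer(), zygosity = character(), member = integer(),
             affected = integer(), bv = numeric(), bv_cat = integer(),
             site = character(), sex = integer(), age = numeric(),
             icv = numeric(), lat_sz = numeric(), lat_bv = numeric(),
             f_a1 = numeric(), f_c1 = numeric(), f_e1 = numeric(),
             f_a2 = numeric(), f_c2 = numeric(), f_e2 = numeric())
}

#' Multi-site ascertainment frame of the pooled twin cohort design
#'
#' Returns the per-site cell counts of the pooled schizophrenia twin cohort:
#' numbers of affected and unaffected individuals by site, zygosity and group
#' (concordant-affected, discordant, healthy-control).  Patient and co-twin
#' counts disagree in some discordant cells (and some control counts are odd),
#' which implies singletons: individuals whose co-twin was not scanned.
#' Total 684 individuals (410 MZ, 274 DZ, 142 affected).
#'
#' @return A `data.frame` with columns `site`, `zygosity`, `group`
#'   (`"concordant"`, `"discordant"`, `"control"`), `n_affected`,
#'   `n_unaffected` and `n` (their sum).
#' @export
#' @examples
#' sum(table1_frame()$n)   # 684
table1_frame <- function() {
  f <- read.csv(text =
"site,zygosity,group,n_affected,n_unaffected
Helsinki,MZ,concordant,13,0
Helsinki,MZ,discordant,14,15
Helsinki,MZ,control,0,48
Helsinki,DZ,discordant,23,23
Helsinki,DZ,control,0,50
Jena,MZ,discordant,11,11
Jena,MZ,control,0,16
London,MZ,concordant,38,0
London,MZ,discordant,14,17
London,MZ,control,0,53
London,DZ,discordant,3,3
London,DZ,control,0,4
Utrecht,MZ,discordant,13,13
Utrecht,MZ,control,0,134
Utrecht,DZ,discordant,13,13
Utrecht,DZ,control,0,142
", stringsAsFactors = FALSE)
  f$n <- f$n_affected + f$n_unaffected
  f
}

#' Ascertain twin pairs by disease status
#'
#' Selects records from a simulated (or observed) population according to an
#' ascertainment scheme.  Selection is pair-wise: a pair is never split except
#' where a frame cell specifies singletons, in which case one member of an
#' additionally drawn pair of the required concordance type is kept.
#'
#' @param records long-format twin data as returned by [simulate_twins()].
#' @param scheme `"population"` (no selection), `"proband_plus_controls"`
#'   (every pair with at least one affected member plus control pairs), or
#'   `"table1_frame"` (fill the cell counts of `frame` by sampling without
#'   replacement).
#' @param frame ascertainment frame (default [table1_frame()]); used by the
#'   `table1_frame` scheme.
#' @param n_control_pairs number of fully unaffected pairs kept under
#'   `proband_plus_controls`; default scales the number of case pairs by the
#'   control:case pair ratio of the bundled frame.
#' @param seed integer seed for the sampling.
#' @return Selected records, with columns `group` (ascertainment cell) and,
#'   for the frame scheme, `site` reassigned from the frame.
#' @export
ascertain <- function(records,
                      scheme = c("population", "proband_plus_controls",
                                 "table1_frame"),
                      frame = table1_frame(), n_control_pairs = NULL,
                      seed = NULL) {
  scheme <- match.arg(scheme)
  if (scheme == "population") return(records)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed))
  }
  if (nrow(records) == 0) return(records)
  # pair-level summary (pairs only; pre-existing singletons treated as pairs of 1)
  aff_by_pair <- tapply(records$affected, records$pair_id, sum)
  size_by_pair <- tapply(records$affected, records$pair_id, length)
  zyg_by_pair <- tapply(as.character(records$zygosity), records$pair_id, `[`, 1)
  pid <- as.numeric(names(aff_by_pair))

  if (scheme == "proband_plus_controls") {
    case_ids <- pid[aff_by_pair >= 1]
    ctrl_ids <- pid[aff_by_pair == 0 & size_by_pair == 2]
    if (is.null(n_control_pairs)) {
      f <- frame
      hc <- sum(f$n_unaffected[f$group == "control"]) %/% 2
      cc <- sum(floor(f$n_affected[f$group == "concordant"] / 2)) +
        sum(pmin(f$n_affected[f$group == "discordant"],
                 f$n_unaffected[f$group == "discordant"]))
      n_control_pairs <- round(length(case_ids) * hc / max(cc, 1))
    }
    n_control_pairs <- min(n_control_pairs, length(ctrl_ids))
    keep <- c(case_ids,
              if (n_control_pairs > 0) sample(ctrl_ids, n_control_pairs))
    out <- records[records$pair_id %in% keep, ]
    out$group <- ifelse(aff_by_pair[as.character(out$pair_id)] >= 1,
                        "case", "control")
    rownames(out) <- NULL
    return(out)
  }

  # table1_frame scheme: fill each cell without replacement
  complete <- pid[size_by_pair == 2]
  pools <- list(
    MZ_concordant = complete[zyg_by_pair[as.character(complete)] == "MZ" &
                               aff_by_pair[as.character(complete)] == 2],
    MZ_discordant = complete[zyg_by_pair[as.character(complete)] == "MZ" &
                               aff_by_pair[as.character(complete)] == 1],
    MZ_control    = complete[zyg_by_pair[as.character(complete)] == "MZ" &
                               aff_by_pair[as.character(complete)] == 0],
    DZ_concordant = complete[zyg_by_pair[as.character(complete)] == "DZ" &
                               aff_by_pair[as.character(complete)] == 2],
    DZ_discordant = complete[zyg_by_pair[as.character(complete)] == "DZ" &
                               aff_by_pair[as.character(complete)] == 1],
    DZ_control    = complete[zyg_by_pair[as.character(complete)] == "DZ" &
                               aff_by_pair[as.character(complete)] == 0])
  pools <- lapply(pools, function(v) v[sample.int(length(v))])
  take <- function(pool_name, k, cell) {
    pool <- pools[[pool_name]]
    if (length(pool) < k)
      stop("ascertainment frame cell exhausted: ", cell, " (need ", k,
           " more pairs of type ", pool_name, ", have ", length(pool), ")",
           call. = FALSE)
    taken <- pool[seq_len(k)]
    pools[[pool_name]] <<- pool[-seq_len(k)]
    taken
  }
  rows <- list()
  for (i in seq_len(nrow(frame))) {
    fr <- frame[i, ]
    cell <- paste(fr$site, fr$zygosity, fr$group)
    pool_name <- paste(fr$zygosity, fr$group, sep = "_")
    if (fr$group == "concordant") {
      np <- fr$n_affected %/% 2; ns <- fr$n_affected %% 2
      ids <- take(pool_name, np + ns, cell)
      sel <- records[records$pair_id %in% ids, ]
      if (ns > 0) {  # singleton: keep one member of the last drawn pair
        drop_id <- ids[np + 1]
        sel <- sel[!(sel$pair_id == drop_id & sel$member == 2), ]
      }
    } else if (fr$group == "discordant") {
      np <- min(fr$n_affected, fr$n_unaffected)
      n_extra_aff <- fr$n_affected - np
      n_extra_un <- fr$n_unaffected - np
      ids <- take(pool_name, np + n_extra_aff + n_extra_un, cell)
      sel <- records[records$pair_id %in% ids[seq_len(np)], ]
      extra <- ids[-seq_len(np)]
      if (n_extra_aff > 0) {
        eid <- extra[seq_len(n_extra_aff)]
        sel <- rbind(sel, records[records$pair_id %in% eid &
                                    records$affected == 1, ])
      }
      if (n_extra_un > 0) {
        eid <- extra[n_extra_aff + seq_len(n_extra_un)]
        sel <- rbind(sel, records[records$pair_id %in% eid &
                                    records$affected == 0, ])
      }
    } else {
      np <- fr$n_unaffected %/% 2; ns <- fr$n_unaffected %% 2
      ids <- take(pool_name, np + ns, cell)
      sel <- records[records$pair_id %in% ids, ]
      if (ns > 0) {
        drop_id <- ids[np + 1]
        sel <- sel[!(sel$pair_id == drop_id & sel$member == 2), ]
      }
    }
    if (nrow(sel) > 0) {
      sel$site <- fr$site
      sel$group <- fr$group
      rows[[length(rows) + 1L]] <- sel
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
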