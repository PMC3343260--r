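# Bivariate Cholesky ACE model with the disorder side fixed
# (ascertainment correction).

ace_path_names <- c("a_pc", "c_pc", "e_pc", "a_s", "c_s")

# map drop labels to paths fixed at zero
ace_drop_mask <- function(drop) {
  lab <- c(A_common = "a_pc", C_common = "c_pc", E_common = "e_pc",
           A_specific = "a_s", C_specific = "c_s")
  if (length(drop) == 0) return(character(0))
  bad <- setdiff(drop, names(lab))
  if (length(bad) > 0)
    stop("unknown component(s) to drop: ", paste(bad, collapse = ", "),
         "; E_specific is never droppable", call. = FALSE)
  unname(lab[drop])
}

# implied correlation structure from BV-side paths with fixed disorder paths
ace_structure <- function(bv_paths, sz_paths) {
  a_c <- sz_paths[1]; c_c <- sz_paths[2]; e_c <- sz_paths[3]
  a_pc <- bv_paths["a_pc"]; c_pc <- bv_paths["c_pc"]; e_pc <- bv_paths["e_pc"]
  a_s <- bv_paths["a_s"]; c_s <- bv_paths["c_s"]; e_s <- bv_paths["e_s"]
  list(
    r_within = unname(a_c * a_pc + c_c * c_pc + e_c * e_pc),
    r_bv_mz = unname(a_pc^2 + a_s^2 + c_pc^2 + c_s^2),
    r_bv_dz = unname(0.5 * (a_pc^2 + a_s^2) + c_pc^2 + c_s^2),
    r_cross_mz = unname(a_c * a_pc + c_c * c_pc),
    r_cross_dz = unname(0.5 * a_c * a_pc + c_c * c_pc),
    r_sz_mz = unname(a_c^2 + c_c^2),
    r_sz_dz = unname(0.5 * a_c^2 + c_c^2))
}

#' Fit the bivariate Cholesky ACE model with a fixed disorder side
#'
#' Full-information maximum-likelihood fit of the bivariate Cholesky ACE
#' decomposition on ordinal twin-pair data.  The disorder-side variance
#' components are fixed to external population estimates (`fixed_sz`,
#' defaults `h2 = .81`, `c2 = .11`, `e2 = .08`) and the disorder threshold to
#' the value implied by `prevalence`; this constitutes the ascertainment
#' correction for proband-selected cohorts.  The free parameters are the five
#' endophenotype paths `a_pc, c_pc, e_pc, a_s, c_s` (loadings on the
#' disorder-side A/C/E factors and endophenotype-specific A/C paths), the
#' specific unique-environmental path `e_s` being eliminated by the
#' unit-variance constraint, plus the shared endophenotype thresholds.
#'
#' Submodels (AE, CE, E) are fitted by fixing the corresponding paths at zero
#' via `drop` or the `model` shorthand.  Starting values are taken from a
#' moment transform of normal-score correlations, with a neutral fallback
#' start; the better solution is kept.
#'
#' @param data long-format twin data with `bv_cat` filled (see [prep_bv()]).
#' @param prevalence disorder population prevalence (default 1%).
#' @param fixed_sz named vector `c(h2=, c2=, e2=)` for the disorder side;
#'   must sum to 1.
#' @param model `"ACE"` (default), `"AE"`, `"CE"` or `"E"`; shorthand for
#'   common `drop` sets.
#' @param drop character vector of components fixed to zero, among
#'   `"A_common"`, `"C_common"`, `"E_common"`, `"A_specific"`,
#'   `"C_specific"`.  `E_specific` is never droppable (it absorbs measurement
#'   error).
#' @param ci `FALSE`, `TRUE`, or character vector of quantities (see
#'   [confint.twin_ace()]): compute profile-likelihood CIs at fit time.
#' @param level confidence level.
#' @param control list: `maxit`, `panel_width`, `gl_pts` as in
#'   [twin_polychoric()], plus `start` (named vector overriding the default
#'   starting paths).
#' @return An object of class `"twin_ace"`: list with `paths` (all nine
#'   Cholesky paths), `solution` (the [standardize()]d correlated-factors
#'   solution), `loglik`, `convergence`, `boundary` flags, and bookkeeping
#'   needed by [confint()], [anova()] and [fit_submodel()].
#' @export
twin_ace <- function(data, prevalence = 0.01,
                     fixed_sz = c(h2 = 0.81, c2 = 0.11, e2 = 0.08),
                     model = c("ACE", "AE", "CE", "E"), drop = NULL,
                     ci = FALSE, level = 0.95, control = list()) {
  model <- match.arg(model)
  stopifnot(all(c("MZ", "DZ") %in% data$zygosity),
            abs(sum(fixed_sz) - 1) < 1e-8, all(fixed_sz >= 0))
  if (is.null(drop))
    drop <- switch(model, ACE = character(0),
                   AE = c("C_common", "C_specific"),
                   CE = c("A_common", "A_specific"),
                   E = c("A_common", "A_specific", "C_common", "C_specific"))
  fixed0 <- ace_drop_mask(drop)
  free <- setdiff(ace_path_names, fixed0)
  if (length(free) == 0)
    stop("model with no free common or specific A/C/E paths is not identified",
         call. = FALSE)
  ctrl <- modifyList(list(maxit = 500, panel_width = 2.0, gl_pts = 8L,
                          start = NULL), control)
  K <- max(data$bv_cat, na.rm = TRUE)
  cells <- build_cell_counts(data)
  sz_paths <- sqrt(unname(fixed_sz[c("h2", "c2", "e2")]))

  full_paths <- function(pv) {
    bp <- setNames(numeric(5), ace_path_names)
    bp[free] <- pv
    ss <- sum(bp^2)
    es2 <- 1 - ss
    c(bp, e_s = if (es2 > 0) sqrt(es2) else NA_real_)
  }
  negll <- function(par) {
    pv <- par[seq_along(free)]
    tpar <- par[-seq_along(free)]
    t1 <- tpar[1]
    tau <- if (K > 2) c(t1, t1 + cumsum(exp(tpar[-1]))) else t1
    if (any(!is.finite(tau))) return(1e10)
    bp <- full_paths(pv)
    if (is.na(bp["e_s"])) return(1e9 * (1 + sum(pv^2)))  # outside unit variance
    s <- do.call(correlation_structure, ace_structure(bp, sz_paths))
    th <- threshold_set(prevalence, tau)
    ll <- cells_loglik(cells, s, th, ctrl$panel_width, ctrl$gl_pts)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  tau0 <- bv_threshold_start(data$bv_cat, K)
  tpar0 <- c(tau0[1], if (K > 2) log(diff(tau0)))
  starts <- list()
  if (!is.null(ctrl$start)) {
    starts <- list(c(ctrl$start[free], tpar0))
  } else {
    mom <- ace_moment_start(data, prevalence, K, sz_paths)
    starts <- list(c(mom[free], tpar0),
                   c(setNames(rep(0.1, length(free)), free) *
                       ifelse(free %in% c("a_s"), 5, 1), tpar0))
  }
  best <- NULL
  for (st in starts) {
    o <- optim(st, negll, method = "Nelder-Mead",
               control = list(maxit = ctrl$maxit))
    if (is.null(best) || o$value < best$value) best <- o
  }
  best <- optim(best$par, negll, method = "BFGS",
                control = list(maxit = 100, reltol = 1e-9))
  if (best$value >= 1e9)
    stop("ACE fit failed to find a feasible point", call. = FALSE)
  pv <- best$par[seq_along(free)]
  tpar <- best$par[-seq_along(free)]
  tau <- if (K > 2) c(tpar[1], tpar[1] + cumsum(exp(tpar[-1]))) else tpar[1]
  bp <- full_paths(pv)
  # sign convention: report r_g with the sign of a_pc; flip path-sign
  # indeterminacies (a_s, c_s, e_s) to non-negative
  bp[c("a_s", "c_s", "e_s")] <- abs(bp[c("a_s", "c_s", "e_s")])
  paths <- twin_paths(sz_paths[1], sz_paths[2], sz_paths[3],
                      bp["a_pc"], bp["c_pc"], bp["e_pc"],
                      bp["a_s"], bp["c_s"], bp["e_s"])
  s <- do.call(correlation_structure, ace_structure(bp, sz_paths))
  th <- threshold_set(prevalence, tau)
  ll <- cells_loglik(cells, s, th, 1.0, 12L)
  n_pairs <- sum(unlist(lapply(cells[grep("pairs", names(cells))], `[[`, "n")))
  n_single <- sum(unlist(lapply(cells[grep("singles", names(cells))], `[[`, "n")))
  fit <- structure(list(
    paths = paths, bv_paths = bp, thresholds = th, structure = s,
    loglik = as.numeric(ll), model = model, drop = drop, free = free,
    fixed_sz = fixed_sz, prevalence = prevalence, K = K, cells = cells,
    convergence = best$convergence == 0,
    boundary = any(abs(bp[free]) < 1e-4 &
                     free %in% c("c_pc", "c_s", "a_pc", "a_s")),
    n_pairs = n_pairs, n_singletons = n_single,
    par = best$par, negll = negll, level = level,
    call = match.call()), class = "twin_ace")
  fit$solution <- standardize(fit)
  if (!isFALSE(ci)) {
    parm <- if (isTRUE(ci)) c("h2_bv", "c2_bv", "e2_bv", "r_g", "r_c",
                              "r_e", "r_ph") else ci
    fit$ci <- confint(fit, parm = parm, level = level)
  }
  fit
}

# Falconer-style moment start from normal-score correlations
ace_moment_start <- function(data, prevalence, K, sz_paths) {
  ms <- structure_moment_start(data, prevalence, K)
  r <- ms$r  # r_within, r_bv_mz, r_bv_dz, r_cross_mz, r_cross_dz
  h2 <- min(max(2 * (r[2] - r[3]), 0.05), 0.95)
  c2 <- min(max(2 * r[3] - r[2], 0), 0.9 - h2 * 0.9)
  a_c <- sz_paths[1]; c_c <- sz_paths[2]; e_c <- sz_paths[3]
  a_pc <- min(max(2 * (r[4] - r[5]) / a_c, -0.9), 0.9)
  c_pc <- if (c_c > 0) min(max((2 * r[5] - r[4]) / c_c, -0.5), 0.5) else 0
  e_pc <- min(max((r[1] - a_c * a_pc - c_c * c_pc) / e_c, -0.5), 0.5)
  a_s <- sqrt(max(h2 - a_pc^2, 0.01))
  c_s <- sqrt(max(c2 - c_pc^2, 0))
  tot <- a_pc^2 + c_pc^2 + e_pc^2 + a_s^2 + c_s^2
  if (tot > 0.95) {
    sc <- sqrt(0.95 / tot)
    a_pc <- a_pc * sc; c_pc <- c_pc * sc; e_pc <- e_pc * sc
    a_s <- a_s * sc; c_s <- c_s * sc
  }
  c(a_pc = a_pc, c_pc = c_pc, e_pc = e_pc, a_s = a_s, c_s = c_s)
}

#' Standardised correlated-factors solution
#'
#' Re-expresses a Cholesky ACE fit (or a raw set of paths) as per-trait
#' variance proportions and cross-trait factor correlations: `h2`, `c2`, `e2`
#' for the endophenotype, the genetic, common- and unique-environmental
#' correlations `r_g`, `r_c`, `r_e`, the phenotypic correlation `r_ph` and its
#' additive decomposition
#' `r_ph = sqrt(h2_sz) r_g sqrt(h2_bv) + sqrt(c2_sz) r_c sqrt(c2_bv) +
#' sqrt(e2_sz) r_e sqrt(e2_bv)`.
#' A factor correlation whose denominator variance component is zero is
#' undefined and returned as `NA` (its contribution to `r_ph` is 0).
#'
#' @param x a `"twin_ace"` fit or a [twin_paths()] object.
#' @param ... unused.
#' @return An object of class `"twin_ace_solution"` (named list).
#' @export
standardize <- function(x, ...) UseMethod("standardize")

#' @export
standardize.twin_ace <- function(x, ...) standardize(x$paths, ...)

#' @export
standardize.twin_paths <- function(x, ...) {
  p <- as.list(x)
  h2_sz <- p$a_c^2; c2_sz <- p$c_c^2; e2_sz <- p$e_c^2
  h2_bv <- p$a_pc^2 + p$a_s^2
  c2_bv <- p$c_pc^2 + p$c_s^2
  e2_bv <- p$e_pc^2 + p$e_s^2
  fac_cor <- function(cov, v1, v2) {
    if (v1 <= 0 || v2 <= 0) return(NA_real_)
    cov / sqrt(v1 * v2)
  }
  r_g <- fac_cor(p$a_c * p$a_pc, h2_sz, h2_bv)
  r_c <- fac_cor(p$c_c * p$c_pc, c2_sz, c2_bv)
  r_e <- fac_cor(p$e_c * p$e_pc, e2_sz, e2_bv)
  r_ph_a <- p$a_c * p$a_pc
  r_ph_c <- p$c_c * p$c_pc
  r_ph_e <- p$e_c * p$e_pc
  structure(list(h2_bv = h2_bv, c2_bv = c2_bv, e2_bv = e2_bv,
                 h2_sz = h2_sz, c2_sz = c2_sz, e2_sz = e2_sz,
                 r_g = r_g, r_c = r_c, r_e = r_e,
                 r_ph = r_ph_a + r_ph_c + r_ph_e,
                 r_ph_a = r_ph_a, r_ph_c = r_ph_c, r_ph_e = r_ph_e),
            class = "twin_ace_solution")
}

#' @export
print.twin_ace_solution <- function(x, digits = 3, ...) {
  cat("Correlated-factors solution\n")
  cat(sprintf("  endophenotype: h2 = %.*f, c2 = %.*f, e2 = %.*f\n",
              digits, x$h2_bv, digits, x$c2_bv, digits, x$e2_bv))
  cat(sprintf("  disorder (fixed): h2 = %.2f, c2 = %.2f, e2 = %.2f\n",
              x$h2_sz, x$c2_sz, x$e2_sz))
  fmt <- function(v) if (is.na(v)) "undef" else sprintf("%.*f", digits, v)
  cat(sprintf("  r_g = %s, r_c = %s, r_e = %s\n",
              fmt(x$r_g), fmt(x$r_c), fmt(x$r_e)))
  cat(sprintf("  r_ph = %.*f = %.*f (A) + %.*f (C) + %.*f (E)\n",
              digits, x$r_ph, digits, x$r_ph_a, digits, x$r_ph_c,
              digits, x$r_ph_e))
  invisible(x)
}

#' Decompose the phenotypic correlation into A/C/E proportions
#'
#' Proportions of the phenotypic correlation attributable to the additive
#' genetic, common-environmental and unique-environmental channels:
#' `r_ph_a / r_ph` etc.  The three proportions sum to 1 but may individually
#' exceed 1 or be negative when parts have opposite signs; they are reported
#' as computed, not clamped.
#'
#' @param sol a `"twin_ace_solution"` (or a `"twin_ace"` fit).
#' @return Named vector `c(genetic=, common_env=, unique_env=)`.
#' @export
#' @examples
#' # printed-value arithmetic: -.17 / -.22 of the cerebrum example
#' round(100 * -0.17 / -0.22)
decompose_rph <- function(sol) {
  if (inherits(sol, "twin_ace")) sol <- sol$solution
  if (!is.finite(sol$r_ph) || sol$r_ph == 0)
    stop("phenotypic correlation is zero; proportions undefined",
         call. = FALSE)
  c(genetic = sol$r_ph_a / sol$r_ph,
    common_env = sol$r_ph_c / sol$r_ph,
    unique_env = sol$r_ph_e / sol$r_ph)
}

#' Percent of endophenotype variance explained by disorder liability
#'
#' @param r_ph phenotypic correlation, `|r_ph| <= 1`.
#' @return `100 * r_ph^2`, in percent.
#' @export
#' @examples
#' variance_explained(-0.22)   # 4.84
variance_explained <- function(r_ph) {
  stopifnot(all(abs(r_ph) <= 1))
  100 * r_ph^2
}

#' Refit with components dropped and test against the fuller model
#'
#' Refits the Cholesky model with the named paths fixed at zero and reports
#' the likelihood-ratio test against the supplied fit.  The chi-squared
#' p-value is nominal: when a dropped variance component lies on the boundary
#' of its parameter space (for example `c2 = 0`), the naive chi-squared
#' reference makes the test conservative.
#'
#' @param full a `"twin_ace"` fit.
#' @param drop character vector of components to drop (see [twin_ace()]),
#'   in addition to any already dropped in `full`.
#' @param data the data used for `full` (pair cells are re-used from the fit
#'   if omitted).
#' @param ... passed to [twin_ace()].
#' @return A list with `fit` (the submodel `"twin_ace"`), `lrt`
#'   (`-2 delta lnL`), `df` and `p_value`.
#' @export
fit_submodel <- function(full, drop, data = NULL, ...) {
  stopifnot(inherits(full, "twin_ace"))
  drop_all <- union(full$drop, drop)
  sub <- refit_ace(full, drop = drop_all, data = data, ...)
  lrt <- max(0, 2 * (full$loglik - sub$loglik))
  df <- length(full$free) - length(sub$free)
  list(fit = sub, lrt = lrt, df = df,
       p_value = if (df > 0) pchisq(lrt, df, lower.tail = FALSE) else NA_real_)
}

# refit from stored cells (internal; data optional)
refit_ace <- function(fit, drop, data = NULL, ...) {
  if (!is.null(data))
    return(twin_ace(data, prevalence = fit$prevalence,
                    fixed_sz = fit$fixed_sz, drop = drop, ...))
  fake <- cells_to_frame(fit$cells)
  twin_ace(fake, prevalence = fit$prevalence, fixed_sz = fit$fixed_sz,
           drop = drop, ...)
}

# expand aggregated cells back to a long-format frame (exact likelihood
# equivalence; used to refit submodels without the original records)
cells_to_frame <- function(cells) {
  rows <- list()
  pid <- 0L
  for (z in c("MZ", "DZ")) {
    pz <- cells[[paste0("pairs_", z)]]
    if (!is.null(pz)) {
      for (i in seq_along(pz$n)) {
        n <- pz$n[i]
        ids <- pid + seq_len(n); pid <- pid + n
        rows[[length(rows) + 1L]] <- data.frame(
          pair_id = rep(ids, each = 2), zygosity = z, member = rep(1:2, n),
          affected = rep(c(pz$sz1[i], pz$sz2[i]), n),
          bv_cat = rep(c(pz$bv1[i], pz$bv2[i]), n))
      }
    }
    sz_ <- cells[[paste0("singles_", z)]]
    if (!is.null(sz_)) {
      for (i in seq_along(sz_$n)) {
        n <- sz_$n[i]
        ids <- pid + seq_len(n); pid <- pid + n
        rows[[length(rows) + 1L]] <- data.frame(
          pair_id = ids, zygosity = z, member = 1L,
          affected = rep(sz_$sz[i], n), bv_cat = rep(sz_$bv[i], n))
      }
    }
  }
  out <- do.call(rbind, rows)
  out$bv_cat[out$bv_cat == 0] <- NA_integer_
  out
}

#' @export
anova.twin_ace <- function(object, ...) {
  fits <- c(list(object), list(...))
  fits <- fits[vapply(fits, inherits, logical(1), "twin_ace")]
  fits <- fits[order(-vapply(fits, function(f) length(f$free), numeric(1)))]
  ll <- vapply(fits, `[[`, numeric(1), "loglik")
  npar <- vapply(fits, function(f) length(f$par), numeric(1))
  lrt <- c(NA, pmax(0, 2 * (ll[-length(ll)] - ll[-1])))
  df <- c(NA, npar[-length(npar)] - npar[-1])
  tab <- data.frame(model = vapply(fits, function(f)
    if (length(f$drop)) paste(f$model, "-", paste(f$drop, collapse = "+"))
    else f$model, character(1)),
    npar = npar, logLik = ll, LRT = lrt, df = df,
    p = ifelse(is.na(df), NA, pchisq(lrt, df, lower.tail = FALSE)))
  cat("Note: components on a variance boundary make the naive chi-squared",
      "LRT conservative.\n")
  tab
}

#' @export
coef.twin_ace <- function(object, ...) object$paths

#' @export
logLik.twin_ace <- function(object, ...) {
  structure(object$loglik, df = length(object$par), class = "logLik")
}

#' @export
print.twin_ace <- function(x, digits = 3, ...) {
  cat(sprintf("Bivariate Cholesky %s model (disorder side fixed: h2 = %.2f, c2 = %.2f, e2 = %.2f)\n",
              x$model, x$fixed_sz["h2"], x$fixed_sz["c2"], x$fixed_sz["e2"]))
  if (length(x$drop) > 0)
    cat("  dropped:", paste(x$drop, collapse = ", "), "\n")
  cat(sprintf("  %d pairs, %d singletons; prevalence %.3g; log-likelihood %.3f%s\n",
              x$n_pairs, x$n_singletons, x$prevalence, x$loglik,
              if (!x$convergence) " (NOT converged)" else ""))
  print(x$solution, digits = digits)
  invisible(x)
}

#' @export
summary.twin_ace <- function(object, ...) {
  if (is.null(object$ci))
    object$ci <- confint(object, parm = c("h2_bv", "c2_bv", "e2_bv",
                                          "r_g", "r_e", "r_ph"))
  class(object) <- c("summary.twin_ace", class(object))
  object
}

#' @export
print.summary.twin_ace <- function(x, digits = 3, ...) {
  class(x) <- "twin_ace"
  print(x, digits = digits)
  cat("Profile-likelihood intervals:\n")
  print(round(x$ci, digits))
  invisible(x)
}

#' Simulate cohorts from a fitted Cholesky model
#'
#' Draws new twin cohorts from the fitted path coefficients (disorder side
#' fixed, endophenotype side estimated) at the fitted prevalence.
#'
#' @param object a `"twin_ace"` fit.
#' @param nsim number of replicate cohorts.
#' @param seed integer seed.
#' @param n_mz,n_dz pairs per zygosity (default: as in the fitted data).
#' @param ... unused.
#' @return A list of `nsim` data frames (a single data frame if `nsim = 1`).
#' @export
simulate.twin_ace <- function(object, nsim = 1, seed = NULL,
                              n_mz = NULL, n_dz = NULL, ...) {
  cz <- object$cells
  if (is.null(n_mz))
    n_mz <- sum(cz$pairs_MZ$n %||% 0)
  if (is.null(n_dz))
    n_dz <- sum(cz$pairs_DZ$n %||% 0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max, nsim)
  out <- lapply(seeds, function(s)
    simulate_twins(object$paths, n_mz, n_dz, object$prevalence, seed = s))
  if (nsim == 1) out[[1]] else out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Profile-likelihood intervals for a Cholesky ACE fit
#'
#' Profile-likelihood confidence intervals for derived quantities of the
#' standardised solution.  The profile for a derived quantity `g` is computed
#' by maximising the likelihood under a quadratic constraint penalty holding
#' `g` at a candidate value, and locating the value where `-2 delta lnL`
#' crosses the chi-squared(1) quantile by root bracketing.
#'
#' @param object a `"twin_ace"` fit.
#' @param parm quantities among `h2_bv`, `c2_bv`, `e2_bv`, `r_g`, `r_c`,
#'   `r_e`, `r_ph`, `r_ph_a`, `r_ph_c`, `r_ph_e`.
#' @param level confidence level.
#' @param ... unused.
#' @return Matrix with `lower`/`upper` columns.  Variance proportions are
#'   bounded to `[0, 1]` and correlations to `[-1, 1]`.
#' @export
confint.twin_ace <- function(object, parm = c("h2_bv", "r_ph"), level = 0.95,
                             ...) {
  all_q <- c("h2_bv", "c2_bv", "e2_bv", "r_g", "r_c", "r_e", "r_ph",
             "r_ph_a", "r_ph_c", "r_ph_e")
  parm <- match.arg(parm, all_q, several.ok = TRUE)
  out <- matrix(NA_real_, length(parm), 2,
                dimnames = list(parm, c("lower", "upper")))
  for (p in parm) out[p, ] <- profile_ci_ace(object, p, level)
  out
}

# derived quantity from a free-path vector + threshold params
ace_quantity <- function(fit, par, what) {
  pv <- par[seq_along(fit$free)]
  bp <- setNames(numeric(5), ace_path_names)
  bp[fit$free] <- pv
  es2 <- 1 - sum(bp^2)
  p <- c(as.list(bp), list(e_s = sqrt(max(es2, 0))))
  sz <- sqrt(unname(fit$fixed_sz[c("h2", "c2", "e2")]))
  h2 <- p$a_pc^2 + p$a_s^2; c2 <- p$c_pc^2 + p$c_s^2
  e2 <- p$e_pc^2 + p$e_s^2
  switch(what,
         h2_bv = h2, c2_bv = c2, e2_bv = e2,
         r_g = if (h2 > 0) sz[1] * p$a_pc / (sz[1] * sqrt(h2)) else 0,
         r_c = if (c2 > 0) p$c_pc / sqrt(c2) else 0,
         r_e = if (e2 > 0) p$e_pc / sqrt(e2) else 0,
         r_ph = sz[1] * p$a_pc + sz[2] * p$c_pc + sz[3] * p$e_pc,
         r_ph_a = sz[1] * p$a_pc, r_ph_c = sz[2] * p$c_pc,
         r_ph_e = sz[3] * p$e_pc)
}

profile_ci_ace <- function(fit, what, level = 0.95, penalty = 2e4) {
  crit <- qchisq(level, 1)
  llmax <- -fit$negll(fit$par)
  hat <- ace_quantity(fit, fit$par, what)
  is_var <- what %in% c("h2_bv", "c2_bv", "e2_bv")
  lim <- if (is_var) c(0, 1) else c(-1, 1)
  q_warm <- fit$par
  prof_deficit <- function(v) {
    inner <- function(q) fit$negll(q) +
      penalty * (ace_quantity(fit, q, what) - v)^2
    o <- optim(q_warm, inner, method = "Nelder-Mead",
               control = list(maxit = 200, reltol = 1e-8))
    q_warm <<- o$par
    llp <- -fit$negll(o$par)
    2 * (llmax - llp) - crit
  }
  bound <- function(dir) {
    step <- 0.08
    v_in <- hat; f_in <- -crit
    repeat {
      v_out <- v_in + dir * step
      if (v_out <= lim[1]) { if (prof_deficit(lim[1] + 1e-6) < 0) return(lim[1]) else v_out <- lim[1] + 1e-6 }
      if (v_out >= lim[2]) { if (prof_deficit(lim[2] - 1e-6) < 0) return(lim[2]) else v_out <- lim[2] - 1e-6 }
      f_out <- prof_deficit(v_out)
      if (!is.finite(f_out)) return(if (dir < 0) lim[1] else lim[2])
      if (f_out > 0) {
        r <- uniroot(prof_deficit, sort(c(v_in, v_out)),
                     f.lower = if (dir > 0) f_in else f_out,
                     f.upper = if (dir > 0) f_out else f_in, tol = 5e-4)
        return(r$root)
      }
      v_in <- v_out; f_in <- f_out
      step <- step * 2
    }
  }
  c(lower = bound(-1), upper = bound(1))
}

#' Plot the standardised solution of a Cholesky ACE fit
#'
#' Barplot of the endophenotype variance components and of the additive
#' decomposition of the phenotypic correlation.
#'
#' @param x a `"twin_ace"` fit.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.twin_ace <- function(x, ...) {
  sol <- x$solution
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::barplot(c(A = sol$h2_bv, C = sol$c2_bv, E = sol$e2_bv),
                    main = "Endophenotype variance", ylab = "proportion",
                    ylim = c(0, 1), ...)
  graphics::barplot(c(A = sol$r_ph_a, C = sol$r_ph_c, E = sol$r_ph_e,
                      total = sol$r_ph),
                    main = "Phenotypic correlation", ylab = "r", ...)
  invisible(x)
}
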