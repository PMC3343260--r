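# Constrained polychoric twin-correlation estimation (saturated correlation
# model of the bivariate liability analysis).

# pack/unpack: 5 correlations on atanh scale, thresholds as first + log-steps
pack_structure_par <- function(r, tau) {
  c(atanh(pmin(pmax(r, -0.999), 0.999)), tau[1],
    if (length(tau) > 1) log(diff(tau)))
}

unpack_structure_par <- function(par, K) {
  r <- tanh(par[1:5])
  t1 <- par[6]
  tau <- if (K > 2) c(t1, t1 + cumsum(exp(par[7:(5 + K - 1)]))) else t1
  list(r = r, tau = tau)
}

# moment-based starting values: normal scores from pooled margins
structure_moment_start <- function(data, prevalence, K) {
  tau <- bv_threshold_start(data$bv_cat, K)
  brk <- c(-Inf, tau, Inf)
  # category midpoint scores E[Z | tau_{k-1} < Z < tau_k]
  pk <- pnorm(brk[-1]) - pnorm(brk[-length(brk)])
  zk <- (dnorm(brk[-length(brk)]) - dnorm(brk[-1])) / pmax(pk, 1e-12)
  t_sz <- threshold_from_prevalence(prevalence)
  p1 <- pnorm(t_sz, lower.tail = FALSE)
  zsz <- ifelse(data$affected == 1, dnorm(t_sz) / p1, -dnorm(t_sz) / (1 - p1))
  zbv <- ifelse(is.na(data$bv_cat) | data$bv_cat == 0, NA, zk[pmax(data$bv_cat, 1)])
  d <- data.frame(pair_id = data$pair_id, zygosity = data$zygosity,
                  member = data$member, zsz = zsz, zbv = zbv)
  safe_cor <- function(x, y) {
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 10 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(0)
    min(max(stats::cor(x[ok], y[ok]), -0.9), 0.9)
  }
  r_within <- safe_cor(d$zsz, d$zbv)
  pairwise <- function(z, col1, col2) {
    dz <- d[d$zygosity == z, ]
    cnt <- table(dz$pair_id)
    dz <- dz[as.character(dz$pair_id) %in% names(cnt)[cnt == 2], ]
    if (nrow(dz) < 20) return(0)
    dz <- dz[order(dz$pair_id, dz$member), ]
    i1 <- seq(1, nrow(dz), by = 2)
    safe_cor(dz[[col1]][i1], dz[[col2]][i1 + 1])
  }
  r <- c(r_within,
         pairwise("MZ", "zbv", "zbv"), pairwise("DZ", "zbv", "zbv"),
         pairwise("MZ", "zsz", "zbv"), pairwise("DZ", "zsz", "zbv"))
  list(r = r, tau = tau)
}

bv_threshold_start <- function(bv_cat, K) {
  cat <- bv_cat[!is.na(bv_cat) & bv_cat > 0]
  pr <- tabulate(cat, K) / length(cat)
  cum <- cumsum(pr)[seq_len(K - 1)]
  qnorm(pmin(pmax(cum, 1e-4), 1 - 1e-4))
}

#' Fit the constrained polychoric twin-correlation structure
#'
#' Maximum-likelihood estimation of the five estimable correlations of the
#' bivariate liability-threshold twin analysis: the within-person cross-trait
#' correlation (constrained equal across all individuals), the cross-twin
#' endophenotype correlation per zygosity, and the member-symmetric cross-twin
#' cross-trait correlation per zygosity, together with the shared
#' endophenotype thresholds.  The disorder cross-twin correlations are fixed
#' (`fix_sz_mz`, `fix_sz_dz`) and the disorder threshold is fixed by
#' `prevalence`: this is the ascertainment correction for cohorts recruited
#' through affected probands.
#'
#' Free correlations are optimised on the atanh scale and thresholds as first
#' threshold plus log-increments, from two deterministic starting points (all
#' correlations zero, and normal-score moment estimates); the best solution is
#' kept.  Confidence intervals are profile-likelihood intervals at the chi
#' squared(1) cutoff (on request via `ci` or [confint()]).
#'
#' @param data long-format twin data with `bv_cat` filled (see [prep_bv()]);
#'   pairs with one missing member (singletons) are marginalised.
#' @param prevalence disorder population prevalence (default 1%).
#' @param fix_sz_mz,fix_sz_dz fixed disorder cross-twin correlations; defaults
#'   `h2 + c2 = .92` and `.5 h2 + c2 = .515` from the external disorder model.
#' @param ci logical or character vector of parameters among
#'   `c("r_within","r_bv_mz","r_bv_dz","r_cross_mz","r_cross_dz")`: compute
#'   profile-likelihood CIs at fit time.
#' @param level confidence level for intervals.
#' @param control list: `maxit` (optimiser iterations), `panel_width`,
#'   `gl_pts` (integration rule during optimisation).
#' @return An object of class `"twin_polychoric"`: a list with `structure`
#'   (the fitted [correlation_structure()]), `thresholds`, `loglik`,
#'   `estimate`, `ci`, `convergence`, `boundary`, `n_pairs`, `n_singletons`.
#' @seealso [twin_ace()] for the Cholesky ACE decomposition.
#' @export
twin_polychoric <- function(data, prevalence = 0.01,
                            fix_sz_mz = 0.92, fix_sz_dz = 0.515,
                            ci = FALSE, level = 0.95, control = list()) {
  stopifnot(all(c("MZ", "DZ") %in% data$zygosity))
  ctrl <- modifyList(list(maxit = 500, panel_width = 2.0, gl_pts = 8L), control)
  K <- max(data$bv_cat, na.rm = TRUE)
  cells <- build_cell_counts(data)
  free <- c("r_within", "r_bv_mz", "r_bv_dz", "r_cross_mz", "r_cross_dz")

  negll <- function(par) {
    up <- unpack_structure_par(par, K)
    if (any(!is.finite(up$tau)) || any(diff(up$tau) <= 0)) return(1e10)
    s <- correlation_structure(up$r[1], up$r[2], up$r[3], up$r[4], up$r[5],
                               fix_sz_mz, fix_sz_dz)
    th <- threshold_set(prevalence, up$tau)
    ll <- cells_loglik(cells, s, th, ctrl$panel_width, ctrl$gl_pts)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  tau0 <- bv_threshold_start(data$bv_cat, K)
  starts <- list(pack_structure_par(rep(0, 5), tau0),
                 do.call(pack_structure_par,
                         structure_moment_start(data, prevalence, K)))
  best <- NULL
  for (st in starts) {
    o <- optim(st, negll, method = "Nelder-Mead",
               control = list(maxit = ctrl$maxit))
    if (is.null(best) || o$value < best$value) best <- o
  }
  best <- optim(best$par, negll, method = "BFGS",
                control = list(maxit = 100, reltol = 1e-9))
  if (best$value >= 1e10)
    stop("polychoric fit failed to find a feasible point", call. = FALSE)
  up <- unpack_structure_par(best$par, K)
  s <- correlation_structure(up$r[1], up$r[2], up$r[3], up$r[4], up$r[5],
                             fix_sz_mz, fix_sz_dz)
  th <- threshold_set(prevalence, up$tau)
  ll <- cells_loglik(cells, s, th, 1.0, 12L)
  est <- setNames(up$r, free)
  n_pairs <- sum(unlist(lapply(cells[grep("pairs", names(cells))], `[[`, "n")))
  n_single <- sum(unlist(lapply(cells[grep("singles", names(cells))], `[[`, "n")))
  fit <- structure(list(
    structure = s, thresholds = th, loglik = as.numeric(ll),
    estimate = est, ci = NULL,
    convergence = best$convergence == 0,
    boundary = any(abs(est) > 0.995),
    n_pairs = n_pairs, n_singletons = n_single,
    cells = cells, K = K, prevalence = prevalence,
    fix_sz = c(MZ = fix_sz_mz, DZ = fix_sz_dz),
    par = best$par, negll = negll, level = level,
    call = match.call()), class = "twin_polychoric")
  if (!isFALSE(ci)) {
    parm <- if (isTRUE(ci)) free else ci
    fit$ci <- confint(fit, parm = parm, level = level)
  }
  fit
}

# Profile-likelihood CI for one free correlation (index j in 1..5).
profile_ci_structure <- function(fit, j, level = 0.95) {
  crit <- qchisq(level, 1)
  llmax <- -fit$negll(fit$par)
  K <- fit$K
  q_warm <- fit$par[-j]
  prof_deficit <- function(v) {
    # fix correlation j at v, re-optimise the rest (warm-started)
    zfix <- atanh(min(max(v, -0.9999), 0.9999))
    inner <- function(q) fit$negll(append(q, zfix, after = j - 1))
    o <- optim(q_warm, inner, method = "Nelder-Mead",
               control = list(maxit = 300, reltol = 1e-8))
    q_warm <<- o$par
    2 * (llmax + o$value) - crit   # o$value = -llprof
  }
  hat <- fit$estimate[j]
  bound <- function(dir) {
    step <- 0.03
    v_in <- hat
    f_in <- -crit
    repeat {
      v_out <- v_in + dir * step
      if (abs(v_out) >= 0.9995) return(sign(v_out) * 1)
      f_out <- prof_deficit(v_out)
      if (is.na(f_out)) return(sign(v_out) * 1)
      if (f_out > 0) {
        r <- uniroot(prof_deficit, c(min(v_in, v_out), max(v_in, v_out)),
                     f.lower = if (dir > 0) f_in else f_out,
                     f.upper = if (dir > 0) f_out else f_in, tol = 1e-5)
        return(r$root)
      }
      v_in <- v_out; f_in <- f_out
      step <- step * 1.6
    }
  }
  c(lower = bound(-1), upper = bound(1))
}

#' @export
confint.twin_polychoric <- function(object, parm, level = 0.95, ...) {
  free <- names(object$estimate)
  if (missing(parm)) parm <- free
  parm <- match.arg(parm, free, several.ok = TRUE)
  out <- matrix(NA_real_, length(parm), 2,
                dimnames = list(parm, c("lower", "upper")))
  for (p in parm)
    out[p, ] <- profile_ci_structure(object, match(p, free), level)
  out
}

#' @export
coef.twin_polychoric <- function(object, ...) object$estimate

#' @export
logLik.twin_polychoric <- function(object, ...) {
  structure(object$loglik, df = length(object$par), class = "logLik")
}

#' @export
print.twin_polychoric <- function(x, digits = 3, ...) {
  cat("Constrained polychoric twin-correlation structure\n")
  cat(sprintf("  %d pairs, %d singletons; %d endophenotype classes\n",
              x$n_pairs, x$n_singletons, x$K))
  cat(sprintf("  disorder cross-twin r fixed at %.3f (MZ) / %.3f (DZ); prevalence %.3g\n",
              x$fix_sz["MZ"], x$fix_sz["DZ"], x$prevalence))
  est <- round(x$estimate, digits)
  if (!is.null(x$ci)) {
    ci <- round(x$ci, digits)
    for (nm in names(est))
      cat(sprintf("  %-11s %6.3f (%.3f to %.3f)\n", nm, est[nm],
                  ci[nm, 1], ci[nm, 2]))
  } else {
    print(est)
  }
  cat(sprintf("  log-likelihood %.3f%s\n", x$loglik,
              if (!x$convergence) " (NOT converged)" else ""))
  if (x$boundary) cat("  note: estimate at correlation boundary\n")
  invisible(x)
}

#' @export
summary.twin_polychoric <- function(object, ...) {
  if (is.null(object$ci)) object$ci <- confint(object)
  class(object) <- c("summary.twin_polychoric", class(object))
  object
}

#' @export
print.summary.twin_polychoric <- function(x, ...) {
  class(x) <- "twin_polychoric"
  print(x)
  cat("  thresholds:", signif(x$thresholds$bv_thresholds, 4), "\n")
  invisible(x)
}
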