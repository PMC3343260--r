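#' Liability threshold from population prevalence
#'
#' Returns the standard-normal threshold `t` with upper-tail mass equal to the
#' prevalence: individuals with liability above `t` are affected.
#'
#' @param p prevalence, strictly in (0, 1).
#' @return The z-value threshold.
#' @export
#' @examples
#' threshold_from_prevalence(0.01)   # 2.3263
threshold_from_prevalence <- function(p) {
  if (!is.numeric(p) || any(p <= 0) || any(p >= 1))
    stop("prevalence must lie strictly in (0, 1)", call. = FALSE)
  qnorm(p, lower.tail = FALSE)
}

#' Bivariate standard-normal rectangle probability
#'
#' Probability that a standard bivariate normal vector with correlation `r`
#' falls in the rectangle `(lower, upper)`.  Computed with Genz's hybrid
#' algorithm; absolute error below 1e-14.
#'
#' @param r correlation in `[-1, 1]`.
#' @param lower,upper length-2 bounds; `-Inf`/`Inf` allowed.
#' @return The rectangle probability.
#' @export
#' @examples
#' bvn_rect(0.5, c(0, 0), c(Inf, Inf))   # 1/4 + asin(.5)/(2*pi)
bvn_rect <- function(r, lower, upper) {
  stopifnot(length(lower) == 2, length(upper) == 2, length(r) == 1,
            abs(r) <= 1)
  if (any(lower >= upper))
    stop("lower bounds must be strictly below upper bounds", call. = FALSE)
  R <- matrix(c(1, r, r, 1), 2, 2)
  as.numeric(cpp_rect_probs(R, matrix(lower, 1), matrix(upper, 1)))
}

#' Multivariate-normal rectangle probability (up to 4 dimensions)
#'
#' Rectangle probability for a standard multivariate normal with correlation
#' matrix `R`.  Dimensions with `(-Inf, Inf)` bounds are marginalised exactly;
#' the two narrowest remaining dimensions are integrated by deterministic
#' panelled Gauss-Legendre quadrature with the other dimensions handled by the
#' analytic conditional bivariate CDF.  The rule is fixed, so results are
#' exactly reproducible; absolute error is well below `abs_tol` for
#' correlation matrices away from singularity.
#'
#' @param R correlation matrix (unit diagonal, positive semi-definite),
#'   dimension 2 to 4.
#' @param lower,upper bound vectors matching `nrow(R)`.
#' @param abs_tol requested absolute accuracy; selects the quadrature rule
#'   (values below 1e-6 use the finer rule).
#' @return The rectangle probability.
#' @export
#' @examples
#' mvn_rect(diag(4), rep(0, 4), rep(Inf, 4))   # 1/16
mvn_rect <- function(R, lower, upper, abs_tol = 1e-7) {
  R <- as.matrix(R)
  d <- nrow(R)
  stopifnot(d >= 2, d <= 4, ncol(R) == d, length(lower) == d,
            length(upper) == d)
  if (any(abs(diag(R) - 1) > 1e-8))
    stop("R must have unit diagonal", call. = FALSE)
  if (any(abs(R - t(R)) > 1e-8))
    stop("R must be symmetric", call. = FALSE)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("R is not positive semi-definite (min eigenvalue ",
         format(min(ev)), ")", call. = FALSE)
  if (any(lower >= upper))
    stop("lower bounds must be strictly below upper bounds", call. = FALSE)
  if (abs_tol < 1e-6)
    as.numeric(cpp_rect_probs(R, matrix(lower, 1), matrix(upper, 1), 1.0, 12L))
  else
    as.numeric(cpp_rect_probs(R, matrix(lower, 1), matrix(upper, 1), 2.0, 8L))
}

#' Constrained polychoric twin-correlation structure
#'
#' Container for the five estimable correlations of the bivariate
#' liability-threshold twin analysis, with the disorder cross-twin
#' correlations fixed by the ascertainment correction.
#'
#' @param r_within within-person cross-trait correlation (one value for the
#'   whole sample).
#' @param r_bv_mz,r_bv_dz cross-twin endophenotype correlations by zygosity.
#' @param r_cross_mz,r_cross_dz cross-twin cross-trait correlations by
#'   zygosity (member-symmetric).
#' @param r_sz_mz,r_sz_dz fixed disorder cross-twin correlations
#'   (`h2 + c2` and `.5 h2 + c2` of the external disorder model).
#' @return An object of class `"correlation_structure"`.
#' @export
correlation_structure <- function(r_within, r_bv_mz, r_bv_dz,
                                  r_cross_mz, r_cross_dz,
                                  r_sz_mz = 0.92, r_sz_dz = 0.515) {
  r <- c(r_within = r_within, r_bv_mz = r_bv_mz, r_bv_dz = r_bv_dz,
         r_cross_mz = r_cross_mz, r_cross_dz = r_cross_dz,
         r_sz_mz = r_sz_mz, r_sz_dz = r_sz_dz)
  stopifnot(all(abs(r) <= 1))
  structure(as.list(r), class = "correlation_structure")
}

# 4x4 implied correlation matrix (sz1, bv1, sz2, bv2) for one zygosity
implied_corr4 <- function(structure, zygosity) {
  s <- structure
  if (zygosity == "MZ") {
    r_sz <- s$r_sz_mz; r_bv <- s$r_bv_mz; r_x <- s$r_cross_mz
  } else {
    r_sz <- s$r_sz_dz; r_bv <- s$r_bv_dz; r_x <- s$r_cross_dz
  }
  rw <- s$r_within
  matrix(c(1,   rw,  r_sz, r_x,
           rw,  1,   r_x,  r_bv,
           r_sz, r_x, 1,   rw,
           r_x, r_bv, rw,  1), 4, 4,
         dimnames = list(c("sz1", "bv1", "sz2", "bv2"),
                         c("sz1", "bv1", "sz2", "bv2")))
}

#' Threshold set for the two-trait liability model
#'
#' @param prevalence disorder prevalence fixing the disorder threshold.
#' @param bv_thresholds strictly increasing z-scale thresholds for the
#'   ordinalised endophenotype (length K-1), shared across members,
#'   zygosities and affection groups.
#' @return An object of class `"threshold_set"`.
#' @export
threshold_set <- function(prevalence, bv_thresholds) {
  stopifnot(all(diff(bv_thresholds) > 0))
  structure(list(prevalence = prevalence,
                 sz_threshold = threshold_from_prevalence(prevalence),
                 bv_thresholds = as.numeric(bv_thresholds)),
            class = "threshold_set")
}

# Aggregate long-format categorized records into pair/singleton cell counts.
# Category 0 (or NA) in bv_cat means "endophenotype unobserved".
build_cell_counts <- function(data) {
  stopifnot(all(c("pair_id", "zygosity", "member", "affected", "bv_cat")
                %in% names(data)))
  d <- data[order(data$pair_id, data$member), ]
  d$bv_cat[is.na(d$bv_cat)] <- 0L
  cnt <- table(d$pair_id)
  if (any(cnt > 2)) stop("more than two members share a pair_id", call. = FALSE)
  single_ids <- names(cnt)[cnt == 1]
  is_single <- as.character(d$pair_id) %in% single_ids
  s <- d[is_single, ]
  p <- d[!is_single, ]
  res <- list()
  for (z in c("MZ", "DZ")) {
    pz <- p[p$zygosity == z, ]
    if (nrow(pz) > 0) {
      i1 <- seq(1, nrow(pz), by = 2)
      key <- paste(pz$affected[i1], pz$bv_cat[i1],
                   pz$affected[i1 + 1], pz$bv_cat[i1 + 1])
      tab <- table(key)
      parts <- do.call(rbind, lapply(strsplit(names(tab), " "), as.integer))
      res[[paste0("pairs_", z)]] <-
        list(sz1 = parts[, 1], bv1 = parts[, 2], sz2 = parts[, 3],
             bv2 = parts[, 4], n = as.integer(tab))
    }
    sz <- s[s$zygosity == z, ]
    if (nrow(sz) > 0) {
      key <- paste(sz$affected, sz$bv_cat)
      tab <- table(key)
      parts <- do.call(rbind, lapply(strsplit(names(tab), " "), as.integer))
      res[[paste0("singles_", z)]] <-
        list(sz = parts[, 1], bv = parts[, 2], n = as.integer(tab))
    }
  }
  res
}

# Interval bounds on the liability scale for one trait category.
# sz: 0/1 against sz_threshold. bv: category 1..K against bv thresholds;
# category 0 = unobserved = (-Inf, Inf).
sz_bounds <- function(aff, t_sz) {
  lo <- ifelse(aff == 1, t_sz, -Inf)
  hi <- ifelse(aff == 1, Inf, t_sz)
  cbind(lo, hi)
}

bv_bounds <- function(cat, tau) {
  brk <- c(-Inf, tau, Inf)
  lo <- ifelse(cat == 0, -Inf, brk[pmax(cat, 1)])
  hi <- ifelse(cat == 0, Inf, brk[pmax(cat, 1) + 1])
  cbind(lo, hi)
}

# Log-likelihood of aggregated cells under a correlation structure +
# thresholds. Returns -Inf (with attribute boundary = TRUE) if any observed
# cell has non-positive probability.
cells_loglik <- function(cells, structure, thresholds, panel_width = 2.0,
                         gl_pts = 8L, xtrunc = if (gl_pts >= 10) 8.5 else 6.0) {
  t_sz <- thresholds$sz_threshold
  tau <- thresholds$bv_thresholds
  ll <- 0
  for (z in c("MZ", "DZ")) {
    pz <- cells[[paste0("pairs_", z)]]
    if (!is.null(pz)) {
      R <- implied_corr4(structure, z)
      if (!is_psd(R)) return(structure(-Inf, boundary = TRUE))
      b1 <- sz_bounds(pz$sz1, t_sz); b2 <- bv_bounds(pz$bv1, tau)
      b3 <- sz_bounds(pz$sz2, t_sz); b4 <- bv_bounds(pz$bv2, tau)
      lo <- cbind(b1[, 1], b2[, 1], b3[, 1], b4[, 1])
      hi <- cbind(b1[, 2], b2[, 2], b3[, 2], b4[, 2])
      pr <- cpp_rect_probs(R, lo, hi, panel_width, gl_pts, xtrunc)
      if (any(pr <= 0))
        return(structure(-Inf, boundary = TRUE))
      ll <- ll + sum(pz$n * log(pr))
    }
    sz_ <- cells[[paste0("singles_", z)]]
    if (!is.null(sz_)) {
      rw <- structure$r_within
      R2 <- matrix(c(1, rw, rw, 1), 2, 2)
      b1 <- sz_bounds(sz_$sz, t_sz); b2 <- bv_bounds(sz_$bv, tau)
      pr <- cpp_rect_probs(R2, cbind(b1[, 1], b2[, 1]),
                           cbind(b1[, 2], b2[, 2]), panel_width, gl_pts,
                           xtrunc)
      if (any(pr <= 0))
        return(structure(-Inf, boundary = TRUE))
      ll <- ll + sum(sz_$n * log(pr))
    }
  }
  ll
}

is_psd <- function(R, tol = 1e-10) {
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  min(ev) > -tol
}

#' Log-likelihood of categorized twin-pair data
#'
#' Full-information maximum-likelihood objective: each complete pair
#' contributes the log probability of its observed (disorder status,
#' endophenotype category) cell for both members under the zygosity-specific
#' 4-variate normal; singletons (pairs with one missing member) contribute the
#' bivariate cell probability of the observed member, i.e. the missing member
#' is marginalised out.  A member with missing endophenotype category
#' contributes through a degenerate `(-Inf, Inf)` interval.
#'
#' @param structure a [correlation_structure()].
#' @param thresholds a [threshold_set()].
#' @param data long-format twin data with `bv_cat` filled (see [prep_bv()]).
#' @return The log-likelihood; `-Inf` with attribute `boundary = TRUE` when
#'   some observed cell has non-positive probability under the model.
#' @export
pair_table_loglik <- function(structure, thresholds, data) {
  cells <- build_cell_counts(data)
  cells_loglik(cells, structure, thresholds, panel_width = 1.0, gl_pts = 12L)
}
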