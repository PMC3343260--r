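#' Cholesky path coefficients for the bivariate liability model
#'
#' Constructs the nine path coefficients of the bivariate Cholesky ACE model:
#' three common paths from the disorder-side factors to the disorder liability
#' (`a_c`, `c_c`, `e_c`), three common paths from the same factors to the
#' endophenotype (`a_pc`, `c_pc`, `e_pc`), and three endophenotype-specific
#' paths (`a_s`, `c_s`, `e_s`).  Both liabilities are standardised: the squared
#' disorder paths must sum to 1, and the six squared endophenotype paths must
#' sum to 1.
#'
#' @param a_c,c_c,e_c disorder-side common paths (liability SD units).
#' @param a_pc,c_pc,e_pc endophenotype loadings on the disorder-side factors.
#' @param a_s,c_s,e_s endophenotype-specific paths.
#' @param tol tolerance for the unit-variance invariants.
#' @return An object of class `"twin_paths"` (named numeric vector).
#' @seealso [twin_paths_from_components()] for the variance-component
#'   parameterisation, [implied_cov()] for the implied twin-pair covariance.
#' @export
#' @examples
#' # disorder side fixed at h2 = .81, c2 = .11, e2 = .08; no shared paths
#' twin_paths(sqrt(.81), sqrt(.11), sqrt(.08), 0, 0, 0, sqrt(.5), 0, sqrt(.5))
twin_paths <- function(a_c, c_c, e_c, a_pc, c_pc, e_pc, a_s, c_s, e_s,
                       tol = 1e-8) {
  p <- c(a_c = a_c, c_c = c_c, e_c = e_c,
         a_pc = a_pc, c_pc = c_pc, e_pc = e_pc,
         a_s = a_s, c_s = c_s, e_s = e_s)
  stopifnot(is.numeric(p), length(p) == 9L, all(is.finite(p)))
  v1 <- a_c^2 + c_c^2 + e_c^2
  v2 <- a_pc^2 + c_pc^2 + e_pc^2 + a_s^2 + c_s^2 + e_s^2
  if (abs(v1 - 1) > tol)
    stop("disorder liability not standardised: a_c^2 + c_c^2 + e_c^2 = ",
         format(v1), call. = FALSE)
  if (abs(v2 - 1) > tol)
    stop("endophenotype not standardised: sum of squared paths = ",
         format(v2), call. = FALSE)
  structure(p, class = "twin_paths")
}

#' Path coefficients from variance components and factor correlations
#'
#' Builds a [twin_paths()] object from the correlated-factors
#' parameterisation: per-trait variance proportions and cross-trait factor
#' correlations.  The disorder-side paths are the square roots of its variance
#' components; the endophenotype common path for, say, A is
#' `r_g * sqrt(h2_bv)` and its specific path `sqrt(h2_bv * (1 - r_g^2))`,
#' so that the genetic correlation equals `r_g` exactly (and likewise for C
#' and E).  A factor correlation paired with a zero variance component is
#' ignored.
#'
#' @param h2_bv,c2_bv,e2_bv endophenotype variance proportions (sum to 1).
#' @param r_g,r_c,r_e genetic, common- and unique-environmental correlations
#'   between disorder and endophenotype.
#' @param h2_sz,c2_sz,e2_sz disorder variance proportions; defaults are the
#'   meta-analytic schizophrenia estimates used for ascertainment correction.
#' @return A `"twin_paths"` object.
#' @export
#' @examples
#' twin_paths_from_components(h2_bv = .76, c2_bv = 0, e2_bv = .24,
#'                            r_g = -.21, r_e = -.40)
twin_paths_from_components <- function(h2_bv, c2_bv, e2_bv,
                                       r_g = 0, r_c = 0, r_e = 0,
                                       h2_sz = 0.81, c2_sz = 0.11,
                                       e2_sz = 0.08) {
  stopifnot(h2_bv >= 0, c2_bv >= 0, e2_bv >= 0,
            abs(h2_bv + c2_bv + e2_bv - 1) < 1e-8,
            abs(h2_sz + c2_sz + e2_sz - 1) < 1e-8,
            abs(r_g) <= 1, abs(r_c) <= 1, abs(r_e) <= 1)
  if (c2_bv == 0) r_c <- 0
  if (h2_bv == 0) r_g <- 0
  if (e2_bv == 0) r_e <- 0
  twin_paths(a_c = sqrt(h2_sz), c_c = sqrt(c2_sz), e_c = sqrt(e2_sz),
             a_pc = r_g * sqrt(h2_bv),
             c_pc = r_c * sqrt(c2_bv),
             e_pc = r_e * sqrt(e2_bv),
             a_s = sqrt(h2_bv * (1 - r_g^2)),
             c_s = sqrt(c2_bv * (1 - r_c^2)),
             e_s = sqrt(e2_bv * (1 - r_e^2)))
}

#' @export
print.twin_paths <- function(x, digits = 4, ...) {
  cat("Bivariate Cholesky path coefficients\n")
  m <- rbind(common_disorder = x[c("a_c", "c_c", "e_c")],
             common_endo     = x[c("a_pc", "c_pc", "e_pc")],
             specific_endo   = x[c("a_s", "c_s", "e_s")])
  colnames(m) <- c("a", "c", "e")
  print(round(m, digits))
  cat("implied within-person cross-trait r:",
      round(unname(x["a_c"] * x["a_pc"] + x["c_c"] * x["c_pc"] +
                   x["e_c"] * x["e_pc"]), digits), "\n")
  invisible(x)
}

#' Model-implied twin-pair covariance matrix
#'
#' Returns the 4x4 covariance (= correlation) matrix over
#' (disorder liability twin 1, endophenotype twin 1, disorder liability twin 2,
#' endophenotype twin 2) implied by a set of Cholesky paths.  Additive-genetic
#' factors correlate `1` across MZ and `0.5` across DZ co-twins; common
#' environment correlates `1` in both; unique environment is uncorrelated.
#'
#' @param paths a [twin_paths()] object.
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return A symmetric positive semi-definite 4x4 matrix with unit diagonal,
#'   dimnames `c("sz1","bv1","sz2","bv2")`.
#' @export
#' @examples
#' p <- twin_paths_from_components(.76, 0, .24, r_g = -.21, r_e = -.40)
#' implied_cov(p, "MZ")["sz1", "sz2"]   # 0.92 when the disorder side is fixed
implied_cov <- function(paths, zygosity = c("MZ", "DZ")) {
  if (!inherits(paths, "twin_paths"))
    paths <- do.call(twin_paths, as.list(paths))
  zygosity <- match.arg(zygosity)
  alpha <- if (zygosity == "MZ") 1 else 0.5
  p <- as.list(paths)
  r_within <- p$a_c * p$a_pc + p$c_c * p$c_pc + p$e_c * p$e_pc
  r_sz  <- alpha * p$a_c^2 + p$c_c^2
  r_bv  <- alpha * (p$a_pc^2 + p$a_s^2) + (p$c_pc^2 + p$c_s^2)
  r_x   <- alpha * p$a_c * p$a_pc + p$c_c * p$c_pc
  m <- matrix(c(1,        r_within, r_sz,     r_x,
                r_within, 1,        r_x,      r_bv,
                r_sz,     r_x,      1,        r_within,
                r_x,      r_bv,     r_within, 1), 4, 4,
              dimnames = list(c("sz1", "bv1", "sz2", "bv2"),
                              c("sz1", "bv1", "sz2", "bv2")))
  m
}
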