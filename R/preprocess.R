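#' Residualise a measure on covariates by ordinary least squares
#'
#' Regresses the continuous endophenotype on covariates (with an intercept)
#' and returns the residuals.  This is the adjustment applied before
#' ordinalisation: one site indicator (the site processed differently from the
#' rest), sex, age and intracranial volume.
#'
#' @param values numeric response vector.
#' @param covariates `data.frame` or matrix of covariates (no intercept
#'   column; one is added).  May be `NULL` or zero-column, in which case the
#'   values are centred only.
#' @return A list with `residuals` (mean-zero, orthogonal to every covariate
#'   column) and `coefficients` of the fitted regression.
#' @export
#' @examples
#' residualize(c(1, 2, 3, 4), data.frame(x = c(0, 0, 1, 1)))$residuals
residualize <- function(values, covariates = NULL) {
  stopifnot(is.numeric(values))
  n <- length(values)
  if (is.null(covariates) || NCOL(covariates) == 0) {
    X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == n)
    if (anyNA(covariates) || anyNA(values))
      stop("missing values in response or covariates", call. = FALSE)
    all_na <- vapply(covariates, function(x) all(is.na(x)), logical(1))
    if (any(all_na))
      stop("all-missing covariate column(s): ",
           paste(names(covariates)[all_na], collapse = ", "), call. = FALSE)
    X <- stats::model.matrix(~ ., data = covariates)
  }
  p <- ncol(X)
  if (n < p + 2)
    stop("need at least ", p + 2, " complete rows for ", p - 1, " covariates",
         call. = FALSE)
  qx <- qr(X)
  if (qx$rank < p) {
    dep <- colnames(X)[qx$pivot[(qx$rank + 1):p]]
    stop("collinear covariate design; dependent column(s): ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  fit <- lm.fit(X, values)
  list(residuals = unname(fit$residuals),
       coefficients = stats::setNames(fit$coefficients, colnames(X)))
}

#' Ordinalise a vector into k classes at empirical quantiles
#'
#' Cuts a numeric vector into `k` classes with roughly equal counts.
#' Cutpoints are left-continuous (type-1) empirical quantiles at
#' `j/k, j = 1..k-1`; ties at a cutpoint are assigned to the lower class, so
#' class sizes are deterministic but may be unequal in the presence of mass
#' points.
#'
#' @param residuals numeric vector (typically residualised values).
#' @param k number of classes (>= 2); requires at least `k` distinct values.
#' @return A list with `category` (integer vector in `1..k`) and `spec`, an
#'   object of class `"ordinal_spec"` holding `k`, the `cutpoints` and the
#'   class `counts`.
#' @export
#' @examples
#' quantile_bin(1:10, 5)$category
quantile_bin <- function(residuals, k = 5) {
  stopifnot(is.numeric(residuals), k >= 2)
  x <- residuals
  if (anyNA(x)) stop("missing values in input", call. = FALSE)
  if (length(unique(x)) < k)
    stop("degenerate binning: fewer than k = ", k, " distinct values",
         call. = FALSE)
  cut_at <- unname(quantile(x, probs = seq_len(k - 1) / k, type = 1))
  # ties at a cutpoint go to the lower class: category = 1 + #{cutpoints < x}
  category <- 1L + rowSums(outer(x, cut_at, ">"))
  if (any(diff(cut_at) <= 0))
    stop("degenerate binning: non-increasing cutpoints (mass point too large)",
         call. = FALSE)
  spec <- structure(list(k = as.integer(k), cutpoints = cut_at,
                         counts = tabulate(category, k)),
                    class = "ordinal_spec")
  list(category = as.integer(category), spec = spec)
}

#' @export
print.ordinal_spec <- function(x, ...) {
  cat("Ordinal spec: k =", x$k, "\ncutpoints:", signif(x$cutpoints, 5),
      "\ncounts:", x$counts, "\n")
  invisible(x)
}

#' Prepare twin data: residualise and ordinalise the endophenotype
#'
#' Applies [residualize()] (site entered as a single indicator for
#' `site_reference`, plus sex, age, intracranial volume) followed by
#' [quantile_bin()] on the pooled sample (affected and unaffected together),
#' filling the `bv_cat` column.
#'
#' @param data long-format twin data (see [simulate_twins()]).
#' @param k number of endophenotype classes.
#' @param covariates character vector of covariate columns to regress out
#'   (among `"site"`, `"sex"`, `"age"`, `"icv"`); `character(0)` centres only.
#' @param site_reference site coded 1 in the site indicator.
#' @return `data` with `bv_cat` filled and attributes `ordinal_spec` and
#'   `residual_fit`.
#' @export
prep_bv <- function(data, k = 5, covariates = c("site", "sex", "age", "icv"),
                    site_reference = "Helsinki") {
  stopifnot("bv" %in% names(data))
  cov_df <- NULL
  if (length(covariates) > 0) {
    cov_df <- data[intersect(covariates, names(data))]
    if ("site" %in% names(cov_df))
      cov_df$site <- as.integer(cov_df$site == site_reference)
  }
  res <- residualize(data$bv, cov_df)
  qb <- quantile_bin(res$residuals, k)
  data$bv_cat <- qb$category
  attr(data, "ordinal_spec") <- qb$spec
  attr(data, "residual_fit") <- res$coefficients
  data
}
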