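# Independent numeric oracles, deliberately on a different code path from the
# package internals (stats::integrate conditioning instead of the compiled
# Genz/Gauss-Legendre machinery).

# P(X > h, Y > k) by 1-D adaptive integration of the conditional normal CDF
bvnu_oracle <- function(h, k, r) {
  if (r == 0) return(pnorm(-h) * pnorm(-k))
  f <- function(x) dnorm(x) * pnorm((k - r * x) / sqrt(1 - r^2),
                                    lower.tail = FALSE)
  stats::integrate(f, h, Inf, rel.tol = 1e-12, abs.tol = 1e-14)$value
}

bvn_rect_oracle <- function(r, lower, upper) {
  bvnu_oracle(lower[1], lower[2], r) - bvnu_oracle(upper[1], lower[2], r) -
    bvnu_oracle(lower[1], upper[2], r) + bvnu_oracle(upper[1], upper[2], r)
}

# brute-force tensor Gauss-Legendre integration of the explicit 4-D density
# over a finite rectangle (nodes via Golub-Welsch eigendecomposition)
gl_nodes <- function(n, a, b) {
  i <- seq_len(n - 1)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- beta
  J[cbind(i + 1, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  list(x = (a + b) / 2 + (b - a) / 2 * e$values,
       w = (b - a) / 2 * 2 * e$vectors[1, ]^2)
}

mvn_rect_grid_oracle <- function(R, lower, upper, n = 32) {
  qs <- Map(function(a, b) gl_nodes(n, a, b), lower, upper)
  pts <- as.matrix(expand.grid(lapply(qs, `[[`, "x")))
  wts <- as.matrix(expand.grid(lapply(qs, `[[`, "w")))
  w <- apply(wts, 1, prod)
  Ri <- solve(R)
  dens <- exp(-0.5 * rowSums((pts %*% Ri) * pts)) /
    ((2 * pi)^(ncol(R) / 2) * sqrt(det(R)))
  sum(w * dens)
}

# tetrachoric log-likelihood of a 2x2 table of (affected, low/high) counts
# at thresholds (t1, t2), using the integrate-based oracle only
tetrachoric_ll_oracle <- function(r, counts, t1, t2) {
  p11 <- bvnu_oracle(t1, t2, r)                    # both high
  p10 <- pnorm(-t1) - p11
  p01 <- pnorm(-t2) - p11
  p00 <- 1 - p11 - p10 - p01
  p <- c(p00, p01, p10, p11)
  if (any(p <= 0)) return(-Inf)
  sum(counts * log(p))
}
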