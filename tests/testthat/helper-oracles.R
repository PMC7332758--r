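## Independent oracles used to freeze expected values.  Each oracle is a
## direct/brute-force route, separate from the package's implementation.

## Two-sided Fisher exact p by exhaustive hypergeometric enumeration
## (point-probability rule) for a 2x2 table (a b / c d).
fisher_enum_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) return(1)
  lo <- max(0, k - n); hi <- min(k, m)
  xs <- lo:hi
  probs <- dhyper(xs, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

## Posterior mean of the normal+exponential convolution model by
## numerical integration: X = S + B, S ~ Exp(mean alpha), B ~ N(mu,
## sigma^2); returns E[S | X = x].
normexp_posterior_quadrature <- function(x, mu, sigma, alpha) {
  f <- function(s) dexp(s, rate = 1 / alpha) * dnorm(x - s, mu, sigma)
  upper <- x + 10 * sigma + 10 * alpha
  num <- integrate(function(s) s * f(s), 0, upper, rel.tol = 1e-10)$value
  den <- integrate(f, 0, upper, rel.tol = 1e-10)$value
  num / den
}

## Simplex-constrained least squares by grid search at fixed resolution
## (intended for small numbers of cell types).
grid_simplex_ls <- function(X, y, step = 0.01) {
  k <- ncol(X)
  stopifnot(k == 3)
  grid <- seq(0, 1, by = step)
  best <- NULL; best_val <- Inf
  for (w1 in grid) for (w2 in seq(0, 1 - w1, by = step)) {
    w <- c(w1, w2, 1 - w1 - w2)
    v <- sum((y - X %*% w)^2)
    if (v < best_val) { best_val <- v; best <- w }
  }
  best
}

## Genomic inflation via an alternative route: the median is preserved
## under the monotone map p -> qchisq(1-p), so lambda equals the upper
## quantile of chi^2_1 at the median p.
lambda_via_median_p <- function(p) {
  qchisq(median(p), df = 1, lower.tail = FALSE) / qchisq(0.5, df = 1)
}

## Kolmogorov-Smirnov distance by direct ECDF evaluation on the pooled
## support.
ks_distance_grid <- function(x, y) {
  g <- sort(unique(c(x, y)))
  max(abs(ecdf(x)(g) - ecdf(y)(g)))
}

## Predicted genomic inflation of an unadjusted scan, from the
## generator's noiseless systematic matrix: closed-form OLS of the
## systematic component on the realized design, with the measurement
## noise variance added to the residual.
predict_null_lambda <- function(m_sys, noise_var, X) {
  n <- nrow(X); p <- ncol(X)
  XtXi <- chol2inv(chol(crossprod(X)))
  B <- m_sys %*% X %*% XtXi
  res <- m_sys - B %*% t(X)
  s2 <- rowSums(res^2) / (n - p) + noise_var
  tstat <- B[, 2] / sqrt(s2 * XtXi[2, 2])
  median(tstat^2) / qchisq(0.5, df = 1)
}
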