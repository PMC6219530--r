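# Independent oracles used across the suite. These deliberately avoid the
# package's own closed forms: beliefs are combined by gridding densities,
# regressions by the normal equations.

# Moments of the normalised product of two Gaussian densities on a dense grid.
grid_product_posterior <- function(mu1, sd1, mu2, sd2,
                                   lo = -200, hi = 200, n = 400001) {
  x <- seq(lo, hi, length.out = n)
  dens <- dnorm(x, mu1, sd1) * dnorm(x, mu2, sd2)
  w <- dens / sum(dens)
  m <- sum(w * x)
  list(mean = m, sd = sqrt(sum(w * (x - m)^2)), mode = x[which.max(dens)])
}

# Simple linear regression by the normal equations, with the
# population-variance residual SD.
normal_equations_fit <- function(t, r) {
  X <- cbind(1, t)
  beta <- solve(t(X) %*% X, t(X) %*% r)
  res <- r - X %*% beta
  list(bias = beta[1], gain = beta[2], sigma_res = sqrt(mean(res^2)))
}

# Monte-Carlo standard error of a regression slope given residual scatter.
gain_se <- function(sigma_res, n, targets_sd) sigma_res / (sqrt(n) * targets_sd)
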