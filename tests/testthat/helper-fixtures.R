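# Shared fixture builders. Everything is generated in code under fixed seeds.

st_levels <- c("Dolphin", "FloatingObject", "School")

# logistic data with linear effects and no spatial structure
make_logistic_obs <- function(n, beta = c(-1, 0.8, -0.5), seed = 1) {
  withr::local_seed(seed)
  x1 <- rnorm(n); x2 <- rnorm(n)
  eta <- beta[1] + beta[2] * x1 + beta[3] * x2
  data.frame(lon = runif(n, 0, 10), lat = runif(n, 0, 10),
             month = sample.int(12L, n, replace = TRUE),
             set_type = factor(sample(st_levels, n, TRUE), levels = st_levels),
             presence = rbinom(n, 1, plogis(eta)),
             x1 = x1, x2 = x2)
}

linear_spec <- function(covs = c(x1 = "linear", x2 = "linear"),
                        spatial = FALSE, settype = FALSE, ...) {
  model_spec(covariates = covs, include_spatial = spatial,
             include_settype = settype, ...)
}

# independently coded penalized IRLS oracle for ridge-logistic regression
# (prior precision lambda * I); deliberately separate from the package's
# Newton implementation
irls_oracle <- function(X, y, lambda = 1 / 100, tol = 1e-10) {
  b <- rep(0, ncol(X))
  for (i in 1:200) {
    eta <- drop(X %*% b)
    p <- 1 / (1 + exp(-eta))
    W <- p * (1 - p)
    z <- eta + (y - p) / W
    b_new <- solve(t(X) %*% (W * X) + diag(lambda, ncol(X)),
                   t(X) %*% (W * z))
    if (max(abs(b_new - b)) < tol) { b <- b_new; break }
    b <- b_new
  }
  drop(b)
}

# independent Bessel-K1 oracle via the integral representation
# K1(x) = int_0^inf exp(-x cosh t) cosh t dt
besselK1_oracle <- function(x) {
  vapply(x, function(xi)
    stats::integrate(function(t) exp(-xi * cosh(t)) * cosh(t),
                     0, 30, rel.tol = 1e-10)$value, numeric(1))
}

# brute-force pairwise AUC
auc_brute <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

expect_seed_identical <- function(expr1, expr2) {
  expect_identical(expr1, expr2)
}
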