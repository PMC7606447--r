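# Latent-Gaussian inference: RW2 penalties, design assembly, the Gaussian
# approximation against independent oracles, hyperparameter recovery,
# summaries and posterior sampling.

test_that("rw2 penalty has the documented rank and nullspace", {
  R5 <- rw2_precision(5)
  expect_equal(attr(R5, "rank"), 3)
  expect_equal(qr(as.matrix(R5))$rank, 3)
  # linear trends live in the nullspace
  v <- 1:5
  expect_lt(abs(drop(t(v) %*% as.matrix(R5) %*% v)), 1e-9)
  R12 <- rw2_precision(12, cyclic = TRUE)
  expect_equal(attr(R12, "rank"), 11)
  vc <- rep(1, 12)
  expect_lt(abs(drop(t(vc) %*% as.matrix(R12) %*% vc)), 1e-9)
  vcos <- cos(2 * pi * (1:12) / 12)
  expect_gt(drop(t(vcos) %*% as.matrix(R12) %*% vcos), 0)
  expect_error(rw2_precision(3), class = "sdm_config_error")
})

test_that("build_design bins, one-hot encodes and wires the blocks correctly", {
  withr::local_seed(20)
  obs <- make_logistic_obs(400)
  obs$u <- runif(400)
  # intercept only
  d0 <- build_design(obs, linear_spec(covs = character(0)))
  expect_equal(dim(d0$A), c(400L, 1L))
  expect_true(all(as.matrix(d0$A) == 1))
  # quantile binning: near-equal counts
  d1 <- build_design(obs, model_spec(covariates = c(u = "rw2"),
                                     include_spatial = FALSE,
                                     include_settype = FALSE, n_bins = 20))
  bcounts <- Matrix::colSums(d1$A[, -1])
  expect_true(max(bcounts) - min(bcounts) <= 1)
  # dummy encoding: exactly one 1 across the three set-type indicators
  d2 <- build_design(obs, model_spec(covariates = character(0),
                                     include_spatial = FALSE,
                                     include_settype = TRUE,
                                     settype_encoding = "dummy"))
  st_cols <- as.matrix(d2$A[, 2:4])
  expect_true(all(rowSums(st_cols) == 1))
  # one constraint row per smooth
  expect_equal(nrow(d1$constraints), 1)
  expect_error(build_design(transform(obs, u = 1),
                            model_spec(covariates = c(u = "rw2"),
                                       include_spatial = FALSE,
                                       include_settype = FALSE)),
               class = "sdm_config_error")
})

test_that("Gaussian approximation recovers the prior with no data and matches 1-D and IRLS oracles", {
  obs0 <- make_logistic_obs(10)[0, ]
  spec0 <- linear_spec(covs = character(0))
  f0 <- fit_gaussian_approx(build_design(obs0, spec0))
  expect_equal(f0$x_mode, 0)
  expect_equal(f0$sd, 10)  # N(0, 100) prior
  # intercept-only, 25 successes of 100: 1-D numerical-optimization oracle
  withr::local_seed(22)
  obs1 <- make_logistic_obs(100)
  obs1$presence <- rep(c(1, 0), c(25, 75))
  f1 <- fit_gaussian_approx(build_design(obs1, spec0))
  oracle <- optimize(function(a)
    -(sum(obs1$presence * a - log(1 + exp(a))) - a^2 / 200),
    c(-5, 5), tol = 1e-10)$minimum
  expect_equal(f1$x_mode, oracle, tolerance = 1e-6)
  expect_lt(abs(f1$x_mode), abs(qlogis(0.25)))  # shrunk toward 0
  # 2-covariate model vs independently coded penalized IRLS
  obs2 <- make_logistic_obs(200, seed = 23)
  d2 <- build_design(obs2, linear_spec())
  f2 <- fit_gaussian_approx(d2)
  X <- as.matrix(d2$A)
  expect_equal(f2$x_mode, unname(irls_oracle(X, obs2$presence)), tolerance = 1e-6)
})

test_that("with a Gaussian likelihood the approximation equals the conjugate posterior", {
  withr::local_seed(24)
  obs <- make_logistic_obs(150)
  obs$presence <- NULL
  d <- build_design(transform(obs, presence = 0), linear_spec())
  yg <- rnorm(150, 1 + 0.5 * obs$x1, 1.3)
  d$y <- yg
  sig <- 1.3
  f <- fit_gaussian_approx(d, family = "gaussian", gaussian_sd = sig)
  X <- as.matrix(d$A)
  Qpost <- diag(1 / 100, 3) + crossprod(X) / sig^2
  mu <- solve(Qpost, crossprod(X, yg) / sig^2)
  expect_equal(f$x_mode, unname(drop(mu)), tolerance = 1e-8)
  expect_equal(as.matrix(f$Sigma), solve(Qpost), tolerance = 1e-8)
})

test_that("smoothing precision of an RW2 effect is recovered from simulated data", {
  nb <- 20
  Rm <- as.matrix(rw2_precision(nb))
  ev <- eigen(Rm, symmetric = TRUE)
  pos <- ev$values > 1e-8
  theta0 <- 1     # true log smoothing precision
  errs <- sapply(1:10, function(rep) {
    withr::local_seed(300 + rep)
    s <- ev$vectors[, pos] %*% (rnorm(sum(pos)) / sqrt(exp(theta0) * ev$values[pos]))
    s <- drop(s) - mean(s)
    n <- 4000
    lev <- sample.int(nb, n, TRUE)
    x <- (lev - 0.5) / nb
    y <- rbinom(n, 1, plogis(s[lev]))
    obs <- data.frame(lon = runif(n), lat = runif(n), month = 1L,
                      set_type = factor("Dolphin", levels = st_levels),
                      presence = y, u = x)
    f <- fit_sdm(obs, model_spec(covariates = c(u = "rw2"),
                                 include_spatial = FALSE,
                                 include_settype = FALSE, n_bins = nb),
                 control = list(grid_mixture = FALSE))
    f$theta_hat - theta0
  })
  expect_lt(abs(mean(errs)), 0.7)
  expect_gt(mean(abs(errs) < 1.5), 0.7)
})

test_that("posterior summaries follow the Gaussian-mixture quantile convention", {
  s <- gaussian_summary(0.917, 18.239)
  expect_equal(s$q025, 0.917 + qnorm(0.025) * 18.239)
  expect_equal(s$q975, 36.67, tolerance = 0.01)
  expect_equal(gaussian_summary(0, 1)$q5, 0)
  # mixture: mean/sd/quantile aggregation across components
  sm <- gaussian_summary(c(-1, 1), c(1, 2), w = c(0.3, 0.7))
  expect_equal(sm$mean, 0.3 * -1 + 0.7 * 1)
  expect_equal(sm$sd, sqrt(0.3 * (1 + 1) + 0.7 * (4 + 1) - sm$mean^2))
  # fitted model: summary table ordered and covering every latent block
  withr::local_seed(26)
  obs <- make_logistic_obs(300)
  f <- fit_sdm(obs, linear_spec(settype = TRUE))
  sm2 <- f$summaries
  expect_equal(nrow(sm2), f$assembly$d)
  expect_true(all(sm2$q025 <= sm2$q5 & sm2$q5 <= sm2$q975))
  expect_true(all(sm2$sd >= 0))
})

test_that("posterior sampling is seeded, constraint-respecting and centered on the mode", {
  withr::local_seed(27)
  n <- 600
  obs <- make_logistic_obs(n)
  obs$u <- runif(n)
  obs$presence <- rbinom(n, 1, plogis(-0.5 + sin(2 * pi * obs$u)))
  spec <- model_spec(covariates = c(u = "rw2"), include_spatial = FALSE,
                     include_settype = FALSE, n_bins = 12)
  f <- fit_sdm(obs, spec, control = list(grid_mixture = FALSE))
  xs <- sample_posterior(f, 4000, seed = 5)
  xs2 <- sample_posterior(f, 4000, seed = 5)
  expect_identical(xs, xs2)
  # smooth block sums to zero in every draw
  sm_idx <- f$assembly$blocks[[2]]$idx
  expect_lt(max(abs(colSums(xs[sm_idx, ]))), 1e-6)
  # sample mean within 3 SE of the (constrained) posterior mean
  mu <- f$components[[1]]$fit$x_mean
  se <- f$components[[1]]$fit$sd / sqrt(4000)
  expect_true(all(abs(rowMeans(xs) - mu) < 4 * pmax(se, 1e-8)))
})

test_that("credible intervals for fixed effects achieve nominal coverage", {
  beta <- c(-1, 0.8, -0.5)
  hits <- 0; total <- 0
  for (rep in 1:60) {
    obs <- make_logistic_obs(1500, beta = beta, seed = 400 + rep)
    d <- build_design(obs, linear_spec())
    f <- fit_gaussian_approx(d)
    lo <- f$x_mean + qnorm(0.025) * f$sd
    hi <- f$x_mean + qnorm(0.975) * f$sd
    hits <- hits + sum(beta >= lo & beta <= hi)
    total <- total + 3
  }
  expect_gte(hits / total, 0.90)
  expect_lte(hits / total, 0.99)
})
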