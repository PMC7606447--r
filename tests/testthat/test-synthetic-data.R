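# Synthetic observer-bycatch generator: covariate envelopes, determinism,
# field moments, prevalence calibration, effect-curve shapes.

test_that("covariate fields respect their declared envelopes and are reproducible", {
  cfg <- sim_config(n_sets = 100, covariates = c("SST", "Chl"), seed = 11)
  g1 <- generate_covariate_fields(cfg)
  g2 <- generate_covariate_fields(cfg)
  expect_identical(g1$SST$values, g2$SST$values)
  expect_true(all(g1$SST$values >= 16.69 & g1$SST$values <= 29.63))
  expect_true(all(g1$Chl$values >= 0.024 & g1$Chl$values <= 1.83))
  # zero-noise config reduces to the deterministic trend
  cfg0 <- sim_config(n_sets = 100, covariates = c("SST",  "Chl"),
                     noise_sd = 0, seed = 11)
  cfg0b <- sim_config(n_sets = 100, covariates = c("SST", "Chl"),
                      noise_sd = 0, seed = 99)
  expect_equal(generate_covariate_fields(cfg0)$SST$values,
               generate_covariate_fields(cfg0b)$SST$values)
  expect_error(sim_config(covariates = "NotAVariable"),
               class = "sdm_config_error")
})

test_that("spatial field draws have the requested moments and Matern correlation", {
  withr::local_seed(4)
  pts <- cbind(runif(400, 0, 10), runif(400, 0, 10))
  range_r <- 3
  expect_identical(simulate_spatial_field(pts, range_r, 0, seed = 1),
                   rep(0, 400))
  expect_error(simulate_spatial_field(pts, -1, 1, seed = 1),
               class = "sdm_config_error")
  draws <- sapply(1:200, function(s)
    simulate_spatial_field(pts, range_r, 1, seed = s, method = "dense"))
  # marginal variance ~ 1 within Monte-Carlo error
  expect_equal(mean(apply(draws, 1, var)), 1, tolerance = 0.08)
  # correlogram at d = range_r ~ 0.13 (Matern nu = 1 convention)
  D <- as.matrix(dist(pts))
  sel <- which(abs(D - range_r) < 0.15 & upper.tri(D), arr.ind = TRUE)
  sel <- sel[seq_len(min(300, nrow(sel))), , drop = FALSE]
  cors <- vapply(seq_len(nrow(sel)), function(k)
    cor(draws[sel[k, 1], ], draws[sel[k, 2], ]), numeric(1))
  expect_equal(mean(cors), 0.13, tolerance = 0.05)
})

test_that("dense and SPDE simulation paths agree in their correlograms", {
  withr::local_seed(9)
  pts <- cbind(runif(300, 0, 10), runif(300, 0, 10))
  range_r <- 3
  mesh <- build_mesh(pts[chull(pts), ], inner_max_edge = 1,
                     outer_max_edge = 2.5, cutoff = 0.2,
                     extension_width = 4.5, planar = TRUE)
  dd <- sapply(1:120, function(s)
    simulate_spatial_field(pts, range_r, 1, seed = s, method = "dense"))
  ds <- sapply(1:120, function(s)
    simulate_spatial_field(pts, range_r, 1, seed = 1000 + s, method = "spde",
                           mesh = mesh))
  D <- as.matrix(dist(pts))
  bins <- seq(0.25, 2 * range_r, by = 0.5)
  corr_at <- function(draws, d0) {
    sel <- which(abs(D - d0) < 0.25 & upper.tri(D), arr.ind = TRUE)
    sel <- sel[seq_len(min(200, nrow(sel))), , drop = FALSE]
    mean(vapply(seq_len(nrow(sel)), function(k)
      cor(draws[sel[k, 1], ], draws[sel[k, 2], ]), numeric(1)))
  }
  for (d0 in bins)
    expect_lt(abs(corr_at(dd, d0) - corr_at(ds, d0)), 0.05 + 2 * 0.04)
})

test_that("observation simulator matches its Bernoulli ground truth", {
  # all effects zero, alpha0 = 0 -> prevalence ~ 0.5
  cfg <- sim_config(n_sets = 10000, zero_curves = TRUE,
                    beta_settype = c(Dolphin = 0, FloatingObject = 0, School = 0),
                    field_params = list(range_r = 8, sigma_w = 0),
                    prevalence_target = NULL, alpha0 = 0, seed = 21)
  sim <- simulate_observations(cfg, generate_covariate_fields(cfg))
  expect_equal(mean(sim$obs$presence), 0.5, tolerance = 3 * sqrt(0.25 / 10000))
  expect_true(all(sim$obs$month %in% 1:12))
  expect_true(all(sim$obs$presence %in% 0:1))
  # bisection hits the observer-data prevalence regime (~0.5%)
  cfg2 <- sim_config(n_sets = 20000, prevalence_target = 0.005, seed = 22)
  sim2 <- simulate_observations(cfg2, generate_covariate_fields(cfg2))
  expect_equal(sim2$truth$prevalence, 0.005, tolerance = 1e-6)
  expect_lt(abs(mean(sim2$obs$presence) - 0.005),
            3 * sqrt(0.005 * 0.995 / 20000))
  # fixed seed -> bit-identical tables
  sim2b <- simulate_observations(cfg2, generate_covariate_fields(cfg2))
  expect_identical(sim2$obs, sim2b$obs)
  # simulated y mean tracks mean true pi
  expect_lt(abs(mean(sim$obs$presence) - mean(sim$truth$pi)),
            3 * sqrt(0.25 / 10000))
})

test_that("spatial residual autocorrelation appears iff the field is on (Moran's I)", {
  skip_if_not_installed("ape")
  base <- list(n_sets = 800, zero_curves = TRUE,
               beta_settype = c(Dolphin = 0, FloatingObject = 0, School = 0),
               prevalence_target = 0.3, seed = 31)
  cfg_f <- do.call(sim_config, c(base, list(
    field_params = list(range_r = 8, sigma_w = 1.5))))
  cfg_0 <- do.call(sim_config, c(base, list(
    field_params = list(range_r = 8, sigma_w = 0))))
  moran_p <- function(sim) {
    r <- sim$obs$presence - mean(sim$obs$presence)
    d <- as.matrix(dist(cbind(sim$obs$lon, sim$obs$lat)))
    w <- 1 / (d + 0.5); diag(w) <- 0
    ape::Moran.I(r, w, alternative = "greater")
  }
  m_f <- moran_p(simulate_observations(cfg_f, generate_covariate_fields(cfg_f)))
  m_0 <- moran_p(simulate_observations(cfg_0, generate_covariate_fields(cfg_0)))
  expect_lt(m_f$p.value, 0.01)
  expect_gt(m_0$p.value, 0.05)
})

test_that("true effect curves have the documented shapes", {
  # chlorophyll dome peaks between 0.1 and 0.2 mg m-3
  xs <- seq(0.024, 1.83, length.out = 2000)
  expect_true(xs[which.max(true_effect_curve("Chl", xs))] >= 0.1)
  expect_true(xs[which.max(true_effect_curve("Chl", xs))] <= 0.2)
  # oxygen window peaks between 210 and 220 mg/l
  xo <- seq(193.605, 252.1, length.out = 2000)
  peak_o <- xo[which.max(true_effect_curve("O2", xo))]
  expect_true(peak_o >= 210 && peak_o <= 220)
  # SSH monotone decreasing
  expect_lt(true_effect_curve("SSH", 0.6), true_effect_curve("SSH", 0.0))
  # month cosine peaks in boreal winter (January)
  expect_equal(which.max(true_effect_curve("month", 1:12)), 1)
  # deterministic
  expect_identical(true_effect_curve("Chl", 0.5), true_effect_curve("Chl", 0.5))
  expect_error(true_effect_curve("Chl", 5), class = "sdm_domain_error")
})
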