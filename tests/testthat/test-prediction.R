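# Prediction grids, posterior surfaces, the latent field surface, raster I/O.

test_that("prediction_grid follows the raster convention", {
  g <- prediction_grid(list(lon = c(0, 1), lat = c(0, 1)), 0.25)
  expect_equal(nrow(g), 16)
  expect_equal(attr(g, "nrow"), 4)
  # centers offset by half a cell from the edges
  expect_equal(min(g$lon), 0.125)
  expect_equal(max(g$lat), 0.875)
  # first row is the northernmost, west to east
  expect_equal(g$lat[1], 0.875)
  expect_lt(g$lon[1], g$lon[2])
  g2 <- prediction_grid(list(lon = c(0, 1), lat = c(0, 1)), 0.125)
  expect_equal(nrow(g2), 64)
  expect_error(prediction_grid(list(lon = c(0, 0.1), lat = c(0, 0.1)), 1),
               class = "sdm_config_error")
})

test_that("ESRI ASCII rasters round-trip bit-exactly", {
  withr::local_seed(50)
  vals <- matrix(rnorm(12), 4, 3)
  vals[2, 2] <- NA
  g <- sdm_grid(vals, xll = -10, yll = 5, cellsize = 0.5)
  path <- tempfile(fileext = ".asc")
  write_raster(g, path)
  hdr <- readLines(path, n = 6)
  expect_match(hdr[1], "^ncols 3$")
  expect_match(hdr[2], "^nrows 4$")
  expect_match(hdr[6], "NODATA_value -9999")
  # masked cell written as NODATA
  expect_true(any(grepl("-9999", readLines(path)[-(1:6)])))
  g2 <- read_raster(path)
  expect_identical(g2$values, g$values)
  expect_identical(c(g2$xll, g2$yll, g2$cellsize), c(-10, 5, 0.5))
})

test_that("intercept-only model predicts a flat surface with valid layers", {
  withr::local_seed(51)
  cfg <- sim_config(n_sets = 400, covariates = "SST", zero_curves = TRUE,
                    field_params = list(range_r = 8, sigma_w = 0),
                    prevalence_target = 0.3, month_effect = FALSE, seed = 51)
  grids <- generate_covariate_fields(cfg)
  sim <- simulate_observations(cfg, grids)
  spec <- model_spec(covariates = character(0), include_spatial = FALSE,
                     include_settype = FALSE)
  f <- fit_sdm(sim$obs, spec)
  g <- prediction_grid(list(lon = range(sim$obs$lon), lat = range(sim$obs$lat)), 2)
  s <- predict_surface(f, g, grids, n_samples = 800, seed = 3)
  mu <- s$mean$values
  expect_lt(diff(range(mu, na.rm = TRUE)), 1e-9)    # constant layer
  expect_equal(mean(mu, na.rm = TRUE),
               mean(plogis(sample_eta(f, 4000, 1)[1, ])), tolerance = 0.02)
  for (nm in c("mean", "sd", "q025", "q975")) {
    v <- s[[nm]]$values
    expect_true(all(is.na(v) | (v >= 0 & v <= 1)))
  }
  expect_true(all(s$q025$values <= s$mean$values + 1e-9, na.rm = TRUE))
  expect_true(all(s$mean$values <= s$q975$values + 1e-9, na.rm = TRUE))
  expect_error(spatial_effect_surface(f, g), class = "sdm_config_error")
})

test_that("sample and Gaussian prediction routes agree within Monte-Carlo error", {
  withr::local_seed(52)
  cfg <- sim_config(n_sets = 800, covariates = c("Chl", "SST"),
                    field_params = list(range_r = 8, sigma_w = 0),
                    prevalence_target = 0.2, seed = 52)
  grids <- generate_covariate_fields(cfg)
  sim <- simulate_observations(cfg, grids)
  spec <- model_spec(covariates = c(Chl = "rw2"), include_spatial = FALSE,
                     include_settype = TRUE, n_bins = 10)
  f <- fit_sdm(sim$obs, spec, control = list(grid_mixture = FALSE))
  g <- prediction_grid(list(lon = range(sim$obs$lon), lat = range(sim$obs$lat)), 4)
  s1 <- predict_surface(f, g, grids, n_samples = 2000, seed = 4)
  s2 <- predict_surface(f, g, grids, method = "gaussian")
  mc_se <- s1$sd$values / sqrt(2000)
  expect_true(all(abs(s1$mean$values - s2$mean$values) <=
                    3 * mc_se + 0.01, na.rm = TRUE))
  # mean layer stable across seeds
  s3 <- predict_surface(f, g, grids, n_samples = 2000, seed = 99)
  expect_true(all(abs(s1$mean$values - s3$mean$values) <=
                    6 * mc_se + 0.005, na.rm = TRUE))
})

test_that("predicted probabilities and latent field recover simulation truth", {
  withr::local_seed(53)
  n <- 2000
  lon <- runif(n, 0, 20); lat <- runif(n, 0, 20)
  w <- simulate_spatial_field(cbind(lon, lat), 6, 1.2, seed = 8)
  x1 <- rnorm(n)
  eta <- -1 + 1.5 * x1 + w
  obs <- data.frame(lon = lon, lat = lat, month = 1L,
                    set_type = factor("Dolphin", levels = st_levels),
                    presence = rbinom(n, 1, plogis(eta)), x1 = x1)
  mesh <- build_mesh(cbind(lon, lat), inner_max_edge = 3, outer_max_edge = 7,
                     planar = TRUE)
  spec <- model_spec(covariates = c(x1 = "linear"), include_spatial = TRUE,
                     include_settype = FALSE)
  f <- fit_sdm(obs, spec, mesh,
               control = list(optimizer = "grid", grid_mixture = FALSE,
                              theta_grid = list(log_range = c(1.3, 1.9),
                                                log_sigma = c(-0.2, 0.3))))
  # held-in probability recovery
  p_hat <- predict_prob(f, obs, n_samples = 300, seed = 5)
  expect_gt(cor(p_hat, plogis(eta)), 0.8)
  # latent field surface correlates with the true field at the same points
  fb <- Filter(function(b) b$type == "field", f$assembly$blocks)[[1]]
  pr <- make_projector(mesh, cbind(lon, lat), planar = TRUE)
  w_hat <- as.vector(pr$A %*% f$components[[1]]$fit$x_mean[fb$idx])
  expect_gt(cor(w_hat, w), 0.6)
  # grid version: vertices reproduce posterior vertex means exactly
  gv <- data.frame(lon = mesh$loc[1:25, 1], lat = mesh$loc[1:25, 2])
  attr(gv, "nrow") <- 5; attr(gv, "ncol") <- 5
  attr(gv, "xll") <- 0; attr(gv, "yll") <- 0; attr(gv, "cellsize") <- 1
  fe <- spatial_effect_surface(f, gv)
  expect_equal(as.vector(t(fe$field_mean$values)),
               f$components[[1]]$fit$x_mean[fb$idx][1:25] *
                 f$weights[1] + 0, tolerance = 1e-6)
})
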