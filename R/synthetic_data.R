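# Synthetic observer-bycatch generator.
#
# Emulates the structure of a tropical purse-seine observer dataset: fishing
# sets clustered in space (effort concentrates on productive grounds), a
# three-level set-type factor (Dolphin / FloatingObject / School), per-set
# environmental covariates drawn from gridded fields, very low prevalence of
# the bycatch species, nonlinear covariate effects, and a Matern spatial
# residual field. Every draw carries a ground-truth sidecar so parameter
# recovery can be tested without re-deriving the truth.

#' Environmental covariate ranges
#'
#' Units and (min, max) envelopes of the oceanographic and topographic
#' covariates used by the generator. SSH is in meters, oxygen and nitrate in
#' mg/l, chlorophyll and phytoplankton in mg m-3.
#'
#' @return data.frame with columns `var`, `unit`, `mean`, `min`, `max`.
#' @export
covariate_ranges <- function() {
  data.frame(
    var  = c("Depth", "Distance", "SST", "Sal", "SSH", "Chl", "Phy",
             "O2", "Ni", "Vel", "Ke", "Heading"),
    unit = c("m", "km*1000", "degC", "psu", "m", "mg m-3", "mg m-3",
             "mg/l", "mg/l", "m/s", "m/s", "deg"),
    mean = c(3732.416, 8.907, 25.276, 34.371, 0.246, 0.217, 1.611,
             209.613, 4.785, 0.247, 0.046, 213.341),
    min  = c(476.67, 0.059, 16.69, 26.943, -0.001, 0.024, 0.427,
             193.605, 0, 0.001, 0, 0),
    max  = c(4535.7, 23.026, 29.63, 36.453, 0.627, 1.83, 15.369,
             252.1, 20.173, 1.161, 0.674, 359.85),
    stringsAsFactors = FALSE)
}

cov_range <- function(name) {
  tab <- covariate_ranges()
  i <- match(name, tab$var)
  if (is.na(i)) stop_sdm("unknown covariate '", name, "'", class = "sdm_config_error")
  c(tab$min[i], tab$max[i])
}

set_type_levels <- c("Dolphin", "FloatingObject", "School")

#' Simulation configuration
#'
#' Defaults describe the study conditions the generator emulates: an eastern
#' tropical Pacific style bounding box, spatially clustered fishing effort,
#' prevalence near 0.5% (about 1 presence in 200 sets, the observer-data
#' regime), dome/window/monotone covariate responses, a winter-peaking
#' seasonal cycle, and a Matern (nu = 1) spatial residual field.
#'
#' @param n_sets number of fishing sets.
#' @param bbox list with `lon` and `lat` (min, max) in degrees.
#' @param effort_clusters list(n = parent count, spread = offspring SD, deg).
#' @param alpha0 intercept on the logit scale; overridden when
#'   `prevalence_target` is set (bisection calibrates the intercept).
#' @param prevalence_target target mean presence probability, or NULL.
#' @param beta_settype named vector of set-type effects (logit scale).
#' @param settype_probs sampling probabilities of the three set types.
#' @param covariates names of environmental covariates to simulate.
#' @param effect_curves named list of functions f(x) on the logit scale; names
#'   not listed get the built-in [true_effect_curve()] shape; use `zero_curves
#'   = TRUE` for a null model.
#' @param month_effect logical: include the seasonal cycle.
#' @param zero_curves logical: force all covariate and month effects to zero.
#' @param field_params list(range_r = Matern range in degrees, sigma_w =
#'   marginal SD of the field).
#' @param grid_cellsize covariate raster resolution in degrees.
#' @param noise_sd stochastic texture SD of covariate fields (fraction of the
#'   0-1 normalized scale).
#' @param seed integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_sets = 5000,
                       bbox = list(lon = c(-120, -80), lat = c(-15, 25)),
                       effort_clusters = list(n = 15, spread = 2.0),
                       alpha0 = 0,
                       prevalence_target = 0.005,
                       beta_settype = c(Dolphin = 0.4, FloatingObject = -0.6,
                                        School = 0.2),
                       settype_probs = c(1, 1, 1) / 3,
                       covariates = c("Chl", "O2", "SSH", "Ni"),
                       effect_curves = NULL,
                       month_effect = TRUE,
                       zero_curves = FALSE,
                       field_params = list(range_r = 8, sigma_w = 1),
                       grid_cellsize = 0.5,
                       noise_sd = 0.1,
                       seed = 1L) {
  if (n_sets < 1) stop_sdm("n_sets must be >= 1", class = "sdm_config_error")
  if (diff(bbox$lon) <= 0 || diff(bbox$lat) <= 0)
    stop_sdm("bbox must be non-degenerate", class = "sdm_config_error")
  if (field_params$sigma_w < 0)
    stop_sdm("sigma_w must be >= 0", class = "sdm_config_error")
  if (abs(sum(settype_probs) - 1) > 1e-8)
    stop_sdm("settype_probs must sum to 1", class = "sdm_config_error")
  for (v in covariates) cov_range(v)  # validates names
  structure(list(n_sets = as.integer(n_sets), bbox = bbox,
                 effort_clusters = effort_clusters, alpha0 = alpha0,
                 prevalence_target = prevalence_target,
                 beta_settype = beta_settype, settype_probs = settype_probs,
                 covariates = covariates, effect_curves = effect_curves,
                 month_effect = month_effect, zero_curves = zero_curves,
                 field_params = field_params, grid_cellsize = grid_cellsize,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "sim_config")
}

#' Built-in true effect curves
#'
#' Deterministic response shapes on the logit scale used as simulation ground
#' truth: chlorophyll is a dome peaking between 0.1 and 0.2 mg m-3 (log-scale
#' Gaussian at 0.15), oxygen a window peaking between 210 and 220 mg/l,
#' sea-surface height monotone decreasing, nitrate a low-to-medium preference
#' dome, SST a thermal-optimum dome, and month a cosine peaking in boreal
#' winter (January).
#'
#' @param name covariate name (one of Chl, O2, SSH, Ni, SST, month).
#' @param x evaluation points; must lie inside the covariate's declared range
#'   (month: 1..12).
#' @return numeric vector f(x).
#' @export
true_effect_curve <- function(name, x) {
  if (name == "month") {
    if (any(x < 1 | x > 12)) stop_sdm("month out of range 1..12",
                                      class = "sdm_domain_error")
    return(1.0 * cos(2 * pi * (x - 1) / 12))
  }
  r <- cov_range(name)
  if (any(x < r[1] - 1e-9 | x > r[2] + 1e-9))
    stop_sdm(name, " value out of range [", r[1], ", ", r[2], "]",
             class = "sdm_domain_error")
  switch(name,
    Chl = 1.6 * exp(-(log(pmax(x, 1e-6)) - log(0.15))^2 / (2 * 0.55^2)),
    O2  = 1.6 * exp(-(x - 215)^2 / (2 * 8^2)),
    SSH = -2.0 * (x - mean(r)) / (diff(r) / 2),
    Ni  = 1.2 * exp(-(x - 4)^2 / (2 * 4^2)),
    SST = 1.0 * exp(-(x - 26)^2 / (2 * 2.5^2)),
    stop_sdm("no built-in effect curve for '", name, "'",
             class = "sdm_config_error"))
}

# Deterministic smooth trend on the unit square, coefficients hashed from the
# variable name so every variable gets a distinct but reproducible surface.
cov_trend <- function(name, u, v) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  a <- 1 + (h %% 3); b <- 1 + ((h %/% 3) %% 2)
  p1 <- (h %% 7) / 7 * 2 * pi; p2 <- (h %% 11) / 11 * 2 * pi
  t <- 0.5 + 0.22 * sin(2 * pi * (a * u + 0.6 * v) / 2 + p1) +
    0.18 * cos(2 * pi * (b * v - 0.4 * u) / 2 + p2) + 0.12 * (v - 0.5)
  pmin(pmax(t, 0), 1)
}

#' Generate gridded covariate fields
#'
#' One raster per requested covariate over the configured bounding box: a
#' deterministic smooth trend plus seeded smooth stochastic texture, rescaled
#' into the covariate's declared (min, max) envelope and clipped there.
#'
#' @param config a [sim_config()].
#' @return named list of [sdm_grid] layers (class `covariate_grids`).
#' @export
generate_covariate_fields <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(config$seed)
  cs <- config$grid_cellsize
  ncols <- max(2L, ceiling(diff(config$bbox$lon) / cs))
  nrows <- max(2L, ceiling(diff(config$bbox$lat) / cs))
  lon <- config$bbox$lon[1] + (seq_len(ncols) - 0.5) * cs
  lat_n2s <- rev(config$bbox$lat[1] + (seq_len(nrows) - 0.5) * cs)
  u <- (lon - config$bbox$lon[1]) / diff(config$bbox$lon)
  v <- (lat_n2s - config$bbox$lat[1]) / diff(config$bbox$lat)
  U <- matrix(u, nrows, ncols, byrow = TRUE)
  V <- matrix(v, nrows, ncols)
  out <- list()
  for (name in config$covariates) {
    r <- cov_range(name)
    t01 <- cov_trend(name, U, V)
    if (config$noise_sd > 0) {
      # smooth texture: sum of random long-wavelength cosines
      K <- 20
      amp <- config$noise_sd / sqrt(K / 2)
      z <- matrix(0, nrows, ncols)
      for (k in seq_len(K)) {
        w <- runif(2, -3, 3); ph <- runif(1, 0, 2 * pi)
        z <- z + amp * cos(2 * pi * (w[1] * U + w[2] * V) + ph)
      }
      t01 <- pmin(pmax(t01 + z, 0), 1)
    }
    out[[name]] <- sdm_grid(r[1] + t01 * (r[2] - r[1]),
                            xll = config$bbox$lon[1], yll = config$bbox$lat[1],
                            cellsize = cs)
  }
  class(out) <- c("covariate_grids", "list")
  out
}

#' Simulate a zero-mean Matern (nu = 1) Gaussian field
#'
#' Draws one realization at arbitrary locations, either by dense Cholesky of
#' the closed-form Matern covariance (exact, small n) or through the SPDE
#' finite-element precision on an internal mesh (sparse, large n).
#'
#' @param points two-column matrix of planar coordinates (degrees).
#' @param range_r Matern range (distance at which correlation drops to ~0.13),
#'   same units as `points`.
#' @param sigma_w marginal standard deviation (>= 0).
#' @param seed integer seed.
#' @param method "dense", "spde", or "auto" (dense up to 2000 points).
#' @param mesh optional prebuilt planar `sdm_mesh` reused by the SPDE path
#'   (avoids re-triangulating across replicate draws).
#' @return numeric vector of field values, one per point.
#' @export
simulate_spatial_field <- function(points, range_r, sigma_w, seed,
                                   method = c("auto", "dense", "spde"),
                                   mesh = NULL) {
  method <- match.arg(method)
  points <- as.matrix(points)
  if (range_r <= 0) stop_sdm("range_r must be > 0", class = "sdm_config_error")
  if (sigma_w < 0) stop_sdm("sigma_w must be >= 0", class = "sdm_config_error")
  n <- nrow(points)
  if (sigma_w == 0) return(rep(0, n))
  if (method == "auto") method <- if (n <= 2000) "dense" else "spde"
  withr::local_seed(seed)
  kappa <- sqrt(8) / range_r
  if (method == "dense") {
    D <- cross_dist(points, points)
    S <- sigma_w^2 * matern_correlation(D, kappa)
    L <- chol(S + diag(1e-10 * sigma_w^2, n))
    drop(crossprod(L, rnorm(n)))
  } else {
    if (is.null(mesh)) {
      rx <- range(points[, 1]); ry <- range(points[, 2])
      edge <- max(range_r / 3, max(diff(rx), diff(ry)) / 40)
      mesh <- build_mesh(points[chull(points), , drop = FALSE],
                         inner_max_edge = edge, outer_max_edge = 2.5 * edge,
                         cutoff = edge / 5, extension_width = 1.5 * range_r,
                         planar = TRUE)
    }
    tau <- 1 / (sigma_w * sqrt(4 * pi) * kappa)
    Q <- spde_precision(fem_matrices(mesh), kappa = kappa, tau = tau)
    L <- Matrix::Cholesky(Q, LDL = FALSE, perm = TRUE)
    z <- rnorm(nrow(Q))
    x <- as.vector(Matrix::solve(L, Matrix::solve(L, z, system = "Lt"),
                                 system = "Pt"))
    A <- make_projector(mesh, points, planar = TRUE)$A
    w <- as.vector(A %*% x)
    # FEM boundary inflation: rescale to the requested marginal SD
    w * sigma_w / sd(w)
  }
}

#' Simulate an observation table with known ground truth
#'
#' Set locations come from a Thomas-style cluster process (seeded parents,
#' Gaussian offspring) inside the bounding box; covariates are sampled from
#' the supplied rasters at each location; the linear predictor combines the
#' intercept, set-type effects, true covariate curves, the seasonal cycle and
#' a Matern spatial field; presences are Bernoulli draws. When
#' `prevalence_target` is set the intercept is calibrated by bisection so the
#' mean presence probability matches it.
#'
#' @param config a [sim_config()].
#' @param grids covariate rasters from [generate_covariate_fields()] (must
#'   cover the bounding box).
#' @return list with `obs` (data.frame: lon, lat, month, set_type, presence,
#'   covariates) and `truth` (all true parameters, linear predictor, field).
#' @export
simulate_observations <- function(config, grids) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(config$seed)
  n <- config$n_sets
  ncl <- config$effort_clusters$n
  spread <- config$effort_clusters$spread
  px <- runif(ncl, config$bbox$lon[1], config$bbox$lon[2])
  py <- runif(ncl, config$bbox$lat[1], config$bbox$lat[2])
  id <- sample.int(ncl, n, replace = TRUE)
  lon <- pmin(pmax(px[id] + rnorm(n, 0, spread), config$bbox$lon[1]),
              config$bbox$lon[2])
  lat <- pmin(pmax(py[id] + rnorm(n, 0, spread), config$bbox$lat[1]),
              config$bbox$lat[2])
  month <- sample.int(12L, n, replace = TRUE)
  set_type <- factor(sample(set_type_levels, n, replace = TRUE,
                            prob = config$settype_probs),
                     levels = set_type_levels)

  covs <- list()
  for (v in config$covariates) {
    if (is.null(grids[[v]]))
      stop_sdm("covariate grid '", v, "' missing", class = "sdm_data_error")
    covs[[v]] <- grid_sample(grids[[v]], lon, lat)
  }

  f_total <- rep(0, n)
  curves <- list()
  if (!config$zero_curves) {
    for (v in config$covariates) {
      f <- config$effect_curves[[v]] %||% function(x) true_effect_curve(v, x)
      fv <- f(covs[[v]])
      fv <- fv - mean(fv)          # center: level belongs to the intercept
      curves[[v]] <- f
      f_total <- f_total + fv
    }
    if (config$month_effect) {
      fm <- true_effect_curve("month", month)
      f_total <- f_total + (fm - mean(fm))
    }
  }

  sigma_w <- config$field_params$sigma_w
  field <- if (sigma_w > 0) {
    lat0 <- mean(config$bbox$lat)
    simulate_spatial_field(scale_coords(lon, lat, lat0),
                           range_r = config$field_params$range_r,
                           sigma_w = sigma_w,
                           seed = derive_seed(config$seed, "field"))
  } else rep(0, n)

  beta <- config$beta_settype[as.character(set_type)]
  eta0 <- f_total + beta + field
  alpha0 <- config$alpha0
  if (!is.null(config$prevalence_target)) {
    tgt <- config$prevalence_target
    fn <- function(a) mean(plogis(a + eta0)) - tgt
    alpha0 <- uniroot(fn, c(-40, 20), tol = 1e-10)$root
  }
  eta <- alpha0 + eta0
  pi_true <- plogis(eta)
  y <- rbinom(n, 1L, pi_true)

  obs <- data.frame(lon = lon, lat = lat, month = month,
                    set_type = set_type, presence = y,
                    stringsAsFactors = FALSE)
  for (v in names(covs)) obs[[v]] <- covs[[v]]
  truth <- list(alpha0 = alpha0, beta_settype = config$beta_settype,
                field = field, eta = eta, pi = pi_true,
                field_params = config$field_params,
                prevalence = mean(pi_true), seed = config$seed)
  list(obs = obs, truth = truth)
}

#' @importFrom stats uniroot
NULL

#' Write an observation table as CSV
#' @param obs observation data.frame.
#' @param path output path.
#' @export
write_observations <- function(obs, path) {
  write.csv(obs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a ground-truth sidecar as JSON
#' @param truth truth record from [simulate_observations()].
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
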