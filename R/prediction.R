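# Posterior prediction surfaces: gridded mean / SD / 2.5% / 97.5% of the
# occurrence probability, plus the latent spatial-effect surface.

#' Regular cell-center prediction grid
#'
#' Row-major ordering: rows run north to south, columns west to east, matching
#' the ESRI ASCII raster convention; cell centers sit half a cell from the
#' extent edges.
#'
#' @param extent list with `lon` and `lat` (min, max) in degrees.
#' @param cell_size cell size in degrees (> 0).
#' @return data.frame (lon, lat) with attributes `nrow`, `ncol`, `xll`,
#'   `yll`, `cellsize`.
#' @export
prediction_grid <- function(extent, cell_size) {
  if (cell_size <= 0) stop_sdm("cell_size must be > 0", class = "sdm_config_error")
  ncols <- floor(round(diff(extent$lon) / cell_size, 9))
  nrows <- floor(round(diff(extent$lat) / cell_size, 9))
  if (ncols < 1 || nrows < 1)
    stop_sdm("extent smaller than one cell", class = "sdm_config_error")
  lon <- extent$lon[1] + (seq_len(ncols) - 0.5) * cell_size
  lat <- rev(extent$lat[1] + (seq_len(nrows) - 0.5) * cell_size)
  g <- expand.grid(lon = lon, lat = lat)[, c("lon", "lat")]
  g <- g[order(-g$lat, g$lon), ]
  rownames(g) <- NULL
  attr(g, "nrow") <- nrows; attr(g, "ncol") <- ncols
  attr(g, "xll") <- extent$lon[1]; attr(g, "yll") <- extent$lat[1]
  attr(g, "cellsize") <- cell_size
  g
}

grid_layer <- function(grid, values) {
  sdm_grid(matrix(values, attr(grid, "nrow"), attr(grid, "ncol"), byrow = TRUE),
           xll = attr(grid, "xll"), yll = attr(grid, "yll"),
           cellsize = attr(grid, "cellsize"))
}

#' Posterior prediction surface of occurrence probability
#'
#' For each grid cell, covariates are sampled from the supplied rasters, the
#' linear predictor is projected through the fitted model, and cellwise
#' mean / SD / empirical 2.5% and 97.5% quantiles of logit^-1(eta) are
#' computed over posterior draws (the `"samples"` method; `"gaussian"` uses
#' the Gaussian marginals of eta — monotone-transform quantiles and
#' Gauss-Hermite means — and agrees within Monte-Carlo error). Cells outside
#' the inner mesh zone or outside the covariate rasters are masked.
#'
#' @param fit an `sdm_fit`.
#' @param grid a [prediction_grid()].
#' @param covariate_grids named list of `sdm_grid` rasters for the model's
#'   covariates.
#' @param n_samples posterior draws (samples method).
#' @param seed integer seed.
#' @param settype_scenario set-type level assumed at prediction cells (a grid
#'   cell has no fishing mode of its own).
#' @param month_scenario month assumed at prediction cells (1..12).
#' @param method "samples" or "gaussian".
#' @return list of class `prediction_surface` with `sdm_grid` layers `mean`,
#'   `sd`, `q025`, `q975` (probability scale), `field_mean`, `field_sd`
#'   (latent scale, when the model has the field), `mask`, and the warning
#'   counters `clamped`/`outside`.
#' @export
predict_surface <- function(fit, grid, covariate_grids, n_samples = 1000,
                            seed = 1L, settype_scenario = "Dolphin",
                            month_scenario = 1L,
                            method = c("samples", "gaussian")) {
  method <- match.arg(method)
  newdata <- data.frame(lon = grid$lon, lat = grid$lat,
                        month = as.integer(month_scenario),
                        set_type = factor(settype_scenario,
                                          levels = set_type_levels))
  covnames <- unique(unlist(lapply(fit$assembly$blocks, function(b)
    if (b$type %in% c("rw2", "rw2_cyclic") && b$name != "month") b$name
    else if (b$type == "fixed")
      setdiff(b$labels, c("(Intercept)", grep(" set$", b$labels, value = TRUE))))))
  inside_cov <- rep(TRUE, nrow(newdata))
  for (v in covnames) {
    gr <- covariate_grids[[v]]
    if (is.null(gr)) stop_sdm("covariate grid '", v, "' missing",
                              class = "sdm_data_error")
    xmax <- gr$xll + gr$ncol * gr$cellsize; ymax <- gr$yll + gr$nrow * gr$cellsize
    ok <- newdata$lon >= gr$xll & newdata$lon <= xmax &
      newdata$lat >= gr$yll & newdata$lat <= ymax
    inside_cov <- inside_cov & ok
    vals <- rep(NA_real_, nrow(newdata))
    if (any(ok)) vals[ok] <- grid_sample(gr, newdata$lon[ok], newdata$lat[ok])
    if (any(!ok)) vals[!ok] <- mean(vals[ok])  # placeholder; cell masked below
    newdata[[v]] <- vals
  }
  ds <- design_for_newdata(fit, newdata)
  mask <- inside_cov
  if (!is.null(fit$mesh)) {
    ib <- fit$mesh$bbox_inner
    P <- if (fit$mesh$planar) cbind(newdata$lon, newdata$lat) else
      scale_coords(newdata$lon, newdata$lat, fit$mesh$lat0)
    mask <- mask & P[, 1] >= ib[1, 1] & P[, 1] <= ib[1, 2] &
      P[, 2] >= ib[2, 1] & P[, 2] <= ib[2, 2]
  }

  if (method == "samples") {
    xs <- sample_posterior(fit, n_samples, seed)
    ps <- plogis(as.matrix(ds$A %*% xs))
    mu <- rowMeans(ps)
    sdv <- apply(ps, 1, sd)
    qs <- t(apply(ps, 1, quantile, probs = c(0.025, 0.975), names = FALSE))
  } else {
    w <- fit$weights
    mus <- sapply(fit$components, function(cc)
      as.vector(ds$A %*% cc$fit$x_mean))
    vars <- sapply(fit$components, function(cc) {
      AS <- as.matrix(ds$A %*% cc$fit$Sigma)
      rowSums(AS * as.matrix(ds$A))
    })
    gh <- gauss_hermite(20)
    pm <- 0; pm2 <- 0; qlo <- 0; qhi <- 0
    for (i in seq_along(w)) {
      s <- sqrt(pmax(vars[, i], 0))
      pr <- sapply(seq_along(gh$x), function(k)
        plogis(mus[, i] + sqrt(2) * s * gh$x[k]) * gh$w[k] / sqrt(pi))
      m1 <- rowSums(pr)
      pr2 <- sapply(seq_along(gh$x), function(k)
        plogis(mus[, i] + sqrt(2) * s * gh$x[k])^2 * gh$w[k] / sqrt(pi))
      pm <- pm + w[i] * m1
      pm2 <- pm2 + w[i] * rowSums(pr2)
      qlo <- qlo + w[i] * plogis(mus[, i] + qnorm(0.025) * s)
      qhi <- qhi + w[i] * plogis(mus[, i] + qnorm(0.975) * s)
    }
    mu <- pm; sdv <- sqrt(pmax(pm2 - pm^2, 0)); qs <- cbind(qlo, qhi)
  }
  mu[!mask] <- NA; sdv[!mask] <- NA; qs[!mask, ] <- NA

  layers <- list(mean = grid_layer(grid, mu), sd = grid_layer(grid, sdv),
                 q025 = grid_layer(grid, qs[, 1]),
                 q975 = grid_layer(grid, qs[, 2]),
                 mask = grid_layer(grid, as.numeric(mask)))
  if (any(vapply(fit$assembly$blocks, function(b) b$type == "field", logical(1)))) {
    fe <- spatial_effect_surface(fit, grid)
    layers$field_mean <- fe$field_mean
    layers$field_sd <- fe$field_sd
  }
  structure(c(layers, list(clamped = ds$clamped, outside = ds$outside,
                           settype_scenario = settype_scenario,
                           month_scenario = month_scenario, method = method)),
            class = "prediction_surface")
}

#' Latent spatial-effect surface
#'
#' Posterior mean and SD of the spatial field w projected onto the grid, on
#' the latent (logit) scale.
#'
#' @param fit an `sdm_fit` whose spec includes the spatial field.
#' @param grid a [prediction_grid()].
#' @return list with `sdm_grid` layers `field_mean` and `field_sd`.
#' @export
spatial_effect_surface <- function(fit, grid) {
  fb <- Filter(function(b) b$type == "field", fit$assembly$blocks)
  if (!length(fb)) stop_sdm("model has no spatial field",
                            class = "sdm_config_error")
  fb <- fb[[1]]
  pr <- suppressWarnings(make_projector(fit$mesh, cbind(grid$lon, grid$lat)))
  A <- pr$A
  w <- fit$weights
  mu <- 0; m2 <- 0
  for (i in seq_along(w)) {
    f <- fit$components[[i]]$fit
    mi <- as.vector(A %*% f$x_mean[fb$idx])
    AS <- as.matrix(A %*% f$Sigma[fb$idx, fb$idx])
    vi <- rowSums(AS * as.matrix(A))
    mu <- mu + w[i] * mi
    m2 <- m2 + w[i] * (vi + mi^2)
  }
  sdv <- sqrt(pmax(m2 - mu^2, 0))
  mu[!pr$ok] <- NA; sdv[!pr$ok] <- NA
  list(field_mean = grid_layer(grid, mu), field_sd = grid_layer(grid, sdv))
}

# Gauss-Hermite nodes/weights (Golub-Welsch on the Jacobi matrix)
gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = sqrt(pi) * e$vectors[1, ]^2)
}

#' Write all prediction-surface layers as ESRI ASCII rasters
#'
#' @param surface a `prediction_surface`.
#' @param dir output directory (`mean.asc`, `sd.asc`, `q025.asc`, `q975.asc`,
#'   `field_mean.asc`, `field_sd.asc`).
#' @export
write_surface <- function(surface, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in intersect(c("mean", "sd", "q025", "q975", "field_mean", "field_sd"),
                       names(surface)))
    write_raster(surface[[nm]], file.path(dir, paste0(nm, ".asc")))
  invisible(dir)
}
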