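# Latent model specification and design assembly for the Bernoulli-logit
# latent Gaussian model: logit(pi_i) = alpha0 + X_i beta + sum_k f_k(x_ki) + w(s_i).
# Continuous smooth terms use second-order random-walk (RW2) priors over
# equal-quantile bins; month uses a cyclic RW2 over its 12 levels; the spatial
# field w uses the SPDE precision on a mesh.

#' Second-order random-walk penalty matrix
#'
#' R = D'D with D the second-difference operator; cyclic variants wrap
#' around. The penalty is scaled so the geometric mean of the marginal
#' variances of its pseudo-inverse is 1, which makes the log-precision
#' hyperparameter comparable across terms of different length.
#'
#' @param n_bins number of levels (>= 4).
#' @param cyclic wrap-around second differences (for month).
#' @param scale apply the generalized-variance-1 scaling.
#' @return sparse symmetric penalty with attributes `rank` (n-2, cyclic n-1)
#'   and `logdet_pseudo` (sum of log nonzero eigenvalues).
#' @export
rw2_precision <- function(n_bins, cyclic = FALSE, scale = TRUE) {
  n <- as.integer(n_bins)
  if (n < 4) stop_sdm("rw2 needs n_bins >= 4", class = "sdm_config_error")
  if (cyclic) {
    D <- matrix(0, n, n)
    for (i in seq_len(n)) {
      D[i, i] <- -2
      D[i, (i %% n) + 1] <- 1
      D[i, ((i - 2) %% n) + 1] <- 1
    }
  } else {
    D <- matrix(0, n - 2, n)
    for (i in seq_len(n - 2)) D[i, i + 0:2] <- c(1, -2, 1)
  }
  R <- crossprod(D)
  ev <- eigen(R, symmetric = TRUE)
  rank <- sum(ev$values > 1e-9 * max(ev$values))
  if (scale) {
    pos <- ev$values > 1e-9 * max(ev$values)
    Sig <- ev$vectors[, pos, drop = FALSE] %*%
      (t(ev$vectors[, pos, drop = FALSE]) / ev$values[pos])
    gv <- exp(mean(log(pmax(diag(Sig), 1e-300))))
    R <- R * gv
  }
  ev2 <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  out <- as_dgC(Matrix::forceSymmetric(Matrix(R, sparse = TRUE)))
  attr(out, "rank") <- rank
  attr(out, "logdet_pseudo") <- sum(log(ev2[ev2 > 1e-9 * max(ev2)]))
  out
}

#' Model specification
#'
#' One candidate of the model grid: which covariates enter and in what form,
#' whether the spatial field is included, and how the set-type factor is
#' encoded.
#'
#' @param covariates named character vector mapping covariate name to form,
#'   one of "linear", "rw2", "rw2_cyclic" (month admits only "rw2_cyclic" or
#'   "linear"). May be empty.
#' @param include_spatial include the SPDE spatial field.
#' @param include_settype include the set-type term.
#' @param settype_encoding "factor" (treatment contrasts, Dolphin reference)
#'   or "dummy" (all three indicator columns under the vague N(0, 100) prior,
#'   which carries identifiability relative to the intercept).
#' @param n_bins number of equal-quantile bins for rw2 terms (>= 4).
#' @param fixed_prior_variance prior variance of fixed effects (default 100).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(covariates = c(Chl = "rw2", O2 = "rw2", Ni = "rw2",
                                      SSH = "rw2", month = "rw2_cyclic"),
                       include_spatial = TRUE,
                       include_settype = TRUE,
                       settype_encoding = c("dummy", "factor"),
                       n_bins = 20,
                       fixed_prior_variance = 100) {
  settype_encoding <- match.arg(settype_encoding)
  if (length(covariates)) {
    bad <- !covariates %in% c("linear", "rw2", "rw2_cyclic")
    if (any(bad)) stop_sdm("unknown form: ",
                           paste(covariates[bad], collapse = ", "),
                           class = "sdm_config_error")
    if ("month" %in% names(covariates) &&
        !covariates[["month"]] %in% c("linear", "rw2_cyclic"))
      stop_sdm("month admits only rw2_cyclic or linear",
               class = "sdm_config_error")
    if (any(covariates == "rw2_cyclic" & names(covariates) != "month"))
      stop_sdm("rw2_cyclic is reserved for month", class = "sdm_config_error")
  }
  if (n_bins < 4) stop_sdm("n_bins >= 4 required", class = "sdm_config_error")
  structure(list(covariates = covariates, include_spatial = include_spatial,
                 include_settype = include_settype,
                 settype_encoding = settype_encoding, n_bins = as.integer(n_bins),
                 fixed_prior_variance = fixed_prior_variance),
            class = "model_spec")
}

spec_label <- function(spec) {
  paste0(if (length(spec$covariates))
    paste(paste0(names(spec$covariates), "(",
                 ifelse(spec$covariates == "linear", "lin", "rw2"), ")"),
          collapse = "+") else "1",
    if (spec$include_settype) paste0("+settype[", spec$settype_encoding, "]"),
    if (spec$include_spatial) "+spatial")
}

#' Assemble the latent design from observations, spec and mesh
#'
#' Stacks the latent vector x = (fixed effects | smooth levels per term |
#' field vertex weights), builds the sparse map A from x to the linear
#' predictor, the block-diagonal prior precision builder, and one sum-to-zero
#' constraint row per smooth block. Continuous rw2 covariates are binned into
#' `n_bins` equal-quantile groups (bin mids retained for prediction lookups).
#'
#' @param obs observation data.frame (presence, set_type, covariates...).
#' @param spec a [model_spec()].
#' @param mesh an `sdm_mesh`; required iff `spec$include_spatial`.
#' @return object of class `sdm_design`.
#' @export
build_design <- function(obs, spec, mesh = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  n <- nrow(obs)
  y <- obs$presence
  if (!is.null(y) && length(y) && !all(y %in% 0:1))
    stop_sdm("presence must be 0/1", class = "sdm_data_error")
  if (spec$include_spatial && is.null(mesh))
    stop_sdm("spatial spec needs a mesh", class = "sdm_config_error")

  blocks <- list()
  Acols <- list()
  d0 <- 0L

  # fixed-effect block: intercept (+ set type, + linear covariates)
  Xf <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (spec$include_settype) {
    st <- obs$set_type
    if (is.null(st)) stop_sdm("set_type column missing", class = "sdm_data_error")
    st <- factor(as.character(st), levels = set_type_levels)
    if (any(is.na(st))) stop_sdm("unseen set-type level; valid: ",
                                 paste(set_type_levels, collapse = ", "),
                                 class = "sdm_data_error")
    if (spec$settype_encoding == "dummy") {
      M <- sapply(set_type_levels, function(l) as.numeric(st == l))
      colnames(M) <- paste0(set_type_levels, " set")
      Xf <- cbind(Xf, M)
    } else {
      M <- model.matrix(~ st)[, -1, drop = FALSE]
      colnames(M) <- paste0(levels(st)[-1], " set")
      Xf <- cbind(Xf, M)
    }
  }
  lin_centers <- c()
  for (v in names(spec$covariates)[spec$covariates == "linear"]) {
    xv <- obs[[v]]
    if (is.null(xv)) stop_sdm("covariate '", v, "' missing", class = "sdm_data_error")
    ctr <- mean(xv)
    lin_centers[v] <- ctr
    Xf <- cbind(Xf, setNames(data.frame(xv - ctr), v)[[1]])
    colnames(Xf)[ncol(Xf)] <- v
  }
  blocks[[length(blocks) + 1]] <- list(
    name = "fixed", type = "fixed", idx = d0 + seq_len(ncol(Xf)),
    labels = colnames(Xf), prior_var = spec$fixed_prior_variance)
  Acols[[length(Acols) + 1]] <- Matrix(Xf, sparse = TRUE)
  d0 <- d0 + ncol(Xf)

  # smooth blocks
  for (v in names(spec$covariates)[spec$covariates %in% c("rw2", "rw2_cyclic")]) {
    cyclic <- spec$covariates[[v]] == "rw2_cyclic"
    if (cyclic) {
      nb <- 12L
      lev <- as.integer(obs[[v]])
      if (any(lev < 1 | lev > 12)) stop_sdm("month out of 1..12",
                                            class = "sdm_data_error")
      breaks <- 0:12 + 0.5
      mids <- 1:12
    } else {
      xv <- obs[[v]]
      if (is.null(xv)) stop_sdm("covariate '", v, "' missing",
                                class = "sdm_data_error")
      if (sd(xv) == 0) stop_sdm("covariate '", v, "' is constant; cannot bin",
                                class = "sdm_config_error")
      nb <- spec$n_bins
      breaks <- unique(quantile(xv, probs = seq(0, 1, length.out = nb + 1)))
      if (length(breaks) - 1 < 4)
        stop_sdm("covariate '", v, "' has too few distinct values",
                 class = "sdm_config_error")
      nb <- length(breaks) - 1L
      lev <- as.integer(cut(xv, breaks, include.lowest = TRUE))
      mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
    }
    R <- rw2_precision(nb, cyclic = cyclic)
    Ak <- Matrix::sparseMatrix(i = seq_len(n), j = lev, x = 1, dims = c(n, nb))
    blocks[[length(blocks) + 1]] <- list(
      name = v, type = if (cyclic) "rw2_cyclic" else "rw2",
      idx = d0 + seq_len(nb), labels = paste0(v, "[", signif(mids, 4), "]"),
      R = R, rank = attr(R, "rank"), logdet_pseudo = attr(R, "logdet_pseudo"),
      breaks = breaks, mids = mids, n_bins = nb)
    Acols[[length(Acols) + 1]] <- Ak
    d0 <- d0 + nb
  }

  # spatial field block
  if (spec$include_spatial) {
    pr <- make_projector(mesh, cbind(obs$lon, obs$lat))
    if (pr$n_outside > 0)
      stop_sdm(pr$n_outside, " observation(s) fall outside the mesh",
               class = "sdm_data_error")
    nv <- nrow(mesh$loc)
    fem <- fem_matrices(mesh)
    diam <- sqrt(diff(mesh$bbox_inner[1, ])^2 + diff(mesh$bbox_inner[2, ])^2)
    blocks[[length(blocks) + 1]] <- list(
      name = "spatial", type = "field", idx = d0 + seq_len(nv),
      labels = paste0("w[", seq_len(nv), "]"), fem = fem,
      range0 = diam / 5)
    Acols[[length(Acols) + 1]] <- pr$A
    d0 <- d0 + nv
  }

  A <- do.call(cbind, Acols)
  # one sum-to-zero row per smooth block
  sm <- Filter(function(b) b$type %in% c("rw2", "rw2_cyclic"), blocks)
  Cmat <- if (length(sm)) {
    m <- matrix(0, length(sm), d0)
    for (i in seq_along(sm)) m[i, sm[[i]]$idx] <- 1
    m
  } else NULL

  # hyperparameter layout: one log-precision per smooth, then field (log
  # range, log sigma)
  theta_map <- list()
  for (b in blocks) if (b$type %in% c("rw2", "rw2_cyclic"))
    theta_map[[length(theta_map) + 1]] <- list(block = b$name, what = "log_prec")
  if (spec$include_spatial) {
    theta_map[[length(theta_map) + 1]] <- list(block = "spatial", what = "log_range")
    theta_map[[length(theta_map) + 1]] <- list(block = "spatial", what = "log_sigma")
  }

  structure(list(y = y, A = as_dgC(A), blocks = blocks, d = d0,
                 constraints = Cmat, theta_map = theta_map, spec = spec,
                 mesh = mesh, lin_centers = lin_centers, n = n),
            class = "sdm_design")
}

# hyperprior on theta: weakly informative Gaussians; field range prior
# centered on 1/5 of the domain diameter
theta_prior <- function(assembly) {
  mm <- ss <- numeric(length(assembly$theta_map))
  for (i in seq_along(assembly$theta_map)) {
    tm <- assembly$theta_map[[i]]
    if (tm$what == "log_prec") { mm[i] <- 0; ss[i] <- 2 }
    if (tm$what == "log_range") {
      b <- Filter(function(b) b$type == "field", assembly$blocks)[[1]]
      mm[i] <- log(b$range0); ss[i] <- 1
    }
    if (tm$what == "log_sigma") { mm[i] <- 0; ss[i] <- 1.5 }
  }
  list(mean = mm, sd = ss)
}

# block-diagonal prior precision at hyperparameters theta, plus the
# generalized log-determinant (rank-aware for intrinsic RW2 blocks)
build_Qprior <- function(assembly, theta) {
  d <- assembly$d
  trip_i <- list(); trip_j <- list(); trip_x <- list()
  gld <- 0
  ti <- 0L
  add <- function(M, idx) {
    M <- as_dgC(M)
    s <- Matrix::summary(M)
    trip_i[[length(trip_i) + 1]] <<- idx[s$i]
    trip_j[[length(trip_j) + 1]] <<- idx[s$j]
    trip_x[[length(trip_x) + 1]] <<- s$x
  }
  for (b in assembly$blocks) {
    if (b$type == "fixed") {
      add(Matrix::Diagonal(length(b$idx), 1 / b$prior_var), b$idx)
      gld <- gld - length(b$idx) * log(b$prior_var)
    } else if (b$type %in% c("rw2", "rw2_cyclic")) {
      th <- theta[ti <- ti + 1L]
      add(exp(th) * b$R + Matrix::Diagonal(length(b$idx), 1e-8), b$idx)
      gld <- gld + b$rank * th + b$logdet_pseudo
    } else if (b$type == "field") {
      lr <- theta[ti <- ti + 1L]; ls <- theta[ti <- ti + 1L]
      kappa <- sqrt(8) / exp(lr)
      tau <- 1 / (exp(ls) * sqrt(4 * pi) * kappa)
      Q <- spde_precision(b$fem, kappa, tau)
      add(Q, b$idx)
      gld <- gld + as.numeric(Matrix::determinant(Q, logarithm = TRUE)$modulus)
    }
  }
  Qp <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                             x = unlist(trip_x), dims = c(d, d), repr = "C")
  list(Q = Matrix::forceSymmetric(Qp), gld = gld)
}
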