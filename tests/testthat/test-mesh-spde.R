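# Triangulation, FEM assembly, SPDE precision and barycentric projection.

test_that("build_mesh keeps input points as vertices and merges duplicates", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  m <- build_mesh(sq, inner_max_edge = 2, outer_max_edge = 4, cutoff = 0.05,
                  planar = TRUE)
  # each input point is a vertex (or within cutoff of one)
  d <- apply(sq, 1, function(p)
    min(sqrt((m$loc[, 1] - p[1])^2 + (m$loc[, 2] - p[2])^2)))
  expect_true(all(d <= 0.05 + 1e-12))
  # duplicated points do not change the vertex count
  m2 <- build_mesh(rbind(sq, sq, sq + 1e-4), inner_max_edge = 2,
                   outer_max_edge = 4, cutoff = 0.05, planar = TRUE)
  expect_equal(nrow(m2$loc), nrow(m$loc))
  # triangles positively oriented, total area = outer box area
  fem <- fem_matrices(m)
  ob <- m$bbox_outer
  expect_equal(fem$area, diff(ob[1, ]) * diff(ob[2, ]), tolerance = 1e-8)
  expect_error(build_mesh(cbind(0:4, 0:4), 1, 2, planar = TRUE),
               class = "sdm_mesh_error")
  expect_error(build_mesh(sq, 2, 1, planar = TRUE), class = "sdm_mesh_error")
})

test_that("halving the inner edge target refines the inner zone", {
  withr::local_seed(12)
  pts <- cbind(runif(40, 0, 10), runif(40, 0, 10))
  m1 <- build_mesh(pts, inner_max_edge = 2, outer_max_edge = 5, planar = TRUE)
  m2 <- build_mesh(pts, inner_max_edge = 1, outer_max_edge = 5, planar = TRUE)
  expect_gt(spdeSDM:::inner_triangle_count(m2),
            spdeSDM:::inner_triangle_count(m1))
  expect_true(all(m1$inner[seq_len(m1$n_data)]))
})

test_that("FEM matrices match hand computation and conservation laws", {
  # single unit right triangle: lumped mass = area/3 per vertex
  tri_mesh <- structure(list(
    loc = cbind(c(0, 1, 0), c(0, 0, 1)),
    tri = matrix(1:3, 1), inner = rep(TRUE, 3), planar = TRUE,
    bbox_inner = rbind(c(0, 1), c(0, 1))), class = "sdm_mesh")
  fem <- fem_matrices(tri_mesh)
  expect_equal(as.numeric(Matrix::diag(fem$C)), rep(1 / 6, 3))
  # general mesh: sum(C) = area, G annihilates constants, G symmetric
  withr::local_seed(13)
  pts <- cbind(runif(30, 0, 5), runif(30, 0, 5))
  m <- build_mesh(pts, inner_max_edge = 1, outer_max_edge = 3, planar = TRUE)
  fm <- fem_matrices(m)
  expect_equal(sum(Matrix::diag(fm$C)), fm$area)
  expect_lt(max(abs(fm$G %*% rep(1, nrow(m$loc)))), 1e-10)
  expect_equal(as.matrix(fm$G), t(as.matrix(fm$G)))
})

test_that("spde_precision scales as tau^2 and is SPD across parameters", {
  withr::local_seed(14)
  pts <- cbind(runif(25, 0, 4), runif(25, 0, 4))
  m <- build_mesh(pts, inner_max_edge = 0.8, outer_max_edge = 2, planar = TRUE)
  fem <- fem_matrices(m)
  Q1 <- spde_precision(fem, kappa = 2, tau = 1)
  Q2 <- spde_precision(fem, kappa = 2, tau = 2)
  expect_equal(as.matrix(Q2), 4 * as.matrix(Q1), tolerance = 1e-12)
  for (k in c(0.5, 2, 8)) for (tau in c(0.1, 1)) {
    ch <- try(Matrix::Cholesky(spde_precision(fem, k, tau)), silent = TRUE)
    expect_s4_class(ch, "CHMfactor")
  }
  expect_error(spde_precision(fem, -1, 1), class = "sdm_config_error")
})

test_that("matern_correlation matches an independent Bessel oracle", {
  expect_equal(matern_correlation(0, 2), 1)
  # kd = 1: K1(1) by quadrature of the integral representation
  expect_equal(matern_correlation(0.5, 2), 1 * besselK1_oracle(1),
               tolerance = 1e-8)
  # at the conventional range sqrt(8)/kappa the correlation is ~0.13
  kappa <- 1.7
  d <- sqrt(8) / kappa
  expect_equal(matern_correlation(d, kappa),
               sqrt(8) * besselK1_oracle(sqrt(8)), tolerance = 1e-8)
  expect_equal(matern_correlation(d, kappa), 0.1397, tolerance = 1e-3)
  expect_error(matern_correlation(-1, 1), class = "sdm_domain_error")
})

test_that("projector rows are barycentric and reproduce linear functions", {
  withr::local_seed(15)
  pts <- cbind(runif(40, 0, 6), runif(40, 0, 6))
  m <- build_mesh(pts, inner_max_edge = 1.2, outer_max_edge = 3, planar = TRUE)
  # at a vertex: unit basis row
  pr_v <- make_projector(m, m$loc[5, , drop = FALSE], planar = TRUE)
  w <- as.numeric(pr_v$A[1, ])
  expect_equal(w[5], 1, tolerance = 1e-9)
  expect_equal(sum(w), 1, tolerance = 1e-9)
  # at a barycenter: (1/3, 1/3, 1/3)
  tr <- m$tri[10, ]
  bc <- colMeans(m$loc[tr, ])
  pr_b <- make_projector(m, rbind(bc), planar = TRUE)
  expect_equal(sort(as.numeric(pr_b$A[1, tr])), rep(1 / 3, 3), tolerance = 1e-6)
  # linear reproduction at 50 random interior points
  locs <- cbind(runif(50, 1, 5), runif(50, 1, 5))
  pr <- make_projector(m, locs, planar = TRUE)
  f <- 2 * m$loc[, 1] + m$loc[, 2]
  expect_equal(as.vector(pr$A %*% f), 2 * locs[, 1] + locs[, 2],
               tolerance = 1e-9)
  expect_true(all(abs(Matrix::rowSums(pr$A) - 1) < 1e-9))
  # outside the mesh: flagged, row zero
  pr_out <- suppressWarnings(make_projector(m, rbind(c(1e3, 1e3)), planar = TRUE))
  expect_false(pr_out$ok[1])
  expect_equal(pr_out$n_outside, 1)
})

test_that("SPDE field correlation converges to closed-form Matern on a fine mesh", {
  pts <- as.matrix(expand.grid(seq(0, 1, 0.25), seq(0, 1, 0.25)))
  mesh <- build_mesh(pts, inner_max_edge = 0.04, outer_max_edge = 0.12,
                     cutoff = 0.008, extension_width = 0.5, planar = TRUE)
  fem <- fem_matrices(mesh)
  kappa <- 8; tau <- 0.4
  Q <- spde_precision(fem, kappa, tau)
  S <- as.matrix(Matrix::solve(Q))
  inner <- which(mesh$loc[, 1] > 0.3 & mesh$loc[, 1] < 0.7 &
                   mesh$loc[, 2] > 0.3 & mesh$loc[, 2] < 0.7)
  expect_equal(mean(diag(S)[inner]), 1 / (4 * pi * kappa^2 * tau^2),
               tolerance = 0.1)
  i0 <- inner[seq_len(min(40, length(inner)))]
  Csub <- S[i0, i0]
  R <- Csub / sqrt(outer(diag(Csub), diag(Csub)))
  D <- as.matrix(dist(mesh$loc[i0, ]))
  expect_lt(max(abs(R - matern_correlation(D, kappa))), 0.05)
})
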