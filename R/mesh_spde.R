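# Two-zone triangulation and the finite-element SPDE representation of the
# Matern field. The triangulation is a Bowyer-Watson Delaunay of the merged
# observation points plus structured fill points: a fine grid over the inner
# zone (the bounding box of the data, the domain of interest) and a coarse
# grid over an outer extension ring that damps boundary effects, giving the
# conventional fine-to-coarse transition.

# --- Bowyer-Watson Delaunay triangulation ------------------------------------

circum <- function(p1, p2, p3) {
  ax <- p1[1]; ay <- p1[2]; bx <- p2[1]; by <- p2[2]; cx <- p3[1]; cy <- p3[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-300) return(c(Inf, Inf, Inf))
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  c(ux, uy, (ux - ax)^2 + (uy - ay)^2)
}

delaunay_triangulate <- function(pts) {
  n <- nrow(pts)
  if (n < 3) stop_sdm("need at least 3 points to triangulate",
                      class = "sdm_mesh_error")
  ctr <- colMeans(pts)
  span <- max(max(pts[, 1]) - min(pts[, 1]), max(pts[, 2]) - min(pts[, 2]), 1e-9)
  M <- 50 * span
  sup <- rbind(ctr + c(-M, -M / 2), ctr + c(M, -M / 2), ctr + c(0, M))
  verts <- rbind(sup, pts)
  # triangle store: columns v1 v2 v3 cx cy r2; grown geometrically
  cap <- 8 * n + 16
  tri <- matrix(NA_real_, cap, 6)
  cc <- circum(verts[1, ], verts[2, ], verts[3, ])
  tri[1, ] <- c(1, 2, 3, cc)
  ntri <- 1L
  alive <- rep(FALSE, cap); alive[1] <- TRUE
  for (ip in seq_len(n)) {
    p <- verts[ip + 3, ]
    act <- which(alive[seq_len(ntri)])
    d2 <- (tri[act, 4] - p[1])^2 + (tri[act, 5] - p[2])^2
    bad <- act[d2 < tri[act, 6] * (1 - 1e-12)]
    if (!length(bad)) next  # duplicate point exactly on hull structure; skip
    # boundary = edges of bad triangles appearing exactly once
    e <- rbind(tri[bad, c(1, 2), drop = FALSE], tri[bad, c(2, 3), drop = FALSE],
               tri[bad, c(3, 1), drop = FALSE])
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    tab <- table(key)
    keep <- key %in% names(tab)[tab == 1]
    alive[bad] <- FALSE
    for (j in which(keep)) {
      a <- e[j, 1]; b <- e[j, 2]
      cc <- circum(verts[a, ], verts[b, ], p)
      ntri <- ntri + 1L
      if (ntri > cap) {
        tri <- rbind(tri, matrix(NA_real_, cap, 6)); alive <- c(alive, rep(FALSE, cap))
        cap <- 2 * cap
      }
      tri[ntri, ] <- c(a, b, ip + 3, cc)
      alive[ntri] <- TRUE
    }
  }
  tt <- tri[which(alive[seq_len(ntri)]), 1:3, drop = FALSE]
  tt <- tt[rowSums(tt <= 3) == 0, , drop = FALSE] - 3
  # enforce counter-clockwise orientation
  for (i in seq_len(nrow(tt))) {
    a <- pts[tt[i, 1], ]; b <- pts[tt[i, 2], ]; c3 <- pts[tt[i, 3], ]
    if ((b[1] - a[1]) * (c3[2] - a[2]) - (b[2] - a[2]) * (c3[1] - a[1]) < 0)
      tt[i, 2:3] <- tt[i, 3:2]
  }
  storage.mode(tt) <- "integer"
  tt
}

# deterministic sub-ulp-style jitter used to break cocircular grid degeneracy
det_jitter <- function(m, scale) {
  j1 <- (sin(seq_len(m) * 12.9898) * 43758.5453) %% 1 - 0.5
  j2 <- (sin(seq_len(m) * 78.233) * 12578.1459) %% 1 - 0.5
  cbind(j1, j2) * scale
}

# --- Mesh construction -------------------------------------------------------

#' Build a two-zone triangulated mesh around observation locations
#'
#' Locations closer than `cutoff` are merged (first occurrence kept). The
#' inner zone is the bounding box of the merged points (plus a small margin)
#' filled at the inner edge target; an outer ring of width `extension_width`
#' is filled at the coarser outer target to push boundary effects away from
#' the data. All merged input points are mesh vertices.
#'
#' @param points matrix or data.frame with two columns (lon, lat in degrees;
#'   or planar coordinates when `planar = TRUE`).
#' @param inner_max_edge target edge length in the inner zone (degrees).
#' @param outer_max_edge target edge length in the extension (>= inner).
#' @param cutoff merge radius; default `inner_max_edge / 5`.
#' @param extension_width width of the outer ring; default 20% of the domain
#'   diameter.
#' @param planar if TRUE, coordinates are used as-is; otherwise longitudes are
#'   scaled by cos(mean latitude) before meshing.
#' @return object of class `sdm_mesh`: `loc` (vertex coordinates, planar),
#'   `tri` (vertex index triples, counter-clockwise), `inner` (logical per
#'   vertex), plus the transform metadata.
#' @export
build_mesh <- function(points, inner_max_edge, outer_max_edge,
                       cutoff = inner_max_edge / 5,
                       extension_width = NULL, planar = FALSE) {
  points <- as.matrix(points)[, 1:2, drop = FALSE]
  if (inner_max_edge <= 0 || outer_max_edge < inner_max_edge)
    stop_sdm("need 0 < inner_max_edge <= outer_max_edge",
             class = "sdm_mesh_error")
  lat0 <- if (planar) 0 else mean(range(points[, 2]))
  P <- if (planar) points else scale_coords(points[, 1], points[, 2], lat0)
  # greedy cutoff merge, keep first occurrence
  keep <- integer(0)
  for (i in seq_len(nrow(P))) {
    if (!length(keep) ||
        min(sqrt((P[keep, 1] - P[i, 1])^2 + (P[keep, 2] - P[i, 2])^2)) > cutoff)
      keep <- c(keep, i)
  }
  P <- P[keep, , drop = FALSE]
  if (nrow(P) < 3) stop_sdm("fewer than 3 distinct points after cutoff merge",
                            class = "sdm_mesh_error")
  if (abs(polygon_area(P[chull(P), , drop = FALSE])) < 1e-12)
    stop_sdm("points are collinear; cannot mesh", class = "sdm_mesh_error")

  margin <- max(cutoff, 0.05 * inner_max_edge)
  ib <- rbind(range(P[, 1]) + c(-margin, margin),
              range(P[, 2]) + c(-margin, margin))
  diam <- sqrt(diff(ib[1, ])^2 + diff(ib[2, ])^2)
  ext <- extension_width %||% (0.2 * diam)
  ob <- ib + cbind(c(-ext, -ext), c(ext, ext))

  gpts <- function(bb, s) {
    gx <- seq(bb[1, 1], bb[1, 2], length.out = max(2, ceiling(diff(bb[1, ]) / s) + 1))
    gy <- seq(bb[2, 1], bb[2, 2], length.out = max(2, ceiling(diff(bb[2, ]) / s) + 1))
    as.matrix(expand.grid(x = gx, y = gy))
  }
  gin <- gpts(ib, 0.8 * inner_max_edge)
  gout <- gpts(ob, 0.85 * outer_max_edge)
  inside_ib <- gout[, 1] > ib[1, 1] - 1e-12 & gout[, 1] < ib[1, 2] + 1e-12 &
    gout[, 2] > ib[2, 1] - 1e-12 & gout[, 2] < ib[2, 2] + 1e-12
  gout <- gout[!inside_ib, , drop = FALSE]
  corners <- as.matrix(expand.grid(x = ob[1, ], y = ob[2, ]))
  fill <- rbind(gin, gout)
  if (nrow(fill)) {
    fill <- fill + det_jitter(nrow(fill), 1e-4 * inner_max_edge)
    # drop fill points crowding a data vertex (capped so a thin extension
    # ring never loses its coverage points)
    thr <- min(max(cutoff, 0.32 * inner_max_edge), 0.9 * ext)
    d <- cross_dist(fill, P)
    fill <- fill[apply(d, 1, min) > thr, , drop = FALSE]
  }
  fill <- rbind(corners, fill)  # exact outer corners guarantee hull coverage
  dup <- apply(cross_dist(fill, fill), 1, function(r)
    which(r < 1e-3 * inner_max_edge)[1]) < seq_len(nrow(fill))
  fill <- fill[!dup, , drop = FALSE]
  V <- rbind(P, fill)
  tri <- delaunay_triangulate(V)
  inner <- V[, 1] >= ib[1, 1] - 1e-9 & V[, 1] <= ib[1, 2] + 1e-9 &
    V[, 2] >= ib[2, 1] - 1e-9 & V[, 2] <= ib[2, 2] + 1e-9
  structure(list(loc = V, tri = tri, inner = inner, n_data = nrow(P),
                 lat0 = lat0, planar = planar, bbox_inner = ib, bbox_outer = ob,
                 cutoff = cutoff, inner_max_edge = inner_max_edge,
                 outer_max_edge = outer_max_edge),
            class = "sdm_mesh")
}

polygon_area <- function(p) {
  if (nrow(p) < 3) return(0)
  x <- p[, 1]; y <- p[, 2]
  0.5 * sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
}

#' @exportS3Method base::print
print.sdm_mesh <- function(x, ...) {
  cat(sprintf("<sdm_mesh> %d vertices (%d inner), %d triangles\n",
              nrow(x$loc), sum(x$inner), nrow(x$tri)))
  invisible(x)
}

# number of triangles whose centroid falls in the inner zone (test hook)
inner_triangle_count <- function(mesh) {
  cx <- rowMeans(matrix(mesh$loc[mesh$tri, 1], ncol = 3))
  cy <- rowMeans(matrix(mesh$loc[mesh$tri, 2], ncol = 3))
  ib <- mesh$bbox_inner
  sum(cx >= ib[1, 1] & cx <= ib[1, 2] & cy >= ib[2, 1] & cy <= ib[2, 2])
}

# --- Finite-element matrices -------------------------------------------------

#' Assemble FEM mass and stiffness matrices on a mesh
#'
#' Piecewise-linear basis: `C` is the lumped (diagonal) mass matrix with
#' C_ii = one third of the total area of triangles incident to vertex i; `G`
#' is the stiffness matrix (symmetric, zero row sums).
#'
#' @param mesh an `sdm_mesh`.
#' @return list with sparse `C`, `G` and `area` (total mesh area).
#' @export
fem_matrices <- function(mesh) {
  V <- mesh$loc; Tt <- mesh$tri
  nt <- nrow(Tt); nv <- nrow(V)
  ii <- integer(9 * nt); jj <- integer(9 * nt); gg <- numeric(9 * nt)
  cdiag <- numeric(nv)
  pos <- 0L
  for (t in seq_len(nt)) {
    id <- Tt[t, ]
    p <- V[id, , drop = FALSE]
    # edge-opposite gradient coefficients
    b <- c(p[2, 2] - p[3, 2], p[3, 2] - p[1, 2], p[1, 2] - p[2, 2])
    cvec <- c(p[3, 1] - p[2, 1], p[1, 1] - p[3, 1], p[2, 1] - p[1, 1])
    A2 <- b[1] * cvec[2] - b[2] * cvec[1]  # = 2*area (signed)
    area <- abs(A2) / 2
    if (area < 1e-14)
      stop_sdm("zero-area triangle ", t, " in mesh", class = "sdm_mesh_error")
    Gl <- (outer(b, b) + outer(cvec, cvec)) / (4 * area)
    cdiag[id] <- cdiag[id] + area / 3
    idx <- pos + 1:9
    ii[idx] <- rep(id, each = 3); jj[idx] <- rep(id, times = 3)
    gg[idx] <- as.vector(Gl)
    pos <- pos + 9L
  }
  G <- Matrix::sparseMatrix(i = ii, j = jj, x = gg, dims = c(nv, nv))
  list(C = Matrix::Diagonal(nv, cdiag), G = Matrix::forceSymmetric(G),
       area = sum(cdiag))
}

#' SPDE precision matrix of the Matern (nu = 1) field
#'
#' Q(kappa, tau) = tau^2 (kappa^4 C + 2 kappa^2 G + G C^-1 G) with lumped mass
#' C — the smoothness-alpha-2 finite-element precision whose inverse
#' approximates a Matern nu = 1 covariance with range sqrt(8)/kappa and
#' marginal variance 1 / (4 pi kappa^2 tau^2).
#'
#' @param fem list from [fem_matrices()].
#' @param kappa inverse-range scale (> 0).
#' @param tau precision scale (> 0).
#' @return sparse symmetric positive-definite precision matrix.
#' @export
spde_precision <- function(fem, kappa, tau) {
  if (kappa <= 0 || tau <= 0)
    stop_sdm("kappa and tau must be > 0", class = "sdm_config_error")
  Cinv <- Matrix::Diagonal(nrow(fem$C), 1 / Matrix::diag(fem$C))
  Q <- tau^2 * (kappa^4 * fem$C + 2 * kappa^2 * fem$G +
                  fem$G %*% Cinv %*% fem$G)
  Matrix::forceSymmetric(Q)
}

#' Matern (nu = 1) correlation function
#'
#' rho(d) = kappa * d * K1(kappa * d), with rho(0) = 1. At the conventional
#' range d = sqrt(8)/kappa the correlation is about 0.13.
#'
#' @param d distances (>= 0), any shape.
#' @param kappa inverse-range scale (> 0).
#' @return correlations in (0, 1], same shape as `d`.
#' @export
matern_correlation <- function(d, kappa) {
  if (kappa <= 0) stop_sdm("kappa must be > 0", class = "sdm_config_error")
  if (any(d < 0)) stop_sdm("distances must be >= 0", class = "sdm_domain_error")
  kd <- kappa * d
  out <- kd
  small <- kd < 1e-8
  out[small] <- 1
  out[!small] <- kd[!small] * besselK(kd[!small], 1)
  out
}

# --- Projection --------------------------------------------------------------

#' Barycentric projector from mesh vertices to point locations
#'
#' Builds the sparse matrix A with at most three nonnegative entries per row
#' (barycentric coordinates of the containing triangle) mapping vertex weights
#' to values at arbitrary locations; exact for piecewise-linear functions.
#'
#' @param mesh an `sdm_mesh`.
#' @param locations two-column matrix (lon/lat, or planar if `planar`).
#' @param planar treat coordinates as already planar.
#' @return list: `A` sparse (n_loc x n_vertex), `ok` logical per location
#'   (FALSE = outside the mesh, row left zero), `n_outside`.
#' @export
make_projector <- function(mesh, locations, planar = mesh$planar) {
  locations <- as.matrix(locations)[, 1:2, drop = FALSE]
  L <- if (planar) locations else
    scale_coords(locations[, 1], locations[, 2], mesh$lat0)
  V <- mesh$loc; Tt <- mesh$tri
  nt <- nrow(Tt)
  # precompute barycentric transforms
  p1 <- V[Tt[, 1], , drop = FALSE]
  d21 <- V[Tt[, 2], , drop = FALSE] - p1
  d31 <- V[Tt[, 3], , drop = FALSE] - p1
  det <- d21[, 1] * d31[, 2] - d21[, 2] * d31[, 1]
  # bucket index on triangle bboxes
  xmin <- pmin(p1[, 1], p1[, 1] + d21[, 1], p1[, 1] + d31[, 1])
  xmax <- pmax(p1[, 1], p1[, 1] + d21[, 1], p1[, 1] + d31[, 1])
  ymin <- pmin(p1[, 2], p1[, 2] + d21[, 2], p1[, 2] + d31[, 2])
  ymax <- pmax(p1[, 2], p1[, 2] + d21[, 2], p1[, 2] + d31[, 2])
  cell <- max(xmax - xmin, ymax - ymin, 1e-9)
  x0 <- min(xmin); y0 <- min(ymin)
  nbx <- max(1L, ceiling((max(xmax) - x0) / cell))
  key <- function(cx, cy) cy * (nbx + 2) + cx
  bucket <- new.env(hash = TRUE, parent = emptyenv())
  for (t in seq_len(nt)) {
    for (cx in floor((xmin[t] - x0) / cell):floor((xmax[t] - x0) / cell))
      for (cy in floor((ymin[t] - y0) / cell):floor((ymax[t] - y0) / cell)) {
        k <- as.character(key(cx, cy))
        bucket[[k]] <- c(bucket[[k]], t)
      }
  }
  m <- nrow(L)
  ri <- integer(3 * m); ci <- integer(3 * m); xi <- numeric(3 * m)
  ok <- rep(FALSE, m); pos <- 0L
  tol <- -1e-9
  for (i in seq_len(m)) {
    k <- as.character(key(floor((L[i, 1] - x0) / cell), floor((L[i, 2] - y0) / cell)))
    for (t in bucket[[k]] %||% integer(0)) {
      dx <- L[i, 1] - p1[t, 1]; dy <- L[i, 2] - p1[t, 2]
      l2 <- (dx * d31[t, 2] - dy * d31[t, 1]) / det[t]
      l3 <- (dy * d21[t, 1] - dx * d21[t, 2]) / det[t]
      l1 <- 1 - l2 - l3
      if (l1 >= tol && l2 >= tol && l3 >= tol) {
        w <- pmax(c(l1, l2, l3), 0); w <- w / sum(w)
        idx <- pos + 1:3
        ri[idx] <- i; ci[idx] <- Tt[t, ]; xi[idx] <- w
        pos <- pos + 3L
        ok[i] <- TRUE
        break
      }
    }
  }
  if (!all(ok))
    warning(sum(!ok), " location(s) outside the mesh; projector rows left zero")
  A <- Matrix::sparseMatrix(i = ri[seq_len(pos)], j = ci[seq_len(pos)],
                            x = xi[seq_len(pos)], dims = c(m, nrow(V)))
  list(A = A, ok = ok, n_outside = sum(!ok))
}
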