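#' Labeled tetrahedral left-ventricular mesh
#'
#' Container for a tetrahedral mesh carrying the labeled boundary surfaces
#' (`endo`, `epi`, `base`) and the apical node region used by the ventricular
#' coordinate solver.  All positions are in millimetres.
#'
#' @param nodes numeric matrix (n x 3) of node positions (mm).
#' @param tets integer matrix (m x 4) of 1-based node indices; every
#'   tetrahedron must have positive signed volume.
#' @param surfaces named list of triangle index matrices (k x 3) with at least
#'   the names `endo`, `epi` and `base`; the three sets must be disjoint.
#' @param apex_region integer vector of node indices inside the apical
#'   transmural cylinder (2 mm diameter by convention); must be non-empty.
#' @param point_data optional named list of per-node arrays.
#'
#' @return an object of class `tet_mesh`.
#' @export
tet_mesh <- function(nodes, tets, surfaces, apex_region, point_data = list()) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  dimnames(nodes) <- NULL
  tets <- as.matrix(tets)
  storage.mode(tets) <- "integer"
  dimnames(tets) <- NULL
  if (ncol(nodes) != 3L) stop("'nodes' must be an n x 3 matrix")
  if (ncol(tets) != 4L) stop("'tets' must be an m x 4 matrix")
  n <- nrow(nodes)
  if (any(tets < 1L) || any(tets > n)) stop("tetrahedron indices out of range")
  needed <- c("endo", "epi", "base")
  missing_lab <- setdiff(needed, names(surfaces))
  if (length(missing_lab) > 0L) {
    stop("missing surface label(s): ", paste(missing_lab, collapse = ", "))
  }
  for (nm in names(surfaces)) {
    tri <- as.matrix(surfaces[[nm]])
    storage.mode(tri) <- "integer"
    if (ncol(tri) != 3L) stop("surface '", nm, "' must be a k x 3 triangle matrix")
    if (nrow(tri) > 0L && (any(tri < 1L) || any(tri > n))) {
      stop("surface '", nm, "' references invalid nodes")
    }
    surfaces[[nm]] <- tri
  }
  key <- function(tri) apply(t(apply(tri, 1L, sort)), 1L, paste, collapse = "-")
  ks <- lapply(surfaces[needed], key)
  if (anyDuplicated(unlist(ks))) stop("endo/epi/base triangle sets must be disjoint")
  apex_region <- as.integer(apex_region)
  if (length(apex_region) == 0L) stop("'apex_region' must be non-empty")
  if (any(apex_region < 1L) || any(apex_region > n)) stop("'apex_region' out of range")
  vol <- tet_volumes_impl(nodes, tets)
  if (any(vol <= 0)) {
    stop(sum(vol <= 0), " tetrahedra have non-positive volume")
  }
  structure(
    list(nodes = nodes, tets = tets, surfaces = surfaces,
         apex_region = apex_region, point_data = point_data),
    class = "tet_mesh")
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat("tet_mesh:", nrow(x$nodes), "nodes,", nrow(x$tets), "tets\n")
  cat("  surfaces:",
      paste(sprintf("%s (%d)", names(x$surfaces),
                    vapply(x$surfaces, nrow, 0L)), collapse = ", "), "\n")
  cat("  apex region:", length(x$apex_region), "nodes\n")
  if (length(x$point_data)) {
    cat("  point data:", paste(names(x$point_data), collapse = ", "), "\n")
  }
  invisible(x)
}

## signed volume of each tet (mm^3); positive for correctly oriented tets
tet_volumes_impl <- function(nodes, tets) {
  a <- nodes[tets[, 1L], , drop = FALSE]
  b <- nodes[tets[, 2L], , drop = FALSE] - a
  c_ <- nodes[tets[, 3L], , drop = FALSE] - a
  d <- nodes[tets[, 4L], , drop = FALSE] - a
  (b[, 1L] * (c_[, 2L] * d[, 3L] - c_[, 3L] * d[, 2L]) +
   b[, 2L] * (c_[, 3L] * d[, 1L] - c_[, 1L] * d[, 3L]) +
   b[, 3L] * (c_[, 1L] * d[, 2L] - c_[, 2L] * d[, 1L])) / 6
}

#' Tetrahedron volumes
#'
#' @param mesh a [tet_mesh()].
#' @return numeric vector of tetrahedron volumes (mm^3).
#' @export
tet_volumes <- function(mesh) {
  tet_volumes_impl(mesh$nodes, mesh$tets)
}

## ---------------------------------------------------------------------------
## Structured grid -> tetrahedra via the Kuhn (6-tet) subdivision.
##
## `idx` is an (n1+1) x (n2+1) x (n3+1) array of global node indices; repeated
## indices (collapsed pole edges, periodic seams) are allowed -- degenerate
## Kuhn tets are dropped, which leaves a conforming triangulation.
kuhn_tets <- function(idx, nodes) {
  d <- dim(idx) - 1L
  i <- rep(seq_len(d[1L]), times = d[2L] * d[3L])
  j <- rep(rep(seq_len(d[2L]), each = d[1L]), times = d[3L])
  k <- rep(seq_len(d[3L]), each = d[1L] * d[2L])
  corner <- function(di, dj, dk) idx[cbind(i + di, j + dj, k + dk)]
  c000 <- corner(0L, 0L, 0L); c100 <- corner(1L, 0L, 0L)
  c110 <- corner(1L, 1L, 0L); c010 <- corner(0L, 1L, 0L)
  c001 <- corner(0L, 0L, 1L); c101 <- corner(1L, 0L, 1L)
  c111 <- corner(1L, 1L, 1L); c011 <- corner(0L, 1L, 1L)
  tets <- rbind(
    cbind(c000, c100, c110, c111),
    cbind(c000, c100, c101, c111),
    cbind(c000, c010, c110, c111),
    cbind(c000, c010, c011, c111),
    cbind(c000, c001, c101, c111),
    cbind(c000, c001, c011, c111))
  dup <- (tets[, 1L] == tets[, 2L]) | (tets[, 1L] == tets[, 3L]) |
    (tets[, 1L] == tets[, 4L]) | (tets[, 2L] == tets[, 3L]) |
    (tets[, 2L] == tets[, 4L]) | (tets[, 3L] == tets[, 4L])
  tets <- tets[!dup, , drop = FALSE]
  vol <- tet_volumes_impl(nodes, tets)
  flip <- vol < 0
  if (any(flip)) {
    tmp <- tets[flip, 3L]
    tets[flip, 3L] <- tets[flip, 4L]
    tets[flip, 4L] <- tmp
    vol[flip] <- -vol[flip]
  }
  keep <- vol > 1e-12 * stats::median(vol[vol > 0])
  tets[keep, , drop = FALSE]
}

## boundary triangles (faces used by exactly one tet), oriented so that the
## triangle normal points out of the owning tetrahedron
boundary_triangles <- function(tets, nodes = NULL) {
  faces <- rbind(tets[, c(1L, 2L, 3L)], tets[, c(1L, 2L, 4L)],
                 tets[, c(1L, 3L, 4L)], tets[, c(2L, 3L, 4L)])
  opp <- c(tets[, 4L], tets[, 3L], tets[, 2L], tets[, 1L])
  sorted <- t(apply(faces, 1L, sort))
  kk <- paste(sorted[, 1L], sorted[, 2L], sorted[, 3L])
  tab <- table(kk)
  keep <- kk %in% names(tab)[tab == 1L]
  faces <- faces[keep, , drop = FALSE]
  opp <- opp[keep]
  if (!is.null(nodes)) {
    a <- nodes[faces[, 1L], , drop = FALSE]
    u <- nodes[faces[, 2L], , drop = FALSE] - a
    v <- nodes[faces[, 3L], , drop = FALSE] - a
    w <- nodes[opp, , drop = FALSE] - a
    trip <- (u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L]) * w[, 1L] +
      (u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L]) * w[, 2L] +
      (u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L]) * w[, 3L]
    flip <- trip > 0
    tmp <- faces[flip, 2L]
    faces[flip, 2L] <- faces[flip, 3L]
    faces[flip, 3L] <- tmp
  }
  faces
}

#' Structured box tetrahedral mesh
#'
#' Axis-aligned box meshed with a structured grid and the Kuhn six-tet cell
#' subdivision.  Mainly a verification fixture: Laplace-Dirichlet solutions on
#' a box have simple closed forms.  Surface labels map `endo` to the face
#' `x = 0`, `epi` to `x = lengths[1]`, and `base` to `z = lengths[3]`.
#'
#' @param n integer vector of cell counts per axis (length 3, or scalar).
#' @param lengths box edge lengths (mm), recycled to length 3.
#' @param origin corner position, default the origin.
#' @return a [tet_mesh()].
#' @export
make_box_mesh <- function(n = c(4L, 4L, 4L), lengths = c(1, 1, 1),
                          origin = c(0, 0, 0)) {
  n <- rep(as.integer(n), length.out = 3L)
  lengths <- rep(as.numeric(lengths), length.out = 3L)
  xs <- seq(0, lengths[1L], length.out = n[1L] + 1L) + origin[1L]
  ys <- seq(0, lengths[2L], length.out = n[2L] + 1L) + origin[2L]
  zs <- seq(0, lengths[3L], length.out = n[3L] + 1L) + origin[3L]
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs, KEEP.OUT.ATTRS = FALSE))
  dimnames(nodes) <- NULL
  idx <- array(seq_len(nrow(nodes)), dim = n + 1L)
  tets <- kuhn_tets(idx, nodes)
  bt <- boundary_triangles(tets, nodes)
  on_plane <- function(tri, coord, value) {
    apply(matrix(abs(nodes[tri, coord] - value), ncol = 3L), 1L,
          max) < 1e-9 * max(lengths)
  }
  surfaces <- list(
    endo = bt[on_plane(bt, 1L, origin[1L]), , drop = FALSE],
    epi = bt[on_plane(bt, 1L, origin[1L] + lengths[1L]), , drop = FALSE],
    base = bt[on_plane(bt, 3L, origin[3L] + lengths[3L]), , drop = FALSE])
  apex <- which(abs(nodes[, 3L] - origin[3L]) < 1e-9 * max(lengths))
  tet_mesh(nodes, tets, surfaces, apex)
}

#' Structured cylindrical annulus mesh
#'
#' Concentric-cylinder annulus, periodic in the angular direction.  Used as an
#' analytic verification fixture: the harmonic field between the walls is
#' `log(r/r1)/log(r2/r1)`.  `endo`/`epi` label the inner/outer walls and
#' `base` the top cap `z = height`.
#'
#' @param r_inner,r_outer inner and outer radii (mm), `r_outer > r_inner > 0`.
#' @param height extrusion length (mm).
#' @param n_r,n_theta,n_z cell counts (radial, angular, axial).
#' @return a [tet_mesh()].
#' @export
make_annulus_mesh <- function(r_inner = 1, r_outer = 2, height = 1,
                              n_r = 4L, n_theta = 32L, n_z = 4L) {
  if (r_inner <= 0 || r_outer <= r_inner) {
    stop("require 0 < r_inner < r_outer")
  }
  rs <- seq(r_inner, r_outer, length.out = n_r + 1L)
  ths <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  zs <- seq(0, height, length.out = n_z + 1L)
  grid <- expand.grid(r = rs, th = ths, z = zs, KEEP.OUT.ATTRS = FALSE)
  nodes <- cbind(grid$r * cos(grid$th), grid$r * sin(grid$th), grid$z)
  nid <- array(seq_len(nrow(nodes)), dim = c(n_r + 1L, n_theta, n_z + 1L))
  idx <- array(0L, dim = c(n_r + 1L, n_theta + 1L, n_z + 1L))
  idx[, seq_len(n_theta), ] <- nid
  idx[, n_theta + 1L, ] <- nid[, 1L, ]  # periodic seam
  tets <- kuhn_tets(idx, nodes)
  bt <- boundary_triangles(tets, nodes)
  r_of <- sqrt(nodes[, 1L]^2 + nodes[, 2L]^2)
  all_at <- function(tri, vals, value, tol) {
    apply(matrix(abs(vals[tri] - value), ncol = 3L), 1L, max) < tol
  }
  tol <- 1e-9 * r_outer
  surfaces <- list(
    endo = bt[all_at(bt, r_of, r_inner, tol), , drop = FALSE],
    epi = bt[all_at(bt, r_of, r_outer, tol), , drop = FALSE],
    base = bt[all_at(bt, nodes[, 3L], height, tol), , drop = FALSE])
  apex <- which(abs(nodes[, 3L]) < tol & abs(r_of - r_inner) < tol)
  tet_mesh(nodes, tets, surfaces, apex)
}

#' Idealized truncated-ellipsoid left-ventricular mesh
#'
#' Generates a truncated prolate ellipsoidal shell standing in for a segmented
#' left ventricle.  The endocardial and epicardial surfaces are coaxial
#' ellipsoids (long axis along z, apex pointing towards negative z) truncated
#' by the basal plane `z = truncation_height`.  The structured parameter grid
#' (transmural, apex-to-base, circumferential) is converted to tetrahedra with
#' the Kuhn subdivision; pole cells collapse to wedges.  The idealized shape
#' is chosen because its shell volume has a closed form, which makes the mesh
#' testable against an analytic oracle (see [ellipsoid_shell_cap_volume()]).
#'
#' @param endo_radii semi-axes (a, b, c) of the endocardial ellipsoid (mm).
#' @param epi_radii semi-axes of the epicardial ellipsoid (mm); must exceed
#'   `endo_radii` component-wise.
#' @param truncation_height basal plane height above the ellipsoid center
#'   (mm); must be below the endocardial pole `endo_radii[3]`.
#' @param edge_length target element edge length (mm).
#' @param seed reserved for randomized variants; mesh generation itself is
#'   deterministic.
#' @param apex_diameter diameter (mm) of the transmural apical cylinder whose
#'   nodes form `apex_region` (2 mm by convention).
#' @return a [tet_mesh()] with labeled `endo`, `epi`, `base` surfaces.
#' @export
make_lv_mesh <- function(endo_radii = c(20, 20, 45), epi_radii = c(30, 30, 55),
                         truncation_height = 10, edge_length = 3,
                         seed = NULL, apex_diameter = 2) {
  endo_radii <- rep(as.numeric(endo_radii), length.out = 3L)
  epi_radii <- rep(as.numeric(epi_radii), length.out = 3L)
  if (any(endo_radii <= 0)) stop("'endo_radii' must be positive")
  if (any(epi_radii <= endo_radii)) {
    stop("'epi_radii' must exceed 'endo_radii' component-wise")
  }
  if (edge_length <= 0) stop("'edge_length' must be positive")
  if (truncation_height >= endo_radii[3L]) {
    stop("'truncation_height' must lie below the endocardial pole (",
         endo_radii[3L], " mm)")
  }
  if (truncation_height <= -endo_radii[3L]) {
    stop("'truncation_height' must lie above the apex")
  }
  phi_t_en <- acos(truncation_height / endo_radii[3L])
  phi_t_ep <- acos(truncation_height / epi_radii[3L])

  r_mid <- (endo_radii + epi_radii) / 2
  circum <- 2 * pi * mean(r_mid[1:2])
  n_theta <- max(8L, 2L * ceiling(circum / edge_length / 2))  # even
  meridian <- mean(r_mid) * (pi - mean(c(phi_t_en, phi_t_ep)))
  n_mu <- max(4L, ceiling(meridian / edge_length))
  thick <- mean(epi_radii - endo_radii)
  n_s <- max(2L, ceiling(thick / edge_length))

  surf_pt <- function(phi, theta, r) {
    cbind(r[1L] * sin(phi) * cos(theta),
          r[2L] * sin(phi) * sin(theta),
          r[3L] * cos(phi))
  }
  ss <- seq(0, 1, length.out = n_s + 1L)
  mus <- seq(0, 1, length.out = n_mu + 1L)
  ths <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]

  ## pole nodes: one per transmural layer
  pole_z <- -((1 - ss) * endo_radii[3L] + ss * epi_radii[3L])
  pole_nodes <- cbind(0, 0, pole_z)
  ## ring nodes: (s, mu>0, theta)
  grid <- expand.grid(s = ss, mu = mus[-1L], th = ths, KEEP.OUT.ATTRS = FALSE)
  phi_en <- pi - grid$mu * (pi - phi_t_en)
  phi_ep <- pi - grid$mu * (pi - phi_t_ep)
  ring_nodes <- (1 - grid$s) * surf_pt(phi_en, grid$th, endo_radii) +
    grid$s * surf_pt(phi_ep, grid$th, epi_radii)
  nodes <- rbind(pole_nodes, ring_nodes)

  n_pole <- n_s + 1L
  ring_id <- array(n_pole + seq_len(nrow(ring_nodes)),
                   dim = c(n_s + 1L, n_mu, n_theta))
  idx <- array(0L, dim = c(n_s + 1L, n_mu + 1L, n_theta + 1L))
  for (it in seq_len(n_theta)) idx[, 1L, it] <- seq_len(n_pole)
  idx[, 1L, n_theta + 1L] <- seq_len(n_pole)
  idx[, 1L + seq_len(n_mu), seq_len(n_theta)] <- ring_id
  idx[, 1L + seq_len(n_mu), n_theta + 1L] <- ring_id[, , 1L]
  tets <- kuhn_tets(idx, nodes)

  ## classify boundary triangles from structural node attributes
  s_idx <- c(seq_len(n_pole), rep(grid$s, 1L)) # s value per node
  s_val <- c(ss, grid$s)
  mu_val <- c(rep(0, n_pole), grid$mu)
  bt <- boundary_triangles(tets, nodes)
  tri_all <- function(vals, value) {
    apply(matrix(abs(vals[bt] - value), ncol = 3L), 1L, max) < 1e-12
  }
  is_base <- tri_all(mu_val, 1)
  is_endo <- tri_all(s_val, 0) & !is_base
  is_epi <- tri_all(s_val, 1) & !is_base
  if (any(!(is_base | is_endo | is_epi))) {
    stop("internal error: unclassified boundary triangles")
  }
  surfaces <- list(endo = bt[is_endo, , drop = FALSE],
                   epi = bt[is_epi, , drop = FALSE],
                   base = bt[is_base, , drop = FALSE])
  apex <- which(sqrt(nodes[, 1L]^2 + nodes[, 2L]^2) <= apex_diameter / 2)
  mesh <- tet_mesh(nodes, tets, surfaces, apex)
  mesh$point_data$structural_s <- s_val
  mesh$point_data$structural_mu <- mu_val
  mesh$meta <- list(endo_radii = endo_radii, epi_radii = epi_radii,
                    truncation_height = truncation_height,
                    edge_length = edge_length, apex_diameter = apex_diameter,
                    long_axis = c(0, 0, 1))
  mesh
}

#' Analytic volume of a truncated ellipsoidal shell
#'
#' Volume between two coaxial ellipsoids, both truncated by the plane
#' `z = h`.  Oracle for the synthetic mesh generator.
#'
#' @param endo_radii,epi_radii semi-axes (mm) of the inner and outer surfaces.
#' @param h truncation plane height above the center (mm).
#' @return volume in mm^3.
#' @export
ellipsoid_shell_cap_volume <- function(endo_radii, epi_radii, h) {
  cap <- function(r) {
    a <- r[1L]; b <- r[2L]; c_ <- r[3L]
    hh <- min(h, c_)
    pi * a * b * ((hh - hh^3 / (3 * c_^2)) - (-c_ + c_ / 3))
  }
  cap(epi_radii) - cap(endo_radii)
}

#' Ventricular cavity volume by tetrahedral partition
#'
#' Computes the cavity volume by partitioning the endocardial surface,
#' connecting every surface triangle to the center of the basal plane, and
#' summing the signed volumes of the resulting tetrahedra.  Because the basal
#' center lies in the plane of the surface's boundary ring, the open basal
#' disc contributes nothing and the sum equals the enclosed volume.
#'
#' @param mesh a [tet_mesh()], or a numeric node matrix if `triangles` is
#'   given explicitly.
#' @param triangles triangle index matrix of the endocardial surface; default
#'   `mesh$surfaces$endo`.
#' @param basal_center center of the basal plane (length-3, mm); default the
#'   centroid of the surface's boundary ring.
#' @param tol tolerance (mm) for the boundary-on-basal-plane check.
#' @return cavity volume in millilitres.
#' @export
cavity_volume <- function(mesh, triangles = NULL, basal_center = NULL,
                          tol = 1e-6) {
  if (inherits(mesh, "tet_mesh")) {
    nodes <- mesh$nodes
    if (is.null(triangles)) triangles <- mesh$surfaces$endo
  } else {
    nodes <- as.matrix(mesh)
    if (is.null(triangles)) stop("'triangles' required with a raw node matrix")
  }
  triangles <- as.matrix(triangles)
  if (nrow(triangles) == 0L) stop("empty endocardial surface")

  ## boundary edges: edges used by exactly one triangle
  edges <- rbind(triangles[, c(1L, 2L)], triangles[, c(2L, 3L)],
                 triangles[, c(3L, 1L)])
  ek <- paste(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
  tab <- table(ek)
  bnd <- edges[ek %in% names(tab)[tab == 1L], , drop = FALSE]

  if (is.null(basal_center)) {
    if (nrow(bnd) == 0L) stop("closed surface: supply 'basal_center' explicitly")
    basal_center <- colMeans(nodes[unique(as.vector(bnd)), , drop = FALSE])
  }
  basal_center <- as.numeric(basal_center)

  if (nrow(bnd) > 0L) {
    ## fit the basal plane through the center and the mean boundary normal:
    ## all boundary nodes must be coplanar with the basal center
    bpts <- nodes[unique(as.vector(bnd)), , drop = FALSE]
    q <- sweep(bpts, 2L, basal_center)
    sv <- svd(q)
    normal <- sv$v[, 3L]
    dist <- abs(q %*% normal)
    scale <- max(1, max(abs(q)))
    bad <- dist > max(tol, 1e-9 * scale)
    if (any(bad)) {
      bad_nodes <- unique(as.vector(bnd))[bad]
      bad_edges <- which(bnd[, 1L] %in% bad_nodes | bnd[, 2L] %in% bad_nodes)
      stop("open endocardial surface: ", length(bad_nodes),
           " boundary node(s) off the basal plane (first offending edges: ",
           paste(utils::head(apply(bnd[bad_edges, , drop = FALSE], 1L, paste,
                                   collapse = "-"), 5L), collapse = ", "), ")")
    }
  }
  a <- sweep(nodes[triangles[, 1L], , drop = FALSE], 2L, basal_center)
  b <- sweep(nodes[triangles[, 2L], , drop = FALSE], 2L, basal_center)
  c_ <- sweep(nodes[triangles[, 3L], , drop = FALSE], 2L, basal_center)
  signed <- (a[, 1L] * (b[, 2L] * c_[, 3L] - b[, 3L] * c_[, 2L]) +
             a[, 2L] * (b[, 3L] * c_[, 1L] - b[, 1L] * c_[, 3L]) +
             a[, 3L] * (b[, 1L] * c_[, 2L] - b[, 2L] * c_[, 1L])) / 6
  abs(sum(signed)) / 1000  # mm^3 -> ml
}

## ---------------------------------------------------------------------------
## Point location: barycentric coordinates in candidate tets found through the
## node->tet incidence of the nearest mesh node, expanding to neighbors and
## finally brute force.  Returns tet index + barycentric weights per point.
node_tet_incidence <- function(mesh) {
  m <- nrow(mesh$tets)
  split(rep(seq_len(m), 4L), as.vector(mesh$tets))
}

nearest_node <- function(nodes, pts, chunk = 512L) {
  out <- integer(nrow(pts))
  nn2 <- rowSums(nodes^2)
  for (start in seq(1L, nrow(pts), by = chunk)) {
    ix <- start:min(start + chunk - 1L, nrow(pts))
    d2 <- outer(rep(1, length(ix)), nn2) - 2 * pts[ix, , drop = FALSE] %*% t(nodes)
    out[ix] <- max.col(-d2, ties.method = "first")
  }
  out
}

bary_coords <- function(nodes, tets, tet_ids, pts) {
  ## barycentric coords of pts (rows) in tets[tet_ids, ]; vectorized pairwise
  v1 <- nodes[tets[tet_ids, 1L], , drop = FALSE]
  v2 <- nodes[tets[tet_ids, 2L], , drop = FALSE]
  v3 <- nodes[tets[tet_ids, 3L], , drop = FALSE]
  v4 <- nodes[tets[tet_ids, 4L], , drop = FALSE]
  t1 <- v1 - v4; t2 <- v2 - v4; t3 <- v3 - v4
  p <- pts - v4
  det3 <- function(a, b, c_) {
    a[, 1L] * (b[, 2L] * c_[, 3L] - b[, 3L] * c_[, 2L]) +
      a[, 2L] * (b[, 3L] * c_[, 1L] - b[, 1L] * c_[, 3L]) +
      a[, 3L] * (b[, 1L] * c_[, 2L] - b[, 2L] * c_[, 1L])
  }
  d0 <- det3(t1, t2, t3)
  b1 <- det3(p, t2, t3) / d0
  b2 <- det3(t1, p, t3) / d0
  b3 <- det3(t1, t2, p) / d0
  cbind(b1, b2, b3, 1 - b1 - b2 - b3)
}

#' Locate points in a tetrahedral mesh
#'
#' @param mesh a [tet_mesh()].
#' @param pts query point matrix (k x 3, mm).
#' @param tol barycentric tolerance: points with all barycentric coordinates
#'   above `-tol` count as inside.
#' @return list with `tet` (index or NA) and `bary` (k x 4 weights).
#' @export
locate_points <- function(mesh, pts, tol = 1e-8) {
  pts <- matrix(as.numeric(pts), ncol = 3L)
  k <- nrow(pts)
  tet <- rep(NA_integer_, k)
  bary <- matrix(NA_real_, k, 4L)
  inc <- node_tet_incidence(mesh)
  nn <- nearest_node(mesh$nodes, pts)

  ## quick reject: farther from the nearest node than its longest incident
  ## edge (with margin) means the point is outside every nearby tet
  h_node <- node_max_edge(mesh)
  d_nn <- sqrt(rowSums((pts - mesh$nodes[nn, , drop = FALSE])^2))
  feasible <- d_nn <= 1.01 * h_node[nn]

  try_candidates <- function(points_ix, cand_list) {
    pair_pt <- rep(points_ix, lengths(cand_list))
    pair_tet <- unlist(cand_list, use.names = FALSE)
    if (length(pair_tet) == 0L) return(invisible(NULL))
    bc <- bary_coords(mesh$nodes, mesh$tets, pair_tet,
                      pts[pair_pt, , drop = FALSE])
    ok <- rowSums(bc >= -tol) == 4L
    if (!any(ok)) return(invisible(NULL))
    hit <- which(ok)[!duplicated(pair_pt[ok])]
    tet[pair_pt[hit]] <<- pair_tet[hit]
    bary[pair_pt[hit], ] <<- bc[hit, , drop = FALSE]
    invisible(NULL)
  }

  todo <- which(feasible)
  if (length(todo) > 0L) try_candidates(todo, inc[nn[todo]])
  cand <- NULL
  for (ring in 1:2) {
    todo <- which(is.na(tet) & feasible)
    if (length(todo) == 0L) break
    ## expand: tets incident to any node of the current candidate tets
    cand <- lapply(todo, function(i) {
      t1 <- if (is.null(cand)) inc[[nn[i]]] else cand[[match(i, attr(cand, "ix"))]]
      if (is.null(t1)) t1 <- inc[[nn[i]]]
      unique(unlist(inc[unique(as.vector(mesh$tets[t1, , drop = FALSE]))],
                    use.names = FALSE))
    })
    attr(cand, "ix") <- todo
    try_candidates(todo, cand)
  }
  list(tet = tet, bary = bary)
}

## longest incident edge per node (cached oracle for the point-location
## quick-reject); recomputed per call, cheap relative to location itself
node_max_edge <- function(mesh) {
  tets <- mesh$tets
  pairs <- rbind(tets[, c(1L, 2L)], tets[, c(1L, 3L)], tets[, c(1L, 4L)],
                 tets[, c(2L, 3L)], tets[, c(2L, 4L)], tets[, c(3L, 4L)])
  len <- sqrt(rowSums((mesh$nodes[pairs[, 1L], , drop = FALSE] -
                       mesh$nodes[pairs[, 2L], , drop = FALSE])^2))
  n <- nrow(mesh$nodes)
  h <- numeric(n)
  agg <- tapply(rep(len, 2L), c(pairs[, 1L], pairs[, 2L]), max)
  h[as.integer(names(agg))] <- as.numeric(agg)
  h
}

#' Linear interpolation of nodal fields at arbitrary points
#'
#' @param mesh a [tet_mesh()].
#' @param values nodal values: vector or (n x k) matrix.
#' @param pts query points (m x 3).
#' @param loc optional precomputed [locate_points()] result.
#' @return matrix (m x k) of interpolated values; rows of points outside the
#'   mesh are NA.  The attribute `inside` flags contained points.
#' @export
interp_at_points <- function(mesh, values, pts, loc = NULL) {
  if (is.null(loc)) loc <- locate_points(mesh, pts)
  values <- as.matrix(values)
  m <- length(loc$tet)
  out <- matrix(NA_real_, m, ncol(values))
  inside <- !is.na(loc$tet)
  if (any(inside)) {
    vtx <- mesh$tets[loc$tet[inside], , drop = FALSE]
    w <- loc$bary[inside, , drop = FALSE]
    acc <- w[, 1L] * values[vtx[, 1L], , drop = FALSE] +
      w[, 2L] * values[vtx[, 2L], , drop = FALSE] +
      w[, 3L] * values[vtx[, 3L], , drop = FALSE] +
      w[, 4L] * values[vtx[, 4L], , drop = FALSE]
    out[inside, ] <- acc
  }
  attr(out, "inside") <- inside
  out
}

## unique node indices of a surface triangle set
surface_nodes <- function(mesh, label) {
  tri <- mesh$surfaces[[label]]
  if (is.null(tri)) stop("missing surface label: ", label)
  sort(unique(as.vector(tri)))
}
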