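## Linear tetrahedral FEM for the Laplace-Dirichlet ("heat transfer")
## problems that define the shape-adapted ventricular coordinates.

## per-element shape-function gradients: list(grads = m x 4 x 3, vol = m)
element_shape_gradients <- function(nodes, tets) {
  m <- nrow(tets)
  a <- nodes[tets[, 1L], , drop = FALSE]
  b <- nodes[tets[, 2L], , drop = FALSE]
  c_ <- nodes[tets[, 3L], , drop = FALSE]
  d <- nodes[tets[, 4L], , drop = FALSE]
  e1 <- b - a; e2 <- c_ - a; e3 <- d - a
  detJ <- e1[, 1L] * (e2[, 2L] * e3[, 3L] - e2[, 3L] * e3[, 2L]) +
    e1[, 2L] * (e2[, 3L] * e3[, 1L] - e2[, 1L] * e3[, 3L]) +
    e1[, 3L] * (e2[, 1L] * e3[, 2L] - e2[, 2L] * e3[, 1L])
  cross <- function(u, v) {
    cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
          u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
          u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
  }
  ## rows of inverse Jacobian transpose: grad of barycentric coords 2..4
  g2 <- cross(e2, e3) / detJ
  g3 <- cross(e3, e1) / detJ
  g4 <- cross(e1, e2) / detJ
  g1 <- -(g2 + g3 + g4)
  grads <- array(0, dim = c(m, 4L, 3L))
  grads[, 1L, ] <- g1; grads[, 2L, ] <- g2
  grads[, 3L, ] <- g3; grads[, 4L, ] <- g4
  list(grads = grads, vol = detJ / 6)
}

## assemble the global stiffness (Laplacian) matrix, dgCMatrix n x n
assemble_stiffness <- function(nodes, tets) {
  sg <- element_shape_gradients(nodes, tets)
  m <- nrow(tets)
  ii <- jj <- integer(16L * m)
  xx <- numeric(16L * m)
  pos <- 0L
  for (p in 1:4) {
    for (q in 1:4) {
      ix <- pos + seq_len(m)
      ii[ix] <- tets[, p]
      jj[ix] <- tets[, q]
      xx[ix] <- rowSums(sg$grads[, p, ] * sg$grads[, q, ]) * sg$vol
      pos <- pos + m
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(nrow(nodes), nrow(nodes)))
}

#' Solve a Laplace-Dirichlet problem on a tetrahedral mesh
#'
#' Discrete harmonic field by linear tetrahedral finite elements with exact
#' Dirichlet values, the building block of the shape-adapted ventricular
#' coordinates.  Steady-state heat conduction with prescribed boundary
#' temperatures is equivalent to this problem.
#'
#' @param mesh a [tet_mesh()].
#' @param dirichlet_sets named or unnamed list; each entry is
#'   `list(nodes = <indices>, value = <scalar or per-node vector>)`.
#' @param exclude_tets optional integer vector of tetrahedra removed from the
#'   assembly (insulating regions, e.g. the apical cylinder in the
#'   circumferential problems).  Nodes that end up detached from the
#'   conducting domain receive NA.
#' @return list with `u` (nodal solution), `residual` (relative interior
#'   residual of the assembled system) and `dirichlet` (logical mask).
#' @export
solve_laplace <- function(mesh, dirichlet_sets, exclude_tets = NULL) {
  n <- nrow(mesh$nodes)
  fixed <- rep(FALSE, n)
  uval <- rep(NA_real_, n)
  for (set in dirichlet_sets) {
    ix <- as.integer(set$nodes)
    if (length(ix) == 0L) next
    if (any(fixed[ix])) stop("Dirichlet node sets must be disjoint")
    fixed[ix] <- TRUE
    uval[ix] <- rep(as.numeric(set$value), length.out = length(ix))
  }
  if (!any(fixed)) stop("singular system: no Dirichlet nodes given")
  vals <- unique(uval[fixed])
  tets <- mesh$tets
  if (!is.null(exclude_tets) && length(exclude_tets) > 0L) {
    tets <- tets[-as.integer(exclude_tets), , drop = FALSE]
  }
  active_nodes <- sort(unique(as.vector(tets)))
  K <- assemble_stiffness(mesh$nodes, tets)

  free <- which(!fixed & seq_len(n) %in% active_nodes)
  fixed_ix <- which(fixed)
  u <- uval
  if (length(free) > 0L) {
    rhs <- -K[free, fixed_ix, drop = FALSE] %*% uval[fixed_ix]
    sol <- Matrix::solve(K[free, free], rhs)
    u[free] <- as.numeric(sol)
  }
  ## relative residual on free (interior) nodes
  resid <- 0
  if (length(free) > 0L) {
    uu <- u
    uu[is.na(uu)] <- 0
    r <- as.numeric(K[free, , drop = FALSE] %*% uu)
    load <- sqrt(sum(as.numeric(K[free, fixed_ix, drop = FALSE] %*%
                                  uval[fixed_ix])^2))
    resid <- if (load > 0) sqrt(sum(r^2)) / load else sqrt(sum(r^2))
  }
  list(u = u, residual = resid, dirichlet = fixed)
}

## element-wise gradient of a nodal scalar field; m x 3
element_gradient <- function(mesh, u, sg = NULL) {
  if (is.null(sg)) sg <- element_shape_gradients(mesh$nodes, mesh$tets)
  tets <- mesh$tets
  uu <- matrix(u[tets], ncol = 4L)
  g <- matrix(0, nrow(tets), 3L)
  for (p in 1:4) g <- g + uu[, p] * sg$grads[, p, ]
  g
}

## volume-weighted average of element vectors onto nodes; n x 3
elements_to_nodes <- function(mesh, ev, sg = NULL) {
  if (is.null(sg)) sg <- element_shape_gradients(mesh$nodes, mesh$tets)
  n <- nrow(mesh$nodes)
  m <- nrow(mesh$tets)
  idx <- as.vector(mesh$tets)            # column-stacked: rep each corner
  w <- rep(sg$vol, times = 4L)
  V <- ev[rep(seq_len(m), times = 4L), , drop = FALSE] * w
  agg <- rowsum(cbind(V, w), group = idx)
  g <- as.integer(rownames(agg))
  out <- matrix(0, n, 3L)
  ws <- numeric(n)
  out[g, ] <- agg[, 1:3]
  ws[g] <- agg[, 4L]
  out / pmax(ws, .Machine$double.xmin)
}
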