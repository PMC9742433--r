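## POD: snapshot-based low-rank model of the fiber projection fields on a
## common equidistant (t, c, l) grid.  The dense fields are sliced with
## transmural normal direction, each (c, l) slice flattened into a vector,
## and all slices of all hearts collected into one snapshot matrix whose SVD
## yields 2-D basis functions Phi_m(c, l).  New sparse data are fitted with a
## gappy POD: a per-transmural-index least squares of the masked basis
## against data transferred to the nearest grid points.

pod_default_grid <- function() c(t = 20L, c = 200L, l = 120L)

## grid coordinate vectors: t and l inclusive endpoints, c periodic
pod_grid_coords <- function(grid) {
  list(t = seq(0, 1, length.out = grid[["t"]]),
       c = (seq_len(grid[["c"]]) - 1L) / grid[["c"]],
       l = seq(0, 1, length.out = grid[["l"]]))
}

#' Build the POD basis from dense synthetic hearts
#'
#' @param hearts list of K >= 2 hearts.  Each heart is either a function
#'   `f(t, c, l)` returning a list/data.frame with `ft`, `fc`, `fl` for
#'   vectors of coordinates, or a list with element `projections`: a
#'   (grid_t x grid_c x grid_l x 3) array already on the common grid.
#' @param grid named sizes of the common equidistant grid, default
#'   `c(t = 20, c = 200, l = 120)`.
#' @param n_modes basis truncation (default 8 modes).
#' @return object of class `pod_model` with orthonormal basis matrices
#'   `Phi[[d]]` ((grid_c * grid_l) x n_modes, one per projection) and the
#'   grid specification.
#' @export
pod_build_basis <- function(hearts, grid = pod_default_grid(), n_modes = 8L) {
  K <- length(hearts)
  if (K < 2L) stop("need >= 2 hearts for a population basis")
  gc_ <- pod_grid_coords(grid)
  nt <- grid[["t"]]; nc <- grid[["c"]]; nl <- grid[["l"]]
  coords_grid <- expand.grid(c = gc_$c, l = gc_$l, KEEP.OUT.ATTRS = FALSE)
  dirs <- c("ft", "fc", "fl")
  ## snapshot matrices per projection: (nc * nl) x (nt * K)
  snaps <- lapply(dirs, function(d) matrix(0, nc * nl, nt * K))
  names(snaps) <- dirs
  for (k in seq_len(K)) {
    h <- hearts[[k]]
    if (is.function(h)) {
      for (i in seq_len(nt)) {
        pr <- h(rep(gc_$t[i], nrow(coords_grid)), coords_grid$c, coords_grid$l)
        for (d in dirs) snaps[[d]][, (k - 1L) * nt + i] <- pr[[d]]
      }
    } else {
      arr <- h$projections
      if (is.null(arr) || !all(dim(arr)[1:3] == c(nt, nc, nl))) {
        stop("heart ", k, ": projections array does not match the common grid (",
             paste(c(nt, nc, nl), collapse = " x "), ")")
      }
      for (d in seq_along(dirs)) {
        for (i in seq_len(nt)) {
          snaps[[dirs[d]]][, (k - 1L) * nt + i] <- as.vector(arr[i, , , d])
        }
      }
    }
  }
  Phi <- lapply(snaps, function(X) {
    ## economical SVD through the small Gram matrix
    G <- crossprod(X)
    e <- eigen(G, symmetric = TRUE)
    pos <- e$values > 1e-12 * max(e$values, 1e-300)
    keep <- min(n_modes, sum(pos))
    U <- X %*% e$vectors[, seq_len(keep), drop = FALSE]
    U <- sweep(U, 2L, sqrt(e$values[seq_len(keep)]), `/`)
    attr(U, "singular_values") <- sqrt(pmax(e$values, 0))
    U
  })
  structure(list(Phi = Phi, grid = grid, n_modes = as.integer(n_modes),
                 n_hearts = K),
            class = "pod_model")
}

## vectorization index of a (c, l) grid point: jc + (kl - 1) * nc
pod_cl_index <- function(jc, kl, nc) jc + (kl - 1L) * nc

#' Gappy-POD weight fit to sparse data
#'
#' The common grid is reduced to the closest grid point of each datum; the
#' scattered data are transferred onto those grid points by (adjoint)
#' tri-linear interpolation; and the weights `w_{m, t_i}` are obtained per
#' transmural index by least squares of the basis restricted to the observed
#' (c, l) points.  Transmural indices without data receive linearly
#' interpolated weights from their observed neighbors.
#'
#' @param model a `pod_model`.
#' @param coords sample coordinates (n x 3 of t, c, l).
#' @param projections sample projections (n x 3 of ft, fc, fl).
#' @param ridge_rel relative Tikhonov regularization applied when a masked
#'   solve is rank-deficient.
#' @return object of class `pod_fit` with `weights`: array
#'   (grid_t x n_modes x 3 projections).
#' @export
pod_fit_gappy <- function(model, coords, projections, ridge_rel = 1e-8) {
  stopifnot(inherits(model, "pod_model"))
  co <- as.matrix(coords)
  pr <- as.matrix(projections)
  nt <- model$grid[["t"]]; nc <- model$grid[["c"]]; nl <- model$grid[["l"]]
  n <- nrow(co)

  ## fractional grid indices
  ti <- pmin(pmax(co[, 1L], 0), 1) * (nt - 1L) + 1
  cj <- (co[, 2L] %% 1) * nc + 1          # periodic
  lk <- pmin(pmax(co[, 3L], 0), 1) * (nl - 1L) + 1

  ## nearest grid point per datum (defines the retained reduced grid)
  near_t <- as.integer(pmin(pmax(round(ti), 1L), nt))
  near_c <- as.integer(((round(cj) - 1L) %% nc) + 1L)
  near_l <- as.integer(pmin(pmax(round(lk), 1L), nl))
  retained <- unique(cbind(near_t, pod_cl_index(near_c, near_l, nc)))

  ## adjoint tri-linear transfer of the data onto grid points
  i0 <- pmin(floor(ti), nt - 1L); wi <- ti - i0
  j0 <- floor(cj); wj <- cj - j0
  k0 <- pmin(floor(lk), nl - 1L); wk <- lk - k0
  num <- array(0, dim = c(nt, nc * nl, 3L))
  den <- matrix(0, nt, nc * nl)
  for (di in 0:1) {
    for (dj in 0:1) {
      for (dk in 0:1) {
        wt <- (if (di == 0) 1 - wi else wi) *
          (if (dj == 0) 1 - wj else wj) *
          (if (dk == 0) 1 - wk else wk)
        gi <- i0 + di
        gj <- ((j0 + dj - 1L) %% nc) + 1L
        gk <- k0 + dk
        flat <- pod_cl_index(gj, gk, nc)
        for (d in 1:3) {
          acc <- rowsum(wt * pr[, d], group = flat + (gi - 1L) * (nc * nl))
          keys <- as.numeric(rownames(acc))
          a_i <- ((keys - 1) %/% (nc * nl)) + 1
          a_f <- ((keys - 1) %% (nc * nl)) + 1
          num[cbind(a_i, a_f, d)] <- num[cbind(a_i, a_f, d)] + acc[, 1L]
        }
        accw <- rowsum(wt, group = flat + (gi - 1L) * (nc * nl))
        keys <- as.numeric(rownames(accw))
        a_i <- ((keys - 1) %/% (nc * nl)) + 1
        a_f <- ((keys - 1) %% (nc * nl)) + 1
        den[cbind(a_i, a_f)] <- den[cbind(a_i, a_f)] + accw[, 1L]
      }
    }
  }

  M <- ncol(model$Phi[[1L]])
  weights <- array(NA_real_, dim = c(nt, M, 3L))
  observed_t <- sort(unique(retained[, 1L]))
  for (i in observed_t) {
    flat <- retained[retained[, 1L] == i, 2L]
    flat <- flat[den[i, flat] > 0]
    if (length(flat) == 0L) next
    for (d in 1:3) {
      A <- model$Phi[[d]][flat, , drop = FALSE]
      y <- num[i, flat, d] / den[i, flat]
      rr <- if (length(flat) < M || qr(A)$rank < M) ridge_rel else 0
      weights[i, , d] <- ls_solve(A, y, ridge_rel = rr)
    }
  }
  ## fill unobserved transmural indices by linear weight interpolation
  filled <- which(!is.na(weights[, 1L, 1L]))
  if (length(filled) == 0L) stop("no transmural index received any data")
  for (d in 1:3) {
    for (m in seq_len(M)) {
      w <- weights[, m, d]
      miss <- which(is.na(w))
      if (length(miss) > 0L) {
        w[miss] <- stats::approx(filled, w[filled], xout = miss, rule = 2)$y
        weights[, m, d] <- w
      }
    }
  }
  structure(list(model = model, weights = weights,
                 observed_t = observed_t),
            class = "pod_fit")
}

#' Evaluate a fitted POD model as a fiber field
#'
#' Reconstructs each projection as `sum_m w_m(t) Phi_m(c, l)` with linear
#' weight interpolation across transmural grid indices and bilinear (periodic
#' in c) interpolation of the 2-D basis functions, then combines the
#' projections with the local frames, renormalizes, and applies the
#' positive-circumferential sign convention.
#'
#' @param fit a `pod_fit`.
#' @param coords (m x 3) matrix of (t, c, l).
#' @param frames `local_frames` at the evaluation points.
#' @return unit fiber matrix (m x 3).
#' @export
pod_evaluate <- function(fit, coords, frames) {
  stopifnot(inherits(fit, "pod_fit"))
  proj <- pod_predict_projections(fit, coords)
  f <- proj[, 1L] * frames$e_t + proj[, 2L] * frames$e_c +
    proj[, 3L] * frames$e_l
  nrm <- sqrt(rowSums(f^2))
  nrm[nrm < 1e-12] <- 1
  fix_fiber_sign_rows(f / nrm, frames)
}

## raw projection predictions (m x 3) of a pod_fit
pod_predict_projections <- function(fit, coords) {
  co <- as.matrix(coords)
  if (any(co[, c(1L, 3L)] < -1e-9 | co[, c(1L, 3L)] > 1 + 1e-9)) {
    warning("coordinates outside [0, 1] clamped")
  }
  nt <- fit$model$grid[["t"]]; nc <- fit$model$grid[["c"]]
  nl <- fit$model$grid[["l"]]
  M <- ncol(fit$model$Phi[[1L]])
  ti <- pmin(pmax(co[, 1L], 0), 1) * (nt - 1L) + 1
  cj <- (co[, 2L] %% 1) * nc + 1
  lk <- pmin(pmax(co[, 3L], 0), 1) * (nl - 1L) + 1
  i0 <- pmin(floor(ti), nt - 1L); wi <- ti - i0
  j0 <- floor(cj); wj <- cj - j0
  k0 <- pmin(floor(lk), nl - 1L); wk <- lk - k0
  j1 <- ((j0 - 1L) %% nc) + 1L
  j2 <- (j0 %% nc) + 1L
  out <- matrix(0, nrow(co), 3L)
  for (d in 1:3) {
    Phi <- fit$model$Phi[[d]]
    ## bilinear basis values at the (c, l) positions, per mode
    bl <- matrix(0, nrow(co), M)
    for (m in seq_len(M)) {
      v11 <- Phi[pod_cl_index(j1, k0, nc), m]
      v21 <- Phi[pod_cl_index(j2, k0, nc), m]
      v12 <- Phi[pod_cl_index(j1, k0 + 1L, nc), m]
      v22 <- Phi[pod_cl_index(j2, k0 + 1L, nc), m]
      bl[, m] <- (1 - wj) * (1 - wk) * v11 + wj * (1 - wk) * v21 +
        (1 - wj) * wk * v12 + wj * wk * v22
    }
    ## linear weight interpolation across transmural indices
    w_lo <- fit$weights[i0, , d, drop = FALSE]
    w_hi <- fit$weights[i0 + 1L, , d, drop = FALSE]
    dim(w_lo) <- dim(w_hi) <- c(nrow(co), M)
    wmat <- (1 - wi) * w_lo + wi * w_hi
    out[, d] <- rowSums(bl * wmat)
  }
  colnames(out) <- c("ft", "fc", "fl")
  out
}
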