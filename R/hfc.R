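## HFC: sparse-to-dense diffusion tensor interpolation with an anisotropic
## Gaussian kernel in the shape-adapted (t, c, l) coordinates, averaging in
## the log-Euclidean framework after transforming every tensor into its local
## frame.  The smoothest of the four reconstruction methods.

#' Anisotropic interpolation kernel
#'
#' SPD 3x3 weighting matrix H in coordinate units (t, c, l).  A scalar or
#' length-3 input builds a diagonal kernel with those bandwidths.
#'
#' @param H SPD 3x3 matrix, or bandwidth vector (recycled to length 3).
#' @return object of class `hfc_kernel`.
#' @export
hfc_kernel <- function(H) {
  if (is.null(dim(H))) {
    H <- diag(rep(as.numeric(H), length.out = 3L), 3L)
  }
  H <- as.matrix(H)
  if (any(dim(H) != 3L)) stop("H must be 3x3")
  if (max(abs(H - t(H))) > 1e-10 * max(abs(H))) stop("H must be symmetric")
  ev <- eigen((H + t(H)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("H must be symmetric positive definite")
  structure(list(H = (H + t(H)) / 2, det = prod(ev)), class = "hfc_kernel")
}

#' Kernel weights between target and data coordinates
#'
#' `w_ij = exp(-d' H^-2 d) / (2 pi det H)` with d the coordinate difference
#' between target j and datum i, wrapped periodically in the circumferential
#' component.  The normalizer cancels in the weighted tensor average and is
#' retained only for fidelity to the kernel definition.
#'
#' @param target_coords (m x 3) matrix of (t, c, l) target coordinates.
#' @param data_coords (n x 3) matrix of (t, c, l) data coordinates.
#' @param kernel an [hfc_kernel()] (or anything accepted by it).
#' @return (m x n) nonnegative weight matrix.
#' @export
hfc_weights <- function(target_coords, data_coords, kernel) {
  if (!inherits(kernel, "hfc_kernel")) kernel <- hfc_kernel(kernel)
  tc <- as.matrix(target_coords)
  dc <- as.matrix(data_coords)
  Hinv <- solve(kernel$H)
  M <- Hinv %*% Hinv                      # H^-2 metric
  dt <- outer(tc[, 1L], dc[, 1L], `-`)
  dcirc <- outer(tc[, 2L], dc[, 2L], `-`)
  dcirc <- dcirc - round(dcirc)           # periodic wrap to [-0.5, 0.5)
  dl <- outer(tc[, 3L], dc[, 3L], `-`)
  quad <- M[1L, 1L] * dt^2 + M[2L, 2L] * dcirc^2 + M[3L, 3L] * dl^2 +
    2 * (M[1L, 2L] * dt * dcirc + M[1L, 3L] * dt * dl + M[2L, 3L] * dcirc * dl)
  exp(-quad) / (2 * pi * kernel$det)
}

## rotate row-tensors into their local frames and take the matrix log;
## returns (n x 6) matrix of vec6 log-tensors
tensors_log_local <- function(tensors6, frames) {
  n <- nrow(tensors6)
  out <- matrix(0, n, 6L)
  for (i in seq_len(n)) {
    R <- cbind(frames$e_t[i, ], frames$e_c[i, ], frames$e_l[i, ])
    Dl <- t(R) %*% vec6_to_sym(tensors6[i, ]) %*% R
    out[i, ] <- sym_to_vec6(spd_log((Dl + t(Dl)) / 2))
  }
  out
}

#' Log-Euclidean kernel interpolation of sparse tensors
#'
#' Interpolated tensor at each target: the kernel-weighted average of the
#' input tensors under the log-Euclidean metric,
#' `D_j = exp(sum_i w_ij log D_i / sum_i w_ij)`, with all tensors first
#' rotated into their local shape-adapted frame (so that the anatomical
#' orientation, not the scanner orientation, is averaged) and the result
#' rotated back at the target frame.  Fibers are the sign-fixed principal
#' eigenvectors of the interpolated tensors.
#'
#' @param data list with `coords` (n x 3 of t, c, l), `tensors` (n x 6),
#'   `frames` (`local_frames`), e.g. from [dataset_stack()].
#' @param target list with `coords` (m x 3) and `frames`.
#' @param kernel an [hfc_kernel()].
#' @param underflow total-weight floor below which a target falls back to its
#'   nearest datum (flagged in the result).
#' @return list with `tensors` (m x 6), `fibers` (m x 3), and `fallback`
#'   (logical, targets that used the nearest-datum fallback).
#' @export
hfc_interpolate <- function(data, target, kernel, underflow = 1e-290) {
  if (!inherits(kernel, "hfc_kernel")) kernel <- hfc_kernel(kernel)
  L <- tensors_log_local(data$tensors, data$frames)
  w <- hfc_weights(target$coords, data$coords, kernel)
  tot <- rowSums(w)
  fallback <- !(tot > underflow) | !is.finite(tot)
  m <- nrow(w)
  out_t <- matrix(0, m, 6L)
  fibers <- matrix(0, m, 3L)
  tfr <- as_frame_rows(target$frames, m)
  for (j in seq_len(m)) {
    if (fallback[j]) {
      ## nearest datum in the kernel metric
      i0 <- which.max(w[j, ])
      if (!is.finite(w[j, i0]) || w[j, i0] == 0) {
        d2 <- (data$coords[, 1L] - target$coords[j, 1L])^2 +
          (pmin(abs(data$coords[, 2L] - target$coords[j, 2L]),
                1 - abs(data$coords[, 2L] - target$coords[j, 2L])))^2 +
          (data$coords[, 3L] - target$coords[j, 3L])^2
        i0 <- which.min(d2)
      }
      Lbar <- L[i0, ]
    } else {
      Lbar <- as.numeric(crossprod(w[j, ], L)) / tot[j]
    }
    R <- cbind(tfr$e_t[j, ], tfr$e_c[j, ], tfr$e_l[j, ])
    D <- R %*% spd_exp(vec6_to_sym(Lbar)) %*% t(R)
    D <- (D + t(D)) / 2
    out_t[j, ] <- sym_to_vec6(D)
    fr_j <- list(e_t = tfr$e_t[j, ], e_c = tfr$e_c[j, ], e_l = tfr$e_l[j, ])
    fibers[j, ] <- suppressWarnings(principal_fiber(D, fr_j))
  }
  if (any(fallback)) {
    message(sum(fallback), " target(s) below the weight underflow floor; ",
            "nearest-datum fallback used")
  }
  colnames(out_t) <- c("Dxx", "Dxy", "Dxz", "Dyy", "Dyz", "Dzz")
  list(tensors = out_t, fibers = fibers, fallback = fallback)
}

#' Kernel bandwidth optimization by slice holdout
#'
#' Searches a diagonal-kernel family `H = diag(h_t, h_c, h_l)` for the
#' bandwidths minimizing the mean absolute angular difference between
#' interpolated fibers and the held-out first eigenvectors, using a
#' leave-one-slice-out protocol on the training dataset.  A log-spaced grid
#' per axis is refined by coordinate descent.
#'
#' @param dataset a `sparse_cdti` with at least two slices.
#' @param holdout_slices indices of slices to hold out (each scored in turn);
#'   default the mid-ventricular slice (see [mid_ventricular_slice()]).
#' @param grid_t,grid_c,grid_l candidate bandwidths per axis.
#' @param refine number of coordinate-descent passes over the three axes.
#' @return list with `kernel` (the optimized [hfc_kernel()]), `error` (its
#'   holdout mean angular error, degrees) and `trace` (evaluated candidates).
#' @export
hfc_optimize_kernel <- function(dataset,
                                holdout_slices = NULL,
                                grid_t = c(0.1, 0.2, 0.4, 0.8),
                                grid_c = c(0.02, 0.04, 0.08, 0.16),
                                grid_l = c(0.05, 0.1, 0.2, 0.4),
                                refine = 2L) {
  if (length(dataset$slices) < 2L) {
    stop("kernel optimization requires at least two slices")
  }
  if (is.null(holdout_slices)) holdout_slices <- mid_ventricular_slice(dataset)

  score <- function(h) {
    k <- hfc_kernel(h)
    errs <- numeric(0)
    for (hs in holdout_slices) {
      train <- dataset_stack(dataset, setdiff(seq_along(dataset$slices), hs))
      test <- dataset_stack(dataset, hs)
      truth <- eigen_fibers(test$tensors, test$frames)
      res <- hfc_interpolate(
        list(coords = as.matrix(train$samples[, c("t", "c", "l")]),
             tensors = train$tensors, frames = train$frames),
        list(coords = as.matrix(test$samples[, c("t", "c", "l")]),
             frames = test$frames),
        k)
      errs <- c(errs, line_angle_diff(res$fibers, truth))
    }
    mean(errs)
  }

  h <- c(grid_t[ceiling(length(grid_t) / 2)],
         grid_c[ceiling(length(grid_c) / 2)],
         grid_l[ceiling(length(grid_l) / 2)])
  grids <- list(grid_t, grid_c, grid_l)
  trace <- list()
  best <- Inf
  for (pass in seq_len(refine)) {
    for (ax in 1:3) {
      vals <- vapply(grids[[ax]], function(g) {
        hh <- h
        hh[ax] <- g
        e <- score(hh)
        trace[[length(trace) + 1L]] <<- c(hh, error = e)
        e
      }, 0)
      h[ax] <- grids[[ax]][which.min(vals)]
      best <- min(vals)
    }
  }
  list(kernel = hfc_kernel(h), error = best,
       trace = do.call(rbind, trace))
}

#' Sign-fixed principal eigenvectors for a block of row-tensors
#'
#' Vectorized convenience around [principal_fiber()] for (n x 6) tensor
#' matrices; warnings from near-degenerate voxels are suppressed (flagging is
#' the caller's job).
#'
#' @param tensors6 (n x 6) tensor matrix (Dxx, Dxy, Dxz, Dyy, Dyz, Dzz).
#' @param frames `local_frames` over the same rows.
#' @return (n x 3) unit fiber matrix.
#' @export
eigen_fibers <- function(tensors6, frames) {
  n <- nrow(tensors6)
  out <- matrix(0, n, 3L)
  for (i in seq_len(n)) {
    fr <- list(e_t = frames$e_t[i, ], e_c = frames$e_c[i, ],
               e_l = frames$e_l[i, ])
    out[i, ] <- suppressWarnings(principal_fiber(vec6_to_sym(tensors6[i, ]), fr))
  }
  out
}
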