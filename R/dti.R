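## Diffusion tensor estimation and the SPD matrix calculus used by the
## log-Euclidean tensor interpolation.

#' Default sparse cDTI diffusion encoding scheme
#'
#' The acquisition emulated throughout the package: 3/3/12 encoding
#' directions at b = 100/200/450 s/mm^2 with eight signal averages, the
#' typical in-vivo protocol for second-order motion-compensated spin-echo
#' cDTI.  Directions are spread quasi-uniformly on the half sphere per shell
#' (deterministic golden-angle spiral).
#'
#' @param bvals shell b-values (s/mm^2).
#' @param ndirs number of directions per shell.
#' @param S0 reference (b = 0) signal amplitude.
#' @param snr signal-to-noise ratio of a single average at b = 0.
#' @param n_averages number of signal averages.
#' @param noise_model one of "rician", "gaussian", "none".
#' @return object of class `dwi_acquisition` with per-volume `bvals` and
#'   unit `bvecs`.
#' @export
dwi_acquisition <- function(bvals = c(100, 200, 450), ndirs = c(3, 3, 12),
                            S0 = 1, snr = 20, n_averages = 8,
                            noise_model = c("rician", "gaussian", "none")) {
  noise_model <- match.arg(noise_model)
  if (length(bvals) != length(ndirs)) stop("'bvals'/'ndirs' length mismatch")
  if (any(bvals < 0)) stop("b-values must be non-negative")
  if (n_averages < 1) stop("'n_averages' must be >= 1")
  b <- rep(bvals, times = ndirs)
  g <- do.call(rbind, lapply(ndirs, sphere_directions))
  structure(list(bvals = b, bvecs = g, S0 = S0, snr = snr,
                 n_averages = as.integer(n_averages),
                 noise_model = noise_model),
            class = "dwi_acquisition")
}

## n quasi-uniform unit directions on the upper half sphere (golden spiral)
sphere_directions <- function(n) {
  i <- seq_len(n) - 0.5
  z <- i / n               # upper hemisphere
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Pack/unpack symmetric 3x3 matrices as length-6 vectors
#'
#' Component order (Dxx, Dxy, Dxz, Dyy, Dyz, Dzz), the row layout used by
#' all tensor-field matrices in the package.
#'
#' @param D symmetric 3x3 matrix; `v` length-6 vector.
#' @return length-6 vector (`sym_to_vec6`) or 3x3 matrix (`vec6_to_sym`).
#' @export
sym_to_vec6 <- function(D) c(D[1, 1], D[1, 2], D[1, 3], D[2, 2], D[2, 3], D[3, 3])

#' @rdname sym_to_vec6
#' @param v length-6 component vector.
#' @export
vec6_to_sym <- function(v) {
  matrix(c(v[1], v[2], v[3],
           v[2], v[4], v[5],
           v[3], v[5], v[6]), 3, 3)
}

#' Clamp a symmetric matrix onto the SPD cone
#'
#' Eigenvalues below `eps_rel * trace` are raised to that floor, so that a
#' noisy tensor estimate never breaks the matrix logarithm.
#'
#' @param D symmetric 3x3 matrix.
#' @param eps_rel relative eigenvalue floor (default 1e-9).
#' @return SPD 3x3 matrix.
#' @export
spd_clamp <- function(D, eps_rel = 1e-9) {
  if (max(abs(D - t(D))) > 1e-8 * max(1, max(abs(D)))) {
    stop("input matrix is not symmetric")
  }
  D <- (D + t(D)) / 2
  e <- eigen(D, symmetric = TRUE)
  tr <- sum(pmax(e$values, 0))
  if (tr <= 0) tr <- 1e-12
  lam <- pmax(e$values, eps_rel * tr)
  e$vectors %*% (lam * t(e$vectors))
}

#' Matrix logarithm / exponential on the SPD cone
#'
#' Eigendecomposition-based maps used by the log-Euclidean tensor
#' interpolation; mutually inverse on SPD matrices.
#'
#' @param D SPD 3x3 matrix (`spd_log`); symmetric 3x3 matrix (`spd_exp`).
#' @param clamp if TRUE (default), [spd_clamp()] is applied before the log.
#' @return symmetric 3x3 matrix (`spd_log`); SPD 3x3 matrix (`spd_exp`).
#' @export
spd_log <- function(D, clamp = TRUE) {
  if (max(abs(D - t(D))) > 1e-8 * max(1, max(abs(D)))) {
    stop("input matrix is not symmetric")
  }
  if (clamp) D <- spd_clamp(D)
  e <- eigen(D, symmetric = TRUE)
  if (any(e$values <= 0)) stop("matrix is not positive definite")
  e$vectors %*% (log(e$values) * t(e$vectors))
}

#' @rdname spd_log
#' @export
spd_exp <- function(D) {
  if (max(abs(D - t(D))) > 1e-8 * max(1, max(abs(D)))) {
    stop("input matrix is not symmetric")
  }
  e <- eigen((D + t(D)) / 2, symmetric = TRUE)
  e$vectors %*% (exp(e$values) * t(e$vectors))
}

#' Moore-Penrose pseudo-inverse diffusion tensor fit
#'
#' Solves the log-linearized Stejskal-Tanner system
#' `ln S = ln S0 - b g' D g` for the six tensor components and `ln S0`
#' jointly (the lowest shell is b = 100 s/mm^2, so no pure reference volume
#' exists and S0 is co-estimated as a seventh unknown).  The estimate is
#' symmetrized and clamped onto the SPD cone.
#'
#' @param signals positive signal amplitudes, one per volume.
#' @param bvals b-values (s/mm^2) per volume.
#' @param bvecs unit gradient directions (n x 3).
#' @return list with `D` (SPD 3x3, mm^2/s), `lnS0`, and `ok` (FALSE when the
#'   voxel had non-positive signals and was skipped).
#' @export
fit_tensor_pinv <- function(signals, bvals, bvecs) {
  bvecs <- as.matrix(bvecs)
  n <- length(signals)
  if (length(bvals) != n || nrow(bvecs) != n) stop("volume count mismatch")
  if (n < 7L) stop("at least 7 volumes are required")
  if (any(signals <= 0)) {
    return(list(D = NULL, lnS0 = NA_real_, ok = FALSE))
  }
  X <- dti_design_matrix(bvals, bvecs)
  r <- qr(X)
  if (r$rank < 7L) {
    stop("rank-deficient diffusion encoding design matrix (rank ", r$rank,
         " < 7): directions do not span 6 independent outer products")
  }
  beta <- qr.coef(r, log(signals))
  D <- vec6_to_sym(beta[2:7])
  list(D = spd_clamp(D), lnS0 = beta[1L], ok = TRUE)
}

## design matrix: column 1 -> ln S0; columns 2..7 -> -(b * outer products)
## with cross terms doubled (so the coefficient is 2*b*gx*gy etc.)
dti_design_matrix <- function(bvals, bvecs) {
  g <- as.matrix(bvecs)
  cbind(1,
        -bvals * g[, 1L]^2,
        -bvals * 2 * g[, 1L] * g[, 2L],
        -bvals * 2 * g[, 1L] * g[, 3L],
        -bvals * g[, 2L]^2,
        -bvals * 2 * g[, 2L] * g[, 3L],
        -bvals * g[, 3L]^2)
}

#' Sign-fixed principal fiber direction of a diffusion tensor
#'
#' First eigenvector of the tensor with the sign convention that the fiber
#' has a positive circumferential component; exact ties fall through the
#' chain e_c, then e_l, then e_t.
#'
#' @param tensor SPD 3x3 diffusion tensor.
#' @param frame list with unit vectors `e_t`, `e_c`, `e_l` (a single-node
#'   slice of a `local_frames` object).
#' @param gap_tol relative eigenvalue-gap threshold below which the principal
#'   direction counts as degenerate (flagged with a warning).
#' @return unit 3-vector with attribute `degenerate`.
#' @export
principal_fiber <- function(tensor, frame, gap_tol = 1e-12) {
  e <- eigen((tensor + t(tensor)) / 2, symmetric = TRUE)
  v <- e$vectors[, 1L]
  degen <- (e$values[1L] - e$values[2L]) <= gap_tol * sum(abs(e$values))
  if (degen) {
    warning("near-degenerate principal eigenvalue; fiber direction unstable")
  }
  v <- fix_fiber_sign(v, frame)
  attr(v, "degenerate") <- degen
  v
}

## sign chain: positive e_c component, ties -> e_l, then e_t
fix_fiber_sign <- function(v, frame) {
  for (ax in list(frame$e_c, frame$e_l, frame$e_t)) {
    d <- sum(v * ax)
    if (abs(d) > 1e-12) {
      if (d < 0) v <- -v
      return(v)
    }
  }
  v
}

## vectorized sign fix for a fiber matrix against frame matrices
fix_fiber_sign_rows <- function(f, frames) {
  d <- rowSums(f * frames$e_c)
  tie <- abs(d) <= 1e-12
  if (any(tie)) {
    d2 <- rowSums(f * frames$e_l)
    d[tie] <- d2[tie]
    tie2 <- tie & abs(d) <= 1e-12
    if (any(tie2)) d[tie2] <- rowSums(f * frames$e_t)[tie2]
  }
  f * ifelse(d < 0, -1, 1)
}

#' Fractional anisotropy of a diffusion tensor
#'
#' @param tensor symmetric 3x3 tensor.
#' @return FA in [0, 1].
#' @export
fractional_anisotropy <- function(tensor) {
  lam <- eigen((tensor + t(tensor)) / 2, symmetric = TRUE, only.values = TRUE)$values
  mb <- mean(lam)
  denom <- sqrt(sum(lam^2))
  if (denom == 0) return(0)
  sqrt(3 / 2) * sqrt(sum((lam - mb)^2)) / denom
}
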