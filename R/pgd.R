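## PGD: separated low-rank representation of the fiber projection fields.
## Each projection f_d(t, c, l) is approximated by a sum of products of three
## 1-D functions discretized with piecewise-linear Galerkin (hat) bases.  The
## per-heart bases are extracted greedily (rank-one enrichment with
## alternating least squares); across hearts the 1-D functions are
## mean-centered and compressed by SVD, giving a population basis whose
## weights are refitted to new sparse data.

## hat-function interpolation matrix: n x N weights of piecewise-linear
## bases at x in [0, 1]; periodic bases identify node N+1 with node 1
hat_matrix <- function(x, N, periodic = FALSE) {
  x <- pmin(pmax(as.numeric(x), 0), 1)
  n <- length(x)
  out <- matrix(0, n, N)
  if (periodic) {
    xs <- x * N            # nodes at k/N, k = 0..N-1
    j0 <- floor(xs)
    w1 <- xs - j0
    j0 <- (j0 %% N) + 1L
    j1 <- (j0 %% N) + 1L
    out[cbind(seq_len(n), j0)] <- out[cbind(seq_len(n), j0)] + (1 - w1)
    out[cbind(seq_len(n), j1)] <- out[cbind(seq_len(n), j1)] + w1
  } else {
    xs <- x * (N - 1L)     # nodes at k/(N-1), k = 0..N-1
    j0 <- pmin(floor(xs), N - 2L)
    w1 <- xs - j0
    j0 <- j0 + 1L
    out[cbind(seq_len(n), j0)] <- out[cbind(seq_len(n), j0)] + (1 - w1)
    out[cbind(seq_len(n), j0 + 1L)] <- out[cbind(seq_len(n), j0 + 1L)] + w1
  }
  out
}

pgd_default_grids <- function() c(t = 14L, c = 24L, l = 10L)

## ridge-stabilized least squares; lambda relative to the Gram trace
ls_solve <- function(A, y, ridge_rel = 0) {
  G <- crossprod(A)
  d <- nrow(G)
  tr <- sum(diag(G))
  if (!is.finite(tr) || tr <= 0) return(numeric(d))  # vanished design
  lam <- ridge_rel * tr / d
  if (lam == 0) {
    sol <- tryCatch(solve(G, crossprod(A, y)), error = function(e) NULL)
    if (!is.null(sol)) return(as.numeric(sol))
    lam <- 1e-12 * tr / d
  }
  sol <- tryCatch(solve(G + diag(lam, d), crossprod(A, y)),
                  error = function(e) NULL)
  if (is.null(sol)) numeric(d) else as.numeric(sol)
}

## greedy rank-one ALS decomposition of scattered data y over hat bases
## Phis = list(t = n x NF, c = n x NG, l = n x NH); returns per-mode
## coefficient lists and the residual
pgd_greedy <- function(Phis, y, n_modes, max_sweeps = 200L, tol = 1e-8) {
  r <- y
  modes <- vector("list", n_modes)
  for (m in seq_len(n_modes)) {
    a <- lapply(Phis, function(P) rep(1, ncol(P)))
    fvals <- lapply(seq_along(Phis), function(v) as.numeric(Phis[[v]] %*% a[[v]]))
    prev <- Inf
    for (sweep in seq_len(max_sweeps)) {
      for (v in seq_along(Phis)) {
        other <- Reduce(`*`, fvals[-v])
        A <- Phis[[v]] * other
        a[[v]] <- ls_solve(A, r)
        fvals[[v]] <- as.numeric(Phis[[v]] %*% a[[v]])
      }
      mis <- sum((r - Reduce(`*`, fvals))^2)
      if (is.finite(prev) && abs(prev - mis) <= tol * max(prev, 1e-300)) break
      prev <- mis
    }
    ## normalization convention: unit-norm c and l factors with non-negative
    ## sum, magnitude carried by the t factor (fixes the scale ambiguity so
    ## that factors are comparable across hearts)
    for (v in 2:3) {
      s <- sqrt(sum(a[[v]]^2))
      if (s > 0) {
        sgn <- if (sum(a[[v]]) < 0) -1 else 1
        a[[v]] <- a[[v]] / (s * sgn)
        a[[1L]] <- a[[1L]] * s * sgn
      }
    }
    fvals <- lapply(seq_along(Phis), function(v) as.numeric(Phis[[v]] %*% a[[v]]))
    r <- r - Reduce(`*`, fvals)
    modes[[m]] <- a
  }
  list(modes = modes, residual = r)
}

#' Build the PGD population basis from dense synthetic hearts
#'
#' Per heart and projection, the fiber projection field is decomposed
#' greedily into `n_modes` rank-one products of 1-D hat-basis functions
#' (alternating least squares).  Across hearts each 1-D function is
#' mean-centered and the variations are compressed by SVD, truncated at
#' `n_svd` modes (capped by the across-heart rank K - 1).
#'
#' @param hearts list of K >= 2 hearts, each a list with `coords` (n x 3 of
#'   t, c, l) and `projections` (n x 3 of ft, fc, fl; see
#'   [fiber_projections()]).
#' @param grids named integer vector of 1-D basis sizes, default
#'   `c(t = 14, c = 24, l = 10)` (circumferential basis periodic).
#' @param n_modes number of PGD modes (default 6).
#' @param n_svd number of SVD variation modes (default 6).
#' @param max_sweeps,tol ALS iteration controls.
#' @return object of class `pgd_model`.
#' @export
pgd_build_basis <- function(hearts, grids = pgd_default_grids(),
                            n_modes = 6L, n_svd = 6L,
                            max_sweeps = 200L, tol = 1e-8) {
  K <- length(hearts)
  if (K < 2L) stop("need >= 2 hearts to extract across-heart variation")
  dirs <- c("ft", "fc", "fl")
  vars <- c("t", "c", "l")
  ## per-heart greedy decompositions
  per_heart <- lapply(hearts, function(h) {
    co <- as.matrix(h$coords)
    Phis <- list(t = hat_matrix(co[, 1L], grids[["t"]]),
                 c = hat_matrix(co[, 2L], grids[["c"]], periodic = TRUE),
                 l = hat_matrix(co[, 3L], grids[["l"]]))
    pr <- as.matrix(h$projections)
    lapply(seq_along(dirs), function(d) {
      pgd_greedy(Phis, pr[, d], n_modes, max_sweeps, tol)$modes
    })
  })
  ## across-heart mean + SVD per (projection, mode, variable)
  basis <- vector("list", length(dirs))
  names(basis) <- dirs
  for (d in seq_along(dirs)) {
    basis[[d]] <- vector("list", n_modes)
    for (m in seq_len(n_modes)) {
      basis[[d]][[m]] <- vector("list", length(vars))
      names(basis[[d]][[m]]) <- vars
      for (v in seq_along(vars)) {
        A <- do.call(rbind, lapply(per_heart, function(ph) ph[[d]][[m]][[v]]))
        mu <- colMeans(A)
        Ac <- sweep(A, 2L, mu)
        sv <- svd(Ac)
        keep <- min(n_svd, K - 1L, sum(sv$d > 1e-12 * max(sv$d, 1e-300)))
        V <- if (keep > 0L) sv$v[, seq_len(keep), drop = FALSE] else
          matrix(0, length(mu), 0L)
        basis[[d]][[m]][[v]] <- list(mean = mu, svd = V,
                                     singular_values = sv$d[seq_len(keep)])
      }
    }
  }
  structure(list(basis = basis, grids = grids, n_modes = n_modes,
                 n_svd = n_svd, n_hearts = K),
            class = "pgd_model")
}

#' Full tensor-product coefficient count of the PGD discretization
#'
#' The number of degrees of freedom a full (non-separated) tensor-product
#' Galerkin discretization of one projection would need on the model's 1-D
#' grids -- the figure the separated representation is compared against
#' (`(N_F + N_G + N_H) * N_PGD` coefficients instead).
#'
#' @param model a `pgd_model`, or a named grid vector.
#' @return integer scalar `N_F * N_G * N_H`.
#' @export
pgd_full_tensor_dof <- function(model = pgd_default_grids()) {
  g <- if (inherits(model, "pgd_model")) model$grids else model
  as.integer(prod(as.integer(g)))
}

## per-direction design blocks B[[v]]: n x (1 + n_svd_eff) columns
## [mean function | svd functions] evaluated at the sample coordinates
pgd_design_blocks <- function(model, coords, d) {
  co <- as.matrix(coords)
  Phis <- list(t = hat_matrix(co[, 1L], model$grids[["t"]]),
               c = hat_matrix(co[, 2L], model$grids[["c"]], periodic = TRUE),
               l = hat_matrix(co[, 3L], model$grids[["l"]]))
  lapply(seq_len(model$n_modes), function(m) {
    lapply(seq_along(Phis), function(v) {
      b <- model$basis[[d]][[m]][[v]]
      cbind(as.numeric(Phis[[v]] %*% b$mean),
            if (ncol(b$svd) > 0L) Phis[[v]] %*% b$svd)
    })
  })
}

#' Fit PGD weights to sparse fiber projections
#'
#' Adapts the population basis to new sparse data: for each projection the
#' weights of Eq.-style expansion
#' `f_d = sum_m prod_v [w_mean f_mean(v) + sum_n w_n f_n(v)]`
#' are estimated mode-by-mode with alternating least squares over the three
#' coordinate directions (a modified PGD performed directly in the SVD
#' basis).  Deterministic: initialized at the population mean
#' (`w_mean = 1`, variation weights 0).
#'
#' @param model a `pgd_model`.
#' @param coords sample coordinates (n x 3 of t, c, l).
#' @param projections sample projections (n x 3 of ft, fc, fl).
#' @param max_sweeps,tol ALS controls.
#' @param ridge_rel relative Tikhonov ridge used when a mode solve is
#'   underdetermined (fewer samples than active weights).
#' @return object of class `pgd_fit`: the model plus fitted `weights` and the
#'   final relative misfit per projection.
#' @export
pgd_fit <- function(model, coords, projections, max_sweeps = 500L,
                    tol = 1e-12, ridge_rel = 1e-8) {
  stopifnot(inherits(model, "pgd_model"))
  pr <- as.matrix(projections)
  n <- nrow(pr)
  dirs <- c("ft", "fc", "fl")
  weights <- vector("list", length(dirs))
  names(weights) <- dirs
  misfit <- numeric(length(dirs))
  for (d in seq_along(dirs)) {
    blocks <- pgd_design_blocks(model, coords, d)
    y <- pr[, d]
    if (sum(y^2) == 0) {
      ## all-zero data: the zero-weight solution is exact
      weights[[d]] <- lapply(blocks, function(bm) {
        lapply(bm, function(B) rep(0, ncol(B)))
      })
      misfit[d] <- 0
      next
    }
    ## weights[[d]][[m]][[v]]: numeric vector (1 + n_svd_eff)
    w <- lapply(blocks, function(bm) {
      lapply(bm, function(B) c(1, rep(0, ncol(B) - 1L)))
    })
    factor_vals <- function(m, v) as.numeric(blocks[[m]][[v]] %*% w[[m]][[v]])
    mode_vals <- vapply(seq_len(model$n_modes), function(m) {
      factor_vals(m, 1L) * factor_vals(m, 2L) * factor_vals(m, 3L)
    }, numeric(n))
    mode_vals <- matrix(mode_vals, nrow = n)
    prev <- Inf
    for (sweep in seq_len(max_sweeps)) {
      for (m in seq_len(model$n_modes)) {
        r <- y - rowSums(mode_vals[, -m, drop = FALSE])
        for (v in 1:3) {
          other <- Reduce(`*`, lapply(setdiff(1:3, v),
                                      function(vv) factor_vals(m, vv)))
          A <- blocks[[m]][[v]] * other
          rr <- if (n < ncol(A)) ridge_rel else 0
          w[[m]][[v]] <- ls_solve(A, r, ridge_rel = rr)
        }
        mode_vals[, m] <- factor_vals(m, 1L) * factor_vals(m, 2L) *
          factor_vals(m, 3L)
      }
      mis <- sum((y - rowSums(mode_vals))^2)
      if (is.finite(prev) && abs(prev - mis) <= tol * max(prev, 1e-300)) break
      prev <- mis
    }
    weights[[d]] <- w
    ssy <- sum(y^2)
    misfit[d] <- if (ssy > 0) sqrt(sum((y - rowSums(mode_vals))^2) / ssy) else 0
  }
  structure(list(model = model, weights = weights, misfit = misfit),
            class = "pgd_fit")
}

#' Evaluate a fitted PGD model as a fiber field
#'
#' Reconstructs the three projection fields at the requested coordinates,
#' combines them with the local frame axes, renormalizes to unit length and
#' applies the positive-circumferential sign convention.  Coordinates
#' outside [0, 1] are clamped with a warning.
#'
#' @param fit a `pgd_fit`.
#' @param coords (m x 3) matrix of (t, c, l).
#' @param frames `local_frames` at the evaluation points.
#' @return unit fiber matrix (m x 3).
#' @export
pgd_evaluate <- function(fit, coords, frames) {
  stopifnot(inherits(fit, "pgd_fit"))
  co <- as.matrix(coords)
  if (any(co[, c(1L, 3L)] < -1e-9 | co[, c(1L, 3L)] > 1 + 1e-9)) {
    warning("coordinates outside [0, 1] clamped")
  }
  proj <- pgd_predict_projections(fit, co)
  f <- proj[, 1L] * frames$e_t + proj[, 2L] * frames$e_c +
    proj[, 3L] * frames$e_l
  nrm <- sqrt(rowSums(f^2))
  nrm[nrm < 1e-12] <- 1
  fix_fiber_sign_rows(f / nrm, frames)
}

## raw projection predictions (m x 3: ft, fc, fl) of a pgd_fit
pgd_predict_projections <- function(fit, coords) {
  co <- as.matrix(coords)
  dirs <- c("ft", "fc", "fl")
  out <- matrix(0, nrow(co), 3L)
  for (d in seq_along(dirs)) {
    blocks <- pgd_design_blocks(fit$model, co, d)
    w <- fit$weights[[d]]
    acc <- 0
    for (m in seq_len(fit$model$n_modes)) {
      fv <- lapply(1:3, function(v) as.numeric(blocks[[m]][[v]] %*% w[[m]][[v]]))
      acc <- acc + fv[[1L]] * fv[[2L]] * fv[[3L]]
    }
    out[, d] <- acc
  }
  colnames(out) <- dirs
  out
}
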