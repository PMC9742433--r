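## Synthetic ground-truth microstructure, diffusion signal simulation, and
## sparse short-axis slice sampling.  These generators stand in for measured
## in-vivo data so that every downstream stage is testable: the idealized
## geometry and rule-based-plus-heterogeneity truth are fixtures, not
## physiological claims.

#' Spatially correlated angular noise field
#'
#' Smoothed white noise on mesh nodes: i.i.d. Gaussian draws convolved with a
#' Gaussian kernel of the stated correlation length, then rescaled to the
#' target standard deviation and centered so the mesh mean is zero.
#'
#' @param positions node positions (n x 3, mm).
#' @param sigma target standard deviation (degrees).
#' @param corr_length kernel correlation length (mm).
#' @param seed integer seed (bit-reproducible given positions and seed).
#' @return numeric vector (degrees), zero mean, sd = sigma.
#' @export
correlated_angle_field <- function(positions, sigma, corr_length, seed) {
  n <- nrow(positions)
  if (sigma == 0) return(numeric(n))
  set.seed(as.integer(seed))
  z <- stats::rnorm(n)
  sm <- numeric(n)
  chunk <- 1024L
  p2 <- rowSums(positions^2)
  for (start in seq(1L, n, by = chunk)) {
    ix <- start:min(start + chunk - 1L, n)
    d2 <- outer(p2[ix], p2, `+`) -
      2 * positions[ix, , drop = FALSE] %*% t(positions)
    w <- exp(-pmax(d2, 0) / (2 * corr_length^2))
    sm[ix] <- as.numeric(w %*% z) / rowSums(w)
  }
  sm <- sm - mean(sm)
  s <- stats::sd(sm)
  if (s == 0) return(numeric(n))
  sm / s * sigma
}

#' Rule-based fiber construction from helix/transverse angles
#'
#' Builds unit fibers by rotating the circumferential axis by the helix angle
#' about the transmural axis and then by the transverse angle about the
#' longitudinal axis:
#' `f = cos(a) cos(b) e_c + cos(a) sin(b) e_t + sin(a) e_l`.
#'
#' @param alpha_deg,beta_deg helix and transverse angles (degrees), per node.
#' @param frames `local_frames` object.
#' @return unit fiber matrix (n x 3).
#' @export
fibers_from_angles <- function(alpha_deg, beta_deg, frames) {
  a <- deg2rad(alpha_deg)
  b <- deg2rad(beta_deg)
  f <- cos(a) * cos(b) * frames$e_c +
    cos(a) * sin(b) * frames$e_t +
    sin(a) * frames$e_l
  rows_normalize(f)
}

#' Ground-truth synthetic microstructure
#'
#' Linear transmural helix/transverse angle profiles plus an optional
#' spatially correlated angular perturbation, evaluated on the supplied
#' coordinates and frames.  With zero perturbation the recomputed helix angle
#' reproduces the generating profile exactly (when the transverse profile is
#' zero).
#'
#' @param coords `ventricular_coords` (or list with element `t`).
#' @param frames `local_frames` object.
#' @param helix_profile `c(alpha_endo, alpha_epi)` in degrees.
#' @param transverse_profile `c(beta_endo, beta_epi)` in degrees.
#' @param perturbation list with `sigma` (degrees) and `corr_length` (mm);
#'   `sigma = 0` disables it.
#' @param seed integer seed for the perturbation field.
#' @param positions node positions (n x 3, mm); required when `sigma > 0`.
#' @return object of class `ground_truth_microstructure` with `fibers`,
#'   the per-node `alpha`/`beta` (including perturbation), and the inputs.
#' @export
make_ground_truth_fibers <- function(coords, frames,
                                     helix_profile = c(60, -60),
                                     transverse_profile = c(0, 0),
                                     perturbation = list(sigma = 0, corr_length = 10),
                                     seed = 1L, positions = NULL) {
  tt <- coords$t
  alpha <- helix_profile[1L] * (1 - tt) + helix_profile[2L] * tt
  beta <- transverse_profile[1L] * (1 - tt) + transverse_profile[2L] * tt
  sigma <- perturbation$sigma %||% 0
  if (sigma > 0) {
    if (is.null(positions)) stop("'positions' required for perturbation > 0")
    corr <- perturbation$corr_length %||% 10
    dalpha <- correlated_angle_field(positions, sigma, corr, seed)
    dbeta <- correlated_angle_field(positions, sigma, corr, seed + 104729L)
    alpha <- alpha + dalpha
    beta <- beta + dbeta
  }
  fibers <- fibers_from_angles(alpha, beta, frames)
  structure(list(fibers = fibers, alpha = alpha, beta = beta,
                 helix_profile = helix_profile,
                 transverse_profile = transverse_profile,
                 perturbation = list(sigma = sigma,
                                     corr_length = perturbation$corr_length %||% 10),
                 seed = as.integer(seed)),
            class = "ground_truth_microstructure")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Diffusion tensors from a fiber field
#'
#' Forward model for the first-eigenvector readout: each tensor is
#' `l1 f f' + l2 s s' + l3 n n'` with the sheet axis taken as the component
#' of the transmural frame axis orthogonal to the fiber and `n = f x s`.
#'
#' @param fibers unit fiber matrix (n x 3).
#' @param frames `local_frames` object.
#' @param eigenvalues strictly decreasing positive eigenvalues (mm^2/s);
#'   default `c(1.5, 0.8, 0.5) * 1e-3`, in the physiological myocardial
#'   diffusivity range.
#' @return tensor field as an (n x 6) matrix with columns
#'   Dxx, Dxy, Dxz, Dyy, Dyz, Dzz.
#' @export
tensors_from_fibers <- function(fibers, frames,
                                eigenvalues = c(1.5, 0.8, 0.5) * 1e-3) {
  if (length(eigenvalues) != 3L || any(diff(eigenvalues) >= 0) ||
      any(eigenvalues <= 0)) {
    stop("'eigenvalues' must satisfy l1 > l2 > l3 > 0 (repeated eigenvalues ",
         "leave the first eigenvector ill-defined)")
  }
  f <- rows_normalize(rbind(fibers))
  n_pts <- nrow(f)
  fr <- as_frame_rows(frames, n_pts)
  s <- fr$e_t - rowSums(fr$e_t * f) * f
  ns <- sqrt(rowSums(s^2))
  deg <- ns < 1e-10
  if (any(deg)) {
    ## fiber parallel to e_t: use the longitudinal axis instead
    s[deg, ] <- fr$e_l[deg, , drop = FALSE] -
      rowSums(fr$e_l[deg, , drop = FALSE] * f[deg, , drop = FALSE]) *
      f[deg, , drop = FALSE]
    ns[deg] <- sqrt(rowSums(s[deg, , drop = FALSE]^2))
  }
  s <- s / ns
  nn <- cbind(f[, 2L] * s[, 3L] - f[, 3L] * s[, 2L],
              f[, 3L] * s[, 1L] - f[, 1L] * s[, 3L],
              f[, 1L] * s[, 2L] - f[, 2L] * s[, 1L])
  l <- eigenvalues
  outer6 <- function(v) cbind(v[, 1L]^2, v[, 1L] * v[, 2L], v[, 1L] * v[, 3L],
                              v[, 2L]^2, v[, 2L] * v[, 3L], v[, 3L]^2)
  D <- l[1L] * outer6(f) + l[2L] * outer6(s) + l[3L] * outer6(nn)
  colnames(D) <- c("Dxx", "Dxy", "Dxz", "Dyy", "Dyz", "Dzz")
  D
}

#' Simulate diffusion-weighted signals
#'
#' Noiseless signal `S = S0 exp(-b g' D g)` per volume, with optional Rician
#' (magnitude MR) or Gaussian noise at the stated SNR, averaged over the
#' acquisition's number of signal averages.
#'
#' @param tensor_field (n x 6) tensor matrix (see [tensors_from_fibers()]).
#' @param acq a [dwi_acquisition()].
#' @param seed integer seed used when noise is enabled.
#' @return signal matrix (n voxels x n volumes).
#' @export
simulate_dwi <- function(tensor_field, acq, seed = 1L) {
  Dv <- rbind(tensor_field)
  g <- acq$bvecs
  b <- acq$bvals
  quad <- Dv[, 1L] %o% g[, 1L]^2 + Dv[, 4L] %o% g[, 2L]^2 +
    Dv[, 6L] %o% g[, 3L]^2 +
    2 * (Dv[, 2L] %o% (g[, 1L] * g[, 2L]) +
         Dv[, 3L] %o% (g[, 1L] * g[, 3L]) +
         Dv[, 5L] %o% (g[, 2L] * g[, 3L]))
  S <- acq$S0 * exp(-sweep(quad, 2L, b, `*`))
  if (acq$noise_model == "none") return(S)
  if (acq$snr <= 0) stop("SNR must be positive when noise is enabled")
  set.seed(as.integer(seed))
  sigma <- acq$S0 / acq$snr
  acc <- matrix(0, nrow(S), ncol(S))
  for (a in seq_len(acq$n_averages)) {
    if (acq$noise_model == "gaussian") {
      acc <- acc + S + matrix(stats::rnorm(length(S), sd = sigma), nrow(S))
    } else {
      re <- S + matrix(stats::rnorm(length(S), sd = sigma), nrow(S))
      im <- matrix(stats::rnorm(length(S), sd = sigma), nrow(S))
      acc <- acc + sqrt(re^2 + im^2)
    }
  }
  acc / acq$n_averages
}

#' Sample nodal fields on sparse short-axis slices
#'
#' Emulates the sparse in-vivo acquisition geometry: voxel centers on a
#' regular in-plane grid inside the myocardium for each short-axis slice.
#' Fields are linearly interpolated at the voxel centers (the circumferential
#' coordinate through its sine/cosine to respect the wrap seam; frames are
#' re-orthonormalized after interpolation).  Through-slice averaging over the
#' slice thickness is an opt-in (`average_thickness`), since point sampling
#' is the default partial-volume model.
#'
#' @param mesh a [tet_mesh()].
#' @param coords `ventricular_coords`.
#' @param frames `local_frames`.
#' @param tensors (n x 6) nodal tensor matrix, or NULL.
#' @param extra named list of additional nodal fields (vectors or matrices)
#'   to interpolate (e.g. ground-truth fibers).
#' @param n_slices number of short-axis slices (apex to base).
#' @param thickness slice thickness (mm), default 8.
#' @param in_plane_spacing voxel spacing (mm), default 2.
#' @param margin longitudinal margin (mm) kept free at apex and base.
#' @param average_thickness if TRUE, average fields over `n_sub` equidistant
#'   positions across the slice thickness.
#' @param n_sub number of through-slice sub-samples when averaging.
#' @return object of class `sparse_cdti`: list of slices ordered apex to
#'   base, each with `z`, `thickness`, `samples` (data.frame x, y, z, t, c,
#'   l, Dxx..Dzz), `frames`, and any `extra` fields.
#' @export
sample_short_axis_slices <- function(mesh, coords, frames, tensors = NULL,
                                     extra = list(), n_slices = 9L,
                                     thickness = 8, in_plane_spacing = 2,
                                     margin = 2, average_thickness = FALSE,
                                     n_sub = 3L) {
  if (n_slices < 1L) stop("'n_slices' must be >= 1")
  zr <- range(mesh$nodes[, 3L])
  lo <- zr[1L] + margin
  hi <- zr[2L] - margin
  if (lo >= hi) stop("slice stack does not fit within the mesh")
  zpos <- if (n_slices == 1L) mean(c(lo, hi)) else seq(lo, hi, length.out = n_slices)
  xs <- seq(min(mesh$nodes[, 1L]), max(mesh$nodes[, 1L]), by = in_plane_spacing)
  ys <- seq(min(mesh$nodes[, 2L]), max(mesh$nodes[, 2L]), by = in_plane_spacing)
  grid2 <- as.matrix(expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE))

  nodal <- cbind(t = coords$t,
                 cs = cos(2 * pi * coords$c), sn = sin(2 * pi * coords$c),
                 l = coords$l,
                 frames$e_t, frames$e_l)
  ncol_fixed <- ncol(nodal)
  if (!is.null(tensors)) nodal <- cbind(nodal, tensors)
  extra_mats <- lapply(extra, as.matrix)
  for (m in extra_mats) nodal <- cbind(nodal, m)

  slices <- vector("list", n_slices)
  for (si in seq_len(n_slices)) {
    center <- interp_at_points(mesh, nodal, cbind(grid2, zpos[si]))
    inside0 <- attr(center, "inside")
    if (average_thickness && n_sub > 1L) {
      offs <- seq(-thickness / 2, thickness / 2, length.out = n_sub)
      acc <- matrix(0, nrow(center), ncol(center))
      wsum <- numeric(nrow(center))
      for (off in offs) {
        v <- interp_at_points(mesh, nodal, cbind(grid2, zpos[si] + off))
        ins <- attr(v, "inside")
        v[!ins, ] <- 0
        acc <- acc + v
        wsum <- wsum + as.numeric(ins)
      }
      keep <- inside0 & wsum > 0
      if (!any(keep)) { slices[[si]] <- NULL; next }
      v <- acc[keep, , drop = FALSE] / wsum[keep]
    } else {
      keep <- inside0
      if (!any(keep)) { slices[[si]] <- NULL; next }
      v <- center[keep, , drop = FALSE]
    }
    cc <- (atan2(v[, 3L], v[, 2L]) / (2 * pi)) %% 1
    e_t <- v[, 5:7, drop = FALSE]
    e_l <- v[, 8:10, drop = FALSE]
    fr <- orthonormal_frames(e_t, e_l)
    samples <- data.frame(x = grid2[keep, 1L], y = grid2[keep, 2L],
                          z = zpos[si],
                          t = pmin(pmax(v[, 1L], 0), 1), c = cc,
                          l = pmin(pmax(v[, 4L], 0), 1))
    sl <- list(z = zpos[si], thickness = thickness, samples = samples,
               frames = fr)
    col0 <- ncol_fixed
    if (!is.null(tensors)) {
      Dm <- v[, col0 + 1:6, drop = FALSE]
      colnames(Dm) <- c("Dxx", "Dxy", "Dxz", "Dyy", "Dyz", "Dzz")
      sl$tensors <- Dm
      col0 <- col0 + 6L
    }
    for (nm in names(extra_mats)) {
      k <- ncol(extra_mats[[nm]])
      sl$extra[[nm]] <- v[, col0 + seq_len(k), drop = FALSE]
      col0 <- col0 + k
    }
    slices[[si]] <- sl
  }
  slices <- Filter(Negate(is.null), slices)
  structure(list(slices = slices,
                 meta = list(n_slices = length(slices), thickness = thickness,
                             in_plane_spacing = in_plane_spacing,
                             averaged = isTRUE(average_thickness))),
            class = "sparse_cdti")
}

#' @export
print.sparse_cdti <- function(x, ...) {
  ns <- vapply(x$slices, function(s) nrow(s$samples), 0L)
  cat("sparse_cdti:", length(x$slices), "slices,", sum(ns), "voxel samples\n")
  cat("  per slice:", paste(ns, collapse = ", "), "\n")
  invisible(x)
}

#' Stack slices of a sparse dataset into one sample table
#'
#' Concatenates the voxel samples, tensors and frames of the selected slices
#' (the input layout expected by the interpolation backends).
#'
#' @param dataset a `sparse_cdti`.
#' @param slices slice indices to include (default all).
#' @return list with `samples`, `tensors`, `frames`, `extra`, `slice_id`.
#' @export
dataset_stack <- function(dataset, slices = seq_along(dataset$slices)) {
  sl <- dataset$slices[slices]
  samples <- do.call(rbind, lapply(sl, `[[`, "samples"))
  tensors <- do.call(rbind, lapply(sl, `[[`, "tensors"))
  frames <- list(
    e_t = do.call(rbind, lapply(sl, function(s) s$frames$e_t)),
    e_c = do.call(rbind, lapply(sl, function(s) s$frames$e_c)),
    e_l = do.call(rbind, lapply(sl, function(s) s$frames$e_l)))
  class(frames) <- "local_frames"
  extras <- list()
  if (length(sl) > 0L && !is.null(sl[[1L]]$extra)) {
    for (nm in names(sl[[1L]]$extra)) {
      extras[[nm]] <- do.call(rbind, lapply(sl, function(s) s$extra[[nm]]))
    }
  }
  list(samples = samples, tensors = tensors, frames = frames, extra = extras,
       slice_id = rep(slices, vapply(sl, function(s) nrow(s$samples), 0L)))
}

#' End-to-end synthetic sparse cDTI dataset
#'
#' Convenience pipeline: idealized LV mesh, ventricular coordinates and
#' frames, ground-truth microstructure, forward diffusion simulation on the
#' sparse slice geometry, and per-voxel tensor refitting -- yielding the
#' sparse dataset a typical in-vivo acquisition would produce, together with
#' the dense ground truth for evaluation.
#'
#' @param mesh optional precomputed [make_lv_mesh()] result.
#' @param coords,frames optional precomputed coordinates/frames for `mesh`.
#' @param helix_profile,transverse_profile,perturbation,seed passed to
#'   [make_ground_truth_fibers()].
#' @param acq a [dwi_acquisition()]; noise model "none" skips refitting noise.
#' @param n_slices,in_plane_spacing,thickness passed to
#'   [sample_short_axis_slices()].
#' @param edge_length mesh edge length (mm) when building the default mesh.
#' @return list with `mesh`, `coords`, `frames`, `truth`, and `dataset`
#'   (a `sparse_cdti` whose tensors come from the simulated signals; each
#'   slice also carries the interpolated ground-truth fibers in
#'   `extra$true_fiber`).
#' @export
make_synthetic_cdti <- function(mesh = NULL, coords = NULL, frames = NULL,
                                helix_profile = c(60, -60),
                                transverse_profile = c(0, 0),
                                perturbation = list(sigma = 0, corr_length = 10),
                                seed = 1L,
                                acq = dwi_acquisition(noise_model = "none"),
                                n_slices = 9L, in_plane_spacing = 2,
                                thickness = 8, edge_length = 3) {
  if (is.null(mesh)) mesh <- make_lv_mesh(edge_length = edge_length)
  if (is.null(coords)) coords <- compute_ventricular_coords(mesh)
  if (is.null(frames)) {
    frames <- compute_local_frames(mesh, coords,
                                   fallback = list(e_t = c(0, 0, -1),
                                                   e_l = coords$long_axis))
  }
  truth <- make_ground_truth_fibers(coords, frames, helix_profile,
                                    transverse_profile, perturbation,
                                    seed = seed, positions = mesh$nodes)
  tensors <- tensors_from_fibers(truth$fibers, frames)
  dataset <- sample_short_axis_slices(mesh, coords, frames, tensors,
                                      extra = list(true_fiber = truth$fibers),
                                      n_slices = n_slices,
                                      thickness = thickness,
                                      in_plane_spacing = in_plane_spacing)
  ## forward-simulate the acquisition per voxel and refit the tensors
  for (si in seq_along(dataset$slices)) {
    sl <- dataset$slices[[si]]
    S <- simulate_dwi(sl$tensors, acq, seed = seed + 7919L * si)
    fit_ok <- rep(TRUE, nrow(S))
    D <- sl$tensors
    for (vx in seq_len(nrow(S))) {
      ft <- fit_tensor_pinv(S[vx, ], acq$bvals, acq$bvecs)
      if (ft$ok) D[vx, ] <- sym_to_vec6(ft$D) else fit_ok[vx] <- FALSE
    }
    dataset$slices[[si]]$tensors <- D
    dataset$slices[[si]]$fit_ok <- fit_ok
    ## renormalize interpolated truth fibers
    tf <- dataset$slices[[si]]$extra$true_fiber
    dataset$slices[[si]]$extra$true_fiber <- rows_normalize(tf)
  }
  list(mesh = mesh, coords = coords, frames = frames, truth = truth,
       dataset = dataset)
}

#' Analytic dense fiber-projection field of a synthetic heart
#'
#' Returns a closure `f(t, c, l) -> list(ft, fc, fl)` giving the fiber
#' projections of a rule-based microstructure (linear transmural helix and
#' transverse profiles) plus smooth low-order harmonic heterogeneity in all
#' three coordinates.  Used to build the PGD/POD population bases from a
#' cohort of synthetic hearts without needing a mesh: the projections are
#' frame-free scalars.
#'
#' @param helix_profile,transverse_profile endpoint angles (degrees).
#' @param heterogeneity_sd amplitude (degrees) of the smooth angular
#'   heterogeneity added to both angles.
#' @param seed integer seed for the harmonic coefficients.
#' @param n_harmonics harmonic orders retained in c and l.
#' @return function of three coordinate vectors returning the projections.
#' @export
synthetic_heart_projections <- function(helix_profile = c(60, -60),
                                        transverse_profile = c(0, 0),
                                        heterogeneity_sd = 0,
                                        seed = 1L, n_harmonics = 2L) {
  set.seed(as.integer(seed))
  ## random smooth angular field: low-order Fourier in c (periodic), low
  ## polynomials in t and l; coefficients scaled to the requested sd
  n_terms <- (2L * n_harmonics + 1L) * (n_harmonics + 1L) * 2L
  coef_a <- stats::rnorm(n_terms)
  coef_b <- stats::rnorm(n_terms)
  smooth_field <- function(t, c_, l, coef) {
    acc <- 0
    idx <- 1L
    for (kc in 0:n_harmonics) {
      cset <- if (kc == 0) list(function(x) rep(1, length(x))) else
        list(function(x) cos(2 * pi * kc * x), function(x) sin(2 * pi * kc * x))
      for (fc_ in cset) {
        for (kl in 0:n_harmonics) {
          acc <- acc + coef[idx] * fc_(c_) * (l - 0.5)^kl * 1 +
            coef[idx + 1L] * fc_(c_) * (l - 0.5)^kl * (t - 0.5)
          idx <- idx + 2L
        }
      }
    }
    acc
  }
  ## calibrate the field sd on a probe grid once
  if (heterogeneity_sd > 0) {
    pg <- expand.grid(t = seq(0, 1, length.out = 7),
                      c_ = seq(0, 1 - 1 / 12, length.out = 12),
                      l = seq(0, 1, length.out = 7))
    sa <- stats::sd(smooth_field(pg$t, pg$c_, pg$l, coef_a))
    sb <- stats::sd(smooth_field(pg$t, pg$c_, pg$l, coef_b))
    coef_a <- coef_a / sa * heterogeneity_sd
    coef_b <- coef_b / sb * heterogeneity_sd
  }
  function(t, c_, l) {
    alpha <- helix_profile[1L] * (1 - t) + helix_profile[2L] * t
    beta <- transverse_profile[1L] * (1 - t) + transverse_profile[2L] * t
    if (heterogeneity_sd > 0) {
      alpha <- alpha + smooth_field(t, c_, l, coef_a)
      beta <- beta + smooth_field(t, c_, l, coef_b)
    }
    a <- deg2rad(alpha)
    b <- deg2rad(beta)
    list(ft = cos(a) * sin(b), fc = cos(a) * cos(b), fl = sin(a))
  }
}
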