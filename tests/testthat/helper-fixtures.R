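## Shared fixtures, built once per test run and memoized.  Sizes are chosen
## so the whole suite stays within a small CPU budget: a coarse idealized LV
## (4 mm edges) is accurate enough for every oracle used here.

.fixtures <- new.env(parent = emptyenv())

lv_fixture <- function() {
  if (is.null(.fixtures$lv)) {
    mesh <- make_lv_mesh(endo_radii = c(20, 20, 45), epi_radii = c(30, 30, 55),
                         truncation_height = 10, edge_length = 4)
    coords <- compute_ventricular_coords(mesh)
    frames <- compute_local_frames(mesh, coords,
                                   fallback = list(e_t = c(0, 0, -1),
                                                   e_l = c(0, 0, 1)))
    .fixtures$lv <- list(mesh = mesh, coords = coords, frames = frames)
  }
  .fixtures$lv
}

## noiseless sparse cDTI dataset over the fixture LV, linear-angle truth
synth_fixture <- function() {
  if (is.null(.fixtures$synth)) {
    lv <- lv_fixture()
    .fixtures$synth <- make_synthetic_cdti(
      mesh = lv$mesh, coords = lv$coords, frames = lv$frames,
      acq = dwi_acquisition(noise_model = "none"),
      n_slices = 9L, in_plane_spacing = 2.5)
  }
  .fixtures$synth
}

## identity local frames replicated over n rows
identity_frames <- function(n) {
  fr <- list(e_t = matrix(rep(c(1, 0, 0), each = n), n),
             e_c = matrix(rep(c(0, 1, 0), each = n), n),
             e_l = matrix(rep(c(0, 0, 1), each = n), n))
  class(fr) <- "local_frames"
  fr
}

## random SPD 3x3 with log-uniform eigenvalues in the diffusivity range
random_spd <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  lam <- sort(exp(stats::runif(3, log(2e-4), log(3e-3))), decreasing = TRUE)
  q %*% (lam * t(q))
}

## brute-force log-Euclidean weighted mean (independent of hfc_interpolate)
brute_logeuclid_mean <- function(tensor_list, w) {
  acc <- matrix(0, 3, 3)
  for (i in seq_along(tensor_list)) {
    e <- eigen(tensor_list[[i]], symmetric = TRUE)
    acc <- acc + w[i] * (e$vectors %*% (log(e$values) * t(e$vectors)))
  }
  acc <- acc / sum(w)
  e <- eigen(acc, symmetric = TRUE)
  e$vectors %*% (exp(e$values) * t(e$vectors))
}

## synthetic-heart cohort for low-rank basis building (scattered samples)
heart_cohort <- function(K = 3L, n = 3000L, heterogeneity_sd = 5,
                         seed = 100L) {
  set.seed(seed)
  lapply(seq_len(K), function(k) {
    co <- cbind(t = stats::runif(n), c = stats::runif(n), l = stats::runif(n))
    fgen <- synthetic_heart_projections(
      helix_profile = c(60, -60) + c(k, -k) * 3,
      heterogeneity_sd = heterogeneity_sd, seed = seed + k)
    pr <- fgen(co[, 1], co[, 2], co[, 3])
    list(coords = co, projections = cbind(ft = pr$ft, fc = pr$fc, fl = pr$fl),
         fgen = fgen)
  })
}
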