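test_that("ground-truth fibers round-trip the generating helix profile", {
  lv <- lv_fixture()
  truth <- make_ground_truth_fibers(lv$coords, lv$frames,
                                    helix_profile = c(60, -60),
                                    transverse_profile = c(0, 0))
  ha <- helix_angle(truth$fibers, lv$frames)
  expect_lt(max(abs(ha - (60 - 120 * lv$coords$t))), 1e-6)
})

test_that("zero profiles give purely circumferential fibers", {
  lv <- lv_fixture()
  truth <- make_ground_truth_fibers(lv$coords, lv$frames,
                                    helix_profile = c(0, 0),
                                    transverse_profile = c(0, 0))
  expect_lt(max(abs(truth$fibers - lv$frames$e_c)), 1e-12)
})

test_that("perturbation fields are reproducible, seed-distinct and centered", {
  lv <- lv_fixture()
  pert <- list(sigma = 10, corr_length = 10)
  t1 <- make_ground_truth_fibers(lv$coords, lv$frames, perturbation = pert,
                                 seed = 1, positions = lv$mesh$nodes)
  t1b <- make_ground_truth_fibers(lv$coords, lv$frames, perturbation = pert,
                                  seed = 1, positions = lv$mesh$nodes)
  t2 <- make_ground_truth_fibers(lv$coords, lv$frames, perturbation = pert,
                                 seed = 2, positions = lv$mesh$nodes)
  expect_identical(t1$fibers, t1b$fibers)          # bit-reproducible
  expect_gt(max(abs(t1$fibers - t2$fibers)), 1e-4) # distinct fields
  dalpha <- t1$alpha - (60 - 120 * lv$coords$t)
  expect_lt(abs(mean(dalpha)), 1)                  # zero mean within 1 degree
  expect_equal(stats::sd(dalpha), 10, tolerance = 1e-6)
})

test_that("tensors from fibers have the stated spectrum and eigenvector", {
  set.seed(14)
  n <- 40
  f <- cardiofiber:::rows_normalize(matrix(rnorm(3 * n), n))
  fr <- identity_frames(n)
  lam <- c(1.5, 0.8, 0.5) * 1e-3
  D <- tensors_from_fibers(f, fr, lam)
  ## trace conservation, exact
  expect_equal(D[, 1] + D[, 4] + D[, 6], rep(sum(lam), n), tolerance = 1e-15)
  ## principal eigenvector is the input fiber (up to sign), for all rows
  for (i in seq_len(n)) {
    e <- eigen(vec6_to_sym(D[i, ]), symmetric = TRUE)
    expect_lt(line_angle_diff(e$vectors[, 1], f[i, ]), 1e-6)
    expect_equal(e$values, sort(lam, decreasing = TRUE), tolerance = 1e-12)
  }
  ## repeated eigenvalues are rejected
  expect_error(tensors_from_fibers(f, fr, c(1.5, 1.5, 0.5) * 1e-3),
               "eigenvalues")
})

test_that("simulated DWI signals follow the Stejskal-Tanner forward model", {
  acq <- dwi_acquisition(noise_model = "none")
  f <- rbind(c(0, 1, 0))
  D <- tensors_from_fibers(f, identity_frames(1))
  S <- simulate_dwi(D, acq)
  Dm <- vec6_to_sym(D[1, ])
  manual <- acq$S0 * exp(-acq$bvals * rowSums((acq$bvecs %*% Dm) * acq$bvecs))
  expect_equal(as.numeric(S), manual, tolerance = 1e-15)
  ## isotropic tensor: identical signal within each shell
  Diso <- matrix(c(1e-3, 0, 0, 1e-3, 0, 1e-3), 1)
  Siso <- simulate_dwi(Diso, acq)
  for (b in unique(acq$bvals)) {
    expect_lt(diff(range(Siso[1, acq$bvals == b])), 1e-15)
  }
  ## noise at non-positive SNR is rejected
  bad <- dwi_acquisition(noise_model = "rician")
  bad$snr <- 0
  expect_error(simulate_dwi(D, bad), "SNR")
})

test_that("eight signal averages shrink the noise by about sqrt(8)", {
  ## Monte-Carlo over many voxels: sd of the averaged Rician signal vs a
  ## single average
  n <- 4000
  D <- matrix(rep(c(1e-3, 0, 0, 1e-3, 0, 1e-3), each = n), n)
  acq1 <- dwi_acquisition(noise_model = "rician", snr = 10, n_averages = 1,
                          bvals = 100, ndirs = 1)
  acq8 <- dwi_acquisition(noise_model = "rician", snr = 10, n_averages = 8,
                          bvals = 100, ndirs = 1)
  s1 <- simulate_dwi(D, acq1, seed = 5)
  s8 <- simulate_dwi(D, acq8, seed = 6)
  ratio <- stats::sd(s1[, 1]) / stats::sd(s8[, 1])
  expect_gt(ratio, sqrt(8) * 0.85)
  expect_lt(ratio, sqrt(8) * 1.15)
})

test_that("short-axis sampling respects the myocardial mask and slice geometry", {
  syn <- synth_fixture()
  st <- dataset_stack(syn$dataset)
  expect_true(all(st$samples$t >= 0 & st$samples$t <= 1))
  expect_true(all(st$samples$l >= 0 & st$samples$l <= 1))
  ## slices ordered apex to base
  zs <- vapply(syn$dataset$slices, `[[`, 0, "z")
  expect_true(all(diff(zs) > 0))
  ## single mid-ventricular slice: longitudinal spread within slice thickness
  one <- sample_short_axis_slices(syn$mesh, syn$coords, syn$frames,
                                  n_slices = 1, thickness = 8,
                                  in_plane_spacing = 2.5)
  lr <- range(one$slices[[1]]$samples$l)
  zr <- diff(range(syn$mesh$nodes[, 3]))
  expect_lt(diff(lr), 8 / zr * 2)   # generous bound: l-span of one slice
  expect_error(sample_short_axis_slices(syn$mesh, syn$coords, syn$frames,
                                        n_slices = 0), "n_slices")
})

test_that("voxel count grows about linearly with the slice count", {
  syn <- synth_fixture()
  n_of <- function(k) {
    d <- sample_short_axis_slices(syn$mesh, syn$coords, syn$frames,
                                  n_slices = k, in_plane_spacing = 3)
    sum(vapply(d$slices, function(s) nrow(s$samples), 0L))
  }
  n3 <- n_of(3)
  n9 <- n_of(9)
  expect_gt(n9 / n3, 2)
  expect_lt(n9 / n3, 4.5)
})
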