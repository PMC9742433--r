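test_that("PGD captures a separable field with a single mode", {
  set.seed(51)
  n <- 3000
  co <- cbind(t = runif(n), c = runif(n), l = runif(n))
  Phis <- list(t = cardiofiber:::hat_matrix(co[, 1], 14),
               c = cardiofiber:::hat_matrix(co[, 2], 24, periodic = TRUE),
               l = cardiofiber:::hat_matrix(co[, 3], 10))
  aF <- sin(seq(0, 2, length.out = 14))
  aG <- 1 + 0.3 * cos(2 * pi * (0:23) / 24)
  aH <- exp(-seq(0, 1, length.out = 10))
  y <- as.numeric((Phis$t %*% aF) * (Phis$c %*% aG) * (Phis$l %*% aH))
  g <- cardiofiber:::pgd_greedy(Phis, y, n_modes = 1)
  expect_gt(1 - sum(g$residual^2) / sum(y^2), 0.999)
})

test_that("identical hearts give zero-energy variation modes and exact means", {
  hearts <- heart_cohort(K = 2, n = 2500, heterogeneity_sd = 4, seed = 60)
  hearts[[2]] <- hearts[[1]]             # duplicate heart
  mod <- pgd_build_basis(hearts, n_modes = 3, n_svd = 3)
  ## all SVD singular values of the variations are ~0
  svals <- unlist(lapply(mod$basis, function(bm) {
    lapply(bm, function(bv) lapply(bv, `[[`, "singular_values"))
  }))
  expect_lt(max(c(0, svals)), 1e-8)
  ## the mean functions reproduce the common field at the samples
  fit <- pgd_fit(mod, hearts[[1]]$coords, hearts[[1]]$projections,
                 max_sweeps = 1)  # weights stay at the mean initialization
  pred <- cardiofiber:::pgd_predict_projections(fit, hearts[[1]]$coords)
  relerr <- sqrt(sum((pred - hearts[[1]]$projections)^2) /
                 sum(hearts[[1]]$projections^2))
  expect_lt(relerr, 0.05)  # greedy truncation error only
})

test_that("the full tensor-product discretization has the documented size", {
  expect_identical(pgd_full_tensor_dof(), 3360L)
  hearts <- heart_cohort(K = 2, n = 600, heterogeneity_sd = 0, seed = 61)
  mod <- pgd_build_basis(hearts, n_modes = 2, n_svd = 2)
  expect_identical(pgd_full_tensor_dof(mod), 3360L)
  ## separated representation size: (N_F + N_G + N_H) * N_PGD
  expect_identical((14L + 24L + 10L) * 6L, 288L)
})

test_that("PGD weight fitting recovers in-span data and descends monotonically", {
  set.seed(52)
  hearts <- heart_cohort(K = 3, n = 2500, heterogeneity_sd = 5, seed = 62)
  mod <- pgd_build_basis(hearts, n_modes = 4, n_svd = 2)
  co <- cbind(t = runif(700), c = runif(700), l = runif(700))
  ## synthesize projections exactly in the fitted span
  pr <- matrix(0, 700, 3)
  for (d in 1:3) {
    blocks <- cardiofiber:::pgd_design_blocks(mod, co, d)
    set.seed(52 + d)
    acc <- 0
    for (m in seq_along(blocks)) {
      fv <- lapply(1:3, function(v) {
        B <- blocks[[m]][[v]]
        as.numeric(B %*% c(1, rnorm(ncol(B) - 1, sd = 0.2)))
      })
      acc <- acc + fv[[1]] * fv[[2]] * fv[[3]]
    }
    pr[, d] <- acc
  }
  fit <- pgd_fit(mod, co, pr)
  expect_lt(max(fit$misfit), 1e-8)
  ## all-zero projections give exactly zero predictions
  fit0 <- pgd_fit(mod, co, matrix(0, 700, 3))
  pred0 <- cardiofiber:::pgd_predict_projections(fit0, co)
  expect_lt(max(abs(pred0)), 1e-10)
})

test_that("POD basis is orthonormal with non-increasing singular values", {
  hearts <- heart_cohort(K = 3, n = 10, heterogeneity_sd = 6, seed = 63)
  gens <- lapply(hearts, `[[`, "fgen")
  grid <- c(t = 8L, c = 40L, l = 24L)
  mod <- pod_build_basis(gens, grid = grid, n_modes = 8)
  for (d in 1:3) {
    Phi <- mod$Phi[[d]]
    expect_equal(crossprod(Phi), diag(ncol(Phi)), tolerance = 1e-10,
                 ignore_attr = TRUE)
    sv <- attr(Phi, "singular_values")
    expect_true(all(diff(sv) <= 1e-9 * sv[1]))
  }
  expect_error(pod_build_basis(gens[1], grid = grid), ">= 2 hearts")
})

test_that("POD reconstructs snapshots exactly when the basis spans them", {
  ## rank-r snapshots with n_modes >= r: every snapshot reproduced
  set.seed(53)
  grid <- c(t = 5L, c = 16L, l = 10L)
  r <- 3
  base <- matrix(rnorm(16 * 10 * r), ncol = r)
  mk_heart <- function(k) {
    cf <- matrix(rnorm(5 * r), 5)
    arr <- array(0, dim = c(5, 16, 10, 3))
    for (i in 1:5) {
      sl <- matrix(base %*% cf[i, ], 16, 10)
      for (d in 1:3) arr[i, , , d] <- sl
    }
    list(projections = arr)
  }
  hearts <- list(mk_heart(1), mk_heart(2))
  mod <- pod_build_basis(hearts, grid = grid, n_modes = r)
  for (d in 1:3) {
    Phi <- mod$Phi[[d]]
    snap <- as.vector(hearts[[1]]$projections[2, , , d])
    proj <- Phi %*% crossprod(Phi, snap)
    expect_lt(max(abs(proj - snap)), 1e-10)
  }
})

test_that("gappy POD: full observation equals orthogonal projection", {
  set.seed(54)
  grid <- c(t = 6L, c = 24L, l = 16L)
  hearts <- lapply(heart_cohort(K = 3, n = 10, heterogeneity_sd = 6,
                                seed = 64), `[[`, "fgen")
  mod <- pod_build_basis(hearts, grid = grid, n_modes = 5)
  gc_ <- cardiofiber:::pod_grid_coords(grid)
  full <- expand.grid(c = gc_$c, l = gc_$l, KEEP.OUT.ATTRS = FALSE)
  co <- cbind(t = rep(gc_$t, each = nrow(full)),
              c = rep(full$c, grid[["t"]]), l = rep(full$l, grid[["t"]]))
  pr <- do.call(cbind, hearts[[1]](co[, 1], co[, 2], co[, 3]))
  fit <- pod_fit_gappy(mod, co, pr)
  ## oracle: dense least squares = Phi' y per transmural slice
  for (i in c(1, 4)) {
    y <- pr[co[, 1] == gc_$t[i], 1]
    expect_equal(fit$weights[i, , 1], as.numeric(crossprod(mod$Phi[[1]], y)),
                 tolerance = 1e-8)
  }
})

test_that("gappy POD recovers in-span data sampled on grid points", {
  set.seed(55)
  grid <- c(t = 8L, c = 32L, l = 20L)
  hearts <- lapply(heart_cohort(K = 3, n = 10, heterogeneity_sd = 6,
                                seed = 65), `[[`, "fgen")
  mod <- pod_build_basis(hearts, grid = grid, n_modes = 6)
  M <- ncol(mod$Phi[[1]])
  w_true <- array(rnorm(grid[["t"]] * M * 3, sd = 0.4),
                  dim = c(grid[["t"]], M, 3))
  fake <- structure(list(model = mod, weights = w_true), class = "pod_fit")
  gc_ <- cardiofiber:::pod_grid_coords(grid)
  co <- do.call(rbind, lapply(seq_len(grid[["t"]]), function(i) {
    jc <- sample(grid[["c"]], 50, replace = TRUE)
    kl <- sample(grid[["l"]], 50, replace = TRUE)
    cbind(t = gc_$t[i], c = gc_$c[jc], l = gc_$l[kl])
  }))
  co <- unique(co)
  pr <- cardiofiber:::pod_predict_projections(fake, co)
  fit <- pod_fit_gappy(mod, co, pr)
  expect_lt(max(abs(fit$weights - w_true)), 1e-8)
})

test_that("transmural indices without data get interpolated weights", {
  set.seed(56)
  grid <- c(t = 6L, c = 24L, l = 16L)
  hearts <- lapply(heart_cohort(K = 3, n = 10, heterogeneity_sd = 6,
                                seed = 66), `[[`, "fgen")
  mod <- pod_build_basis(hearts, grid = grid, n_modes = 4)
  gc_ <- cardiofiber:::pod_grid_coords(grid)
  ## observe only transmural indices 2 and 6
  co <- do.call(rbind, lapply(c(2L, 6L), function(i) {
    cbind(t = gc_$t[i], c = gc_$c[seq(1, 24, by = 2)],
          l = gc_$l[rep(c(3L, 9L), length.out = 12)])
  }))
  pr <- do.call(cbind, hearts[[1]](co[, 1], co[, 2], co[, 3]))
  fit <- pod_fit_gappy(mod, co, pr)
  expect_identical(fit$observed_t, c(2L, 6L))
  expect_true(all(is.finite(fit$weights)))
  ## interior fill is the linear interpolation of the observed neighbors
  lam <- (4 - 2) / (6 - 2)
  expect_equal(fit$weights[4, , 1],
               (1 - lam) * fit$weights[2, , 1] + lam * fit$weights[6, , 1],
               tolerance = 1e-12)
  ## ends are held constant
  expect_equal(fit$weights[1, , 2], fit$weights[2, , 2], tolerance = 1e-12)
})

test_that("evaluated fibers from all model backends are unit sign-fixed vectors", {
  lv <- lv_fixture()
  sub <- sample(nrow(lv$mesh$nodes), 200)
  co <- cbind(t = lv$coords$t[sub], c = lv$coords$c[sub], l = lv$coords$l[sub])
  fr <- list(e_t = lv$frames$e_t[sub, ], e_c = lv$frames$e_c[sub, ],
             e_l = lv$frames$e_l[sub, ])
  class(fr) <- "local_frames"
  hearts <- heart_cohort(K = 2, n = 1500, heterogeneity_sd = 4, seed = 67)
  pmod <- pgd_build_basis(hearts, n_modes = 2, n_svd = 1)
  pfit <- pgd_fit(pmod, hearts[[1]]$coords, hearts[[1]]$projections,
                  max_sweeps = 3)
  f1 <- pgd_evaluate(pfit, co, fr)
  gens <- lapply(heart_cohort(K = 2, n = 10, heterogeneity_sd = 4,
                              seed = 68), `[[`, "fgen")
  qmod <- pod_build_basis(gens, grid = c(t = 6L, c = 24L, l = 16L), n_modes = 4)
  gc_ <- cardiofiber:::pod_grid_coords(c(t = 6L, c = 24L, l = 16L))
  co_g <- as.matrix(expand.grid(t = gc_$t, c = gc_$c[seq(1, 24, 3)],
                                l = gc_$l[seq(1, 16, 3)]))
  pr_g <- do.call(cbind, gens[[1]](co_g[, 1], co_g[, 2], co_g[, 3]))
  qfit <- pod_fit_gappy(qmod, co_g, pr_g)
  f2 <- pod_evaluate(qfit, co, fr)
  f3 <- rbm_evaluate(rbm_params(60, -60), list(t = co[, 1]), fr)
  for (f in list(f1, f2, f3)) {
    expect_equal(rowSums(f^2), rep(1, nrow(f)), tolerance = 1e-10)
    expect_true(all(rowSums(f * fr$e_c) >= -1e-12))
  }
})
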