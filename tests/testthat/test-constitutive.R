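f0 <- c(1, 0, 0)
s0 <- c(0, 1, 0)

test_that("reference state: documented energy value and zero stress", {
  p <- ho_params()
  expect_equal(ho_isochoric_energy(diag(3), f0, s0, p),
               p$A * p$a_iso / (2 * p$b_iso), tolerance = 1e-14)
  expect_lt(max(abs(passive_cauchy_stress(diag(3), f0, s0, p))), 1e-10)
  ## energy is linear in the scaling factor A
  p2 <- ho_params(A = 2)
  expect_equal(ho_isochoric_energy(diag(c(1.2, 1, 1 / 1.2)), f0, s0, p2),
               2 * ho_isochoric_energy(diag(c(1.2, 1, 1 / 1.2)), f0, s0,
                                       ho_params(A = 1)),
               tolerance = 1e-12)
  expect_error(ho_isochoric_energy(diag(c(1, 1, -1)), f0, s0, p),
               "positive definite")
})

test_that("volumetric penalty matches direct arithmetic and is convex", {
  expect_equal(volumetric_energy(1, 0.1), 0)
  expect_equal(volumetric_energy(1.1, 0.1),
               10 * ((1.1^2 - 1) / 2 - log(1.1)), tolerance = 1e-14)
  expect_equal(volumetric_energy(1.1, 0.1), 0.09690, tolerance = 1e-4)
  ## convex near J = 1: positive second difference
  h <- 1e-3
  d2 <- volumetric_energy(1 + h, 0.1) - 2 * volumetric_energy(1, 0.1) +
    volumetric_energy(1 - h, 0.1)
  expect_gt(d2, 0)
  expect_error(volumetric_energy(-0.5, 0.1), "positive")
})

test_that("analytic stress agrees with finite differences of the energy", {
  set.seed(91)
  p <- ho_params()
  for (rep in 1:6) {
    F <- diag(3) + 0.08 * matrix(rnorm(9), 3)
    if (det(F) <= 0.2) next
    fs <- cardiofiber:::rows_normalize(matrix(rnorm(3), 1))[1, ]
    ss_raw <- rnorm(3)
    ss <- ss_raw - sum(ss_raw * fs) * fs
    ss <- ss / sqrt(sum(ss^2))
    sig <- passive_cauchy_stress(F, fs, ss, p)
    expect_lt(max(abs(sig - t(sig))), 1e-12)
    h <- 1e-6
    P <- matrix(0, 3, 3)
    for (i in 1:3) {
      for (j in 1:3) {
        Fp <- F; Fp[i, j] <- Fp[i, j] + h
        Fm <- F; Fm[i, j] <- Fm[i, j] - h
        P[i, j] <- (passive_energy(Fp, fs, ss, p) -
                    passive_energy(Fm, fs, ss, p)) / (2 * h)
      }
    }
    sig_fd <- P %*% t(F) / det(F)
    sig_fd <- (sig_fd + t(sig_fd)) / 2
    expect_lt(max(abs(sig - sig_fd)) / max(abs(sig)), 1e-6)
  }
})

test_that("energy and stress are frame-indifferent", {
  set.seed(92)
  p <- ho_params()
  F <- diag(3) + 0.1 * matrix(rnorm(9), 3)
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  ## pure rotation: zero stress
  expect_lt(max(abs(passive_cauchy_stress(R, f0, s0, p))), 1e-10)
  ## simultaneous rotation of (C, f, s) leaves the energy unchanged
  C <- t(F) %*% F
  e1 <- ho_isochoric_energy(C, f0, s0, p)
  e2 <- ho_isochoric_energy(t(R) %*% C %*% R, as.numeric(t(R) %*% f0),
                            as.numeric(t(R) %*% s0), p)
  expect_equal(e1, e2, tolerance = 1e-12)
  expect_error(passive_cauchy_stress(-diag(3), f0, s0, p), "det F")
})

test_that("active tension respects its three phases and boundary values", {
  ap <- active_params()
  expect_equal(active_tension(0, 0, ap), 0)
  l <- ap$l_r
  t_r <- ap$m * l + ap$b
  ## direct evaluation oracle at peak (t = t0, E_ff = 0)
  eca50 <- ap$Ca0_max / sqrt(expm1(ap$B * (l - ap$l0) * 1e-3))
  T_peak <- ap$T_max * ap$Ca0^2 / (ap$Ca0^2 + eca50^2)
  expect_equal(active_tension(ap$t0, 0, ap), T_peak, tolerance = 1e-12)
  ## zero after relaxation ends
  expect_equal(active_tension(ap$t0 + t_r, 0, ap), 0)
  expect_equal(active_tension(ap$t0 + t_r + 100, 0, ap), 0)
  ## continuity across the phase boundaries, non-negativity throughout
  ts <- seq(0, ap$t0 + t_r + 50, length.out = 4000)
  Tv <- active_tension(ts, 0, ap)
  expect_true(all(Tv >= 0))
  expect_lt(max(abs(diff(Tv))), T_peak * 0.01)
  ## low-length switch: no force at or below the threshold length
  E_thr <- ((ap$l0 / ap$l_r)^2 - 1) / 2
  expect_equal(active_tension(ap$t0, E_thr, ap), 0)
  expect_gt(active_tension(ap$t0, E_thr + 0.05, ap), 0)
  ## unphysical compression is an error
  expect_error(active_tension(10, -0.6, ap), "compression")
})

test_that("active stress acts only along fiber and sheet directions", {
  sig_p <- diag(c(1, 2, 3))
  out0 <- fiber_sheet_stress(sig_p, 5, f0, s0, n = 0)
  expect_equal(out0$sigma_active, 5 * tcrossprod(f0))
  out1 <- fiber_sheet_stress(sig_p, 5, f0, s0, n = 1)
  expect_equal(as.numeric(t(s0) %*% out1$sigma_active %*% s0),
               as.numeric(t(f0) %*% out1$sigma_active %*% f0))
  ## trace identity for unit f, s
  outn <- fiber_sheet_stress(sig_p, 5, f0, s0, n = 0.7)
  expect_equal(sum(diag(outn$sigma_active)), 5 * (1 + 0.7), tolerance = 1e-12)
  expect_error(fiber_sheet_stress(sig_p, 5, f0, s0, n = 1.2), "0, 1")
})
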