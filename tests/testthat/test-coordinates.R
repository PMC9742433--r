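test_that("Laplace solver is exact on the unit slab and obeys bounds", {
  b <- make_box_mesh(c(4, 4, 4))
  sol <- solve_laplace(b, list(list(nodes = surface_nodes(b, "endo"), value = 0),
                               list(nodes = surface_nodes(b, "epi"), value = 1)))
  expect_lt(max(abs(sol$u - b$nodes[, 1])), 1e-10)
  expect_lt(sol$residual, 1e-10)
  ## discrete maximum principle
  expect_true(all(sol$u >= -1e-12 & sol$u <= 1 + 1e-12))
})

test_that("Laplace solver matches the analytic annulus solution", {
  a <- make_annulus_mesh(1, 2, 1, n_r = 6, n_theta = 48, n_z = 3)
  sol <- solve_laplace(a, list(list(nodes = surface_nodes(a, "endo"), value = 0),
                               list(nodes = surface_nodes(a, "epi"), value = 1)))
  r <- sqrt(a$nodes[, 1]^2 + a$nodes[, 2]^2)
  expect_lt(max(abs(sol$u - log(r) / log(2))), 5e-3)
})

test_that("equal Dirichlet values give a constant field; none give an error", {
  b <- make_box_mesh(c(3, 3, 3))
  sol <- solve_laplace(b, list(list(nodes = surface_nodes(b, "endo"), value = 0.4),
                               list(nodes = surface_nodes(b, "epi"), value = 0.4)))
  expect_lt(max(abs(sol$u - 0.4)), 1e-12)
  expect_error(solve_laplace(b, list()), "Dirichlet")
})

test_that("ventricular coordinates meet their boundary contracts", {
  lv <- lv_fixture()
  vc <- lv$coords
  mesh <- lv$mesh
  expect_true(all(vc$t[surface_nodes(mesh, "endo")] == 0))
  expect_true(all(vc$t[surface_nodes(mesh, "epi")] == 1))
  expect_true(all(vc$l[surface_nodes(mesh, "base")] == 1))
  expect_true(all(vc$t >= 0 & vc$t <= 1))
  expect_true(all(vc$l >= 0 & vc$l <= 1))
  expect_true(all(vc$c >= 0 & vc$c < 1))
})

test_that("circumferential coordinate agrees with the axis angle on the idealized LV", {
  lv <- lv_fixture()
  th <- (atan2(lv$mesh$nodes[, 2], lv$mesh$nodes[, 1]) / (2 * pi)) %% 1
  d <- abs(lv$coords$c - th)
  d <- pmin(d, 1 - d)
  expect_lt(max(d), 0.02)
  ## split-plane values are 0 / 0.5 up to the seam convention
  on_plane <- abs(lv$mesh$nodes[, 2]) < 1e-6 &
    !(seq_len(nrow(lv$mesh$nodes)) %in% lv$mesh$apex_region)
  cc <- lv$coords$c[on_plane]
  expect_true(all(pmin(abs(cc), abs(cc - 0.5), abs(cc - 1)) < 1e-9))
})

test_that("missing surface labels are reported by name", {
  lv <- lv_fixture()$mesh
  broken <- lv
  broken$surfaces$epi <- broken$surfaces$epi[integer(0), , drop = FALSE]
  expect_error(compute_ventricular_coords(broken), "epi")
})

test_that("local frames are orthonormal with consistent handedness", {
  lv <- lv_fixture()
  fr <- lv$frames
  expect_lt(max(abs(rowSums(fr$e_t * fr$e_l))), 1e-8)
  expect_lt(max(abs(rowSums(fr$e_t * fr$e_c))), 1e-8)
  expect_lt(max(abs(rowSums(fr$e_c * fr$e_l))), 1e-8)
  expect_lt(max(abs(rowSums(fr$e_t^2) - 1)), 1e-12)
  cross_lt <- cbind(fr$e_l[, 2] * fr$e_t[, 3] - fr$e_l[, 3] * fr$e_t[, 2],
                    fr$e_l[, 3] * fr$e_t[, 1] - fr$e_l[, 1] * fr$e_t[, 3],
                    fr$e_l[, 1] * fr$e_t[, 2] - fr$e_l[, 2] * fr$e_t[, 1])
  expect_lt(max(abs(cross_lt - fr$e_c)), 1e-10)
})

test_that("Gram-Schmidt frame construction matches the hand-computed example", {
  fr <- orthonormal_frames(rbind(c(1, 0, 0)), rbind(c(0.1, 0, 1)))
  expect_equal(as.numeric(fr$e_t), c(1, 0, 0))
  expect_equal(as.numeric(fr$e_l), c(0, 0, 1), tolerance = 1e-12)
  expect_equal(as.numeric(fr$e_c), c(0, 1, 0), tolerance = 1e-12)
  ## idempotence on already-orthonormal inputs
  fr2 <- orthonormal_frames(fr$e_t, fr$e_l)
  expect_equal(fr2$e_t, fr$e_t)
  expect_equal(fr2$e_l, fr$e_l)
  ## degenerate gradient errors name the node, unless a fallback is given
  expect_error(orthonormal_frames(rbind(c(1, 0, 0), c(0, 0, 0)),
                                  rbind(c(0, 0, 1), c(0, 0, 1))),
               "node")
  fr3 <- orthonormal_frames(rbind(c(1, 0, 0), c(0, 0, 0)),
                            rbind(c(0, 0, 1), c(0, 0, 1)),
                            fallback = list(e_t = c(0, 1, 0)))
  expect_equal(as.numeric(fr3$e_t[2, ]), c(0, 1, 0))
  expect_equal(fr3$degenerate, 2L)
})

test_that("streamline normalization is exact on the slab and symmetric under reversal", {
  b <- make_box_mesh(c(5, 5, 5))
  sol <- solve_laplace(b, list(list(nodes = surface_nodes(b, "endo"), value = 0),
                               list(nodes = surface_nodes(b, "epi"), value = 1)))
  g <- cardiofiber:::nodal_gradient(b, sol$u)
  u <- streamline_normalize(b, g)
  expect_lt(max(abs(u - b$nodes[, 1]), na.rm = TRUE), 1e-6)
  expect_length(attr(u, "failed"), 0L)
  u_rev <- streamline_normalize(b, -g)
  expect_lt(max(abs(u + u_rev - 1), na.rm = TRUE), 1e-6)
})

test_that("streamline normalization matches the analytic annulus radial fraction", {
  a <- make_annulus_mesh(1, 2, 0.6, n_r = 5, n_theta = 32, n_z = 2)
  sol <- solve_laplace(a, list(list(nodes = surface_nodes(a, "endo"), value = 0),
                               list(nodes = surface_nodes(a, "epi"), value = 1)))
  term <- union(surface_nodes(a, "endo"), surface_nodes(a, "epi"))
  u <- streamline_normalize(a, cardiofiber:::nodal_gradient(a, sol$u),
                            terminal = term)
  r <- sqrt(a$nodes[, 1]^2 + a$nodes[, 2]^2)
  expect_lt(max(abs(u - (r - 1)), na.rm = TRUE), 0.01)
})

test_that("coordinate fields are monotone along their own streamlines", {
  lv <- lv_fixture()
  ## transmural Laplace value increases along e_t steps at interior nodes
  mesh <- lv$mesh
  set.seed(4)
  ix <- sample(which(lv$coords$t > 0.2 & lv$coords$t < 0.8), 40)
  h <- 0.5
  ahead <- mesh$nodes[ix, ] + h * lv$frames$e_t[ix, ]
  t_ahead <- interp_at_points(mesh, lv$coords$t, ahead)
  ok <- !is.na(t_ahead[, 1])
  expect_true(all(t_ahead[ok, 1] > lv$coords$t[ix][ok]))
})
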