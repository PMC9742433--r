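test_that("shell mesh volume matches the analytic truncated-ellipsoid oracle", {
  ## spherical-cap shell: radii 20/30 mm, base plane through the center
  analytic <- ellipsoid_shell_cap_volume(c(20, 20, 20), c(30, 30, 30), 0)
  vols <- sapply(c(3, 1.5), function(edge) {
    m <- make_lv_mesh(c(20, 20, 20), c(30, 30, 30), truncation_height = 0,
                      edge_length = edge)
    sum(tet_volumes(m))
  })
  expect_lt(abs(vols[1] - analytic) / analytic, 0.03)
  expect_lt(abs(vols[2] - analytic) / analytic, 0.03)
  ## refinement improves the volume estimate
  expect_lte(abs(vols[2] - analytic), abs(vols[1] - analytic) + 1e-9)
})

test_that("halving the edge length refines the mesh by at least 4x", {
  m1 <- make_lv_mesh(edge_length = 6)
  m2 <- make_lv_mesh(edge_length = 3)
  expect_gte(nrow(m2$tets), 4L * nrow(m1$tets))
})

test_that("degenerate geometry parameters are rejected with clear messages", {
  expect_error(make_lv_mesh(c(20, 20, 45), c(30, 30, 55),
                            truncation_height = 45),
               "truncation_height")
  expect_error(make_lv_mesh(c(20, 20, 45), c(19, 30, 55)), "epi_radii")
  expect_error(make_lv_mesh(edge_length = -1), "edge_length")
})

test_that("mesh invariants hold: positive volumes, disjoint labels, apex set", {
  lv <- lv_fixture()$mesh
  expect_true(all(tet_volumes(lv) > 0))
  expect_gt(length(lv$apex_region), 0L)
  key <- function(tri) apply(t(apply(tri, 1, sort)), 1, paste, collapse = "-")
  all_keys <- unlist(lapply(lv$surfaces[c("endo", "epi", "base")], key))
  expect_false(anyDuplicated(all_keys) > 0)
  ## apex region is the stated transmural cylinder
  r <- sqrt(lv$nodes[lv$apex_region, 1]^2 + lv$nodes[lv$apex_region, 2]^2)
  expect_true(all(r <= 1 + 1e-9))
})

test_that("cavity volume reproduces analytic solids", {
  ## hemisphere: (2/3) pi R^3
  m <- make_lv_mesh(c(20, 20, 20), c(30, 30, 30), truncation_height = 0,
                    edge_length = 1.5)
  expect_equal(cavity_volume(m), 2 / 3 * pi * 20^3 / 1000, tolerance = 0.01)

  ## closed cube of side a partitioned from its centroid -> a^3
  a <- 7
  box <- make_box_mesh(c(3, 3, 3), lengths = a)
  all_tris <- cardiofiber:::boundary_triangles(box$tets, box$nodes)
  expect_equal(cavity_volume(box$nodes, triangles = all_tris,
                             basal_center = c(a, a, a) / 2),
               a^3 / 1000, tolerance = 1e-12)

  ## surface collapsed onto the basal plane -> 0
  flat <- box$surfaces$base
  zc <- c(a / 2, a / 2, a)
  expect_equal(cavity_volume(box$nodes, triangles = flat, basal_center = zc), 0)
})

test_that("cavity volume is invariant under rigid-body motion", {
  m <- make_lv_mesh(c(20, 20, 20), c(30, 30, 30), truncation_height = 0,
                    edge_length = 3)
  v0 <- cavity_volume(m)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  R2 <- rbind(c(1, 0, 0), c(0, cos(.3), -sin(.3)), c(0, sin(.3), cos(.3)))
  nodes2 <- m$nodes %*% t(R2 %*% R) + matrix(c(5, -3, 11), nrow(m$nodes), 3,
                                             byrow = TRUE)
  expect_equal(cavity_volume(nodes2, triangles = m$surfaces$endo), v0,
               tolerance = 1e-10)
})

test_that("open endocardial surface off the basal plane is rejected", {
  m <- make_lv_mesh(edge_length = 5)
  ## removing interior endo triangles opens the surface mid-wall
  tri <- m$surfaces$endo
  zmid <- stats::median(m$nodes[tri, 3])
  drop <- apply(matrix(m$nodes[tri, 3], ncol = 3) < zmid, 1, all)
  expect_error(cavity_volume(m$nodes, triangles = tri[!drop, , drop = FALSE]),
               "basal plane")
})

test_that("point location and linear interpolation are exact for linear fields", {
  lv <- lv_fixture()$mesh
  set.seed(2)
  ## points at random barycentric positions of random tets are found
  ix <- sample(nrow(lv$tets), 50)
  w <- matrix(stats::rexp(200), 50)
  w <- w / rowSums(w)
  pts <- sapply(1:3, function(k) {
    rowSums(w * matrix(lv$nodes[lv$tets[ix, ], k], 50))
  })
  loc <- locate_points(lv, pts)
  expect_true(all(!is.na(loc$tet)))
  lin <- 2 * lv$nodes[, 1] - 0.5 * lv$nodes[, 2] + lv$nodes[, 3] + 4
  got <- interp_at_points(lv, lin, pts, loc = loc)
  expect_equal(as.numeric(got),
               2 * pts[, 1] - 0.5 * pts[, 2] + pts[, 3] + 4,
               tolerance = 1e-9)
  ## far-away points are reported outside
  expect_true(is.na(locate_points(lv, rbind(c(500, 0, 0)))$tet))
})
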