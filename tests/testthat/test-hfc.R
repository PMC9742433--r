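test_that("kernel weights follow the anisotropic Gaussian closed form", {
  k <- hfc_kernel(c(0.3, 0.05, 0.2))
  ## zero distance is the maximal weight for that datum
  dc <- rbind(c(0.5, 0.2, 0.5), c(0.6, 0.2, 0.5), c(0.5, 0.9, 0.5))
  w <- hfc_weights(rbind(c(0.5, 0.2, 0.5)), dc, k)
  expect_equal(which.max(w[1, ]), 1L)
  ## |d| = sigma along one axis gives a ratio of exp(-1)
  ki <- hfc_kernel(0.1)
  w2 <- hfc_weights(rbind(c(0, 0.5, 0)), rbind(c(0, 0.5, 0), c(0.1, 0.5, 0)), ki)
  expect_equal(w2[1, 2] / w2[1, 1], exp(-1), tolerance = 1e-12)
  ## periodic wrap: c-distance of 0.95 acts as 0.05
  w3 <- hfc_weights(rbind(c(0.5, 0.975, 0.5)),
                    rbind(c(0.5, 0.025, 0.5), c(0.5, 0.5, 0.5)), k)
  expect_gt(w3[1, 1], w3[1, 2])
  ## singular H is rejected
  expect_error(hfc_kernel(matrix(0, 3, 3)), "positive definite")
})

test_that("weights decrease monotonically with the Mahalanobis distance", {
  set.seed(41)
  H <- diag(c(0.3, 0.07, 0.25))
  k <- hfc_kernel(H)
  tgt <- matrix(runif(3), 1)
  dc <- matrix(runif(300), 100)
  w <- hfc_weights(tgt, dc, k)[1, ]
  d <- sweep(dc, 2, tgt[1, ])
  d[, 2] <- d[, 2] - round(d[, 2])
  Minv2 <- solve(H %*% H)
  maha <- rowSums((d %*% Minv2) * d)
  expect_true(all(diff(w[order(maha)]) <= 1e-15))
})

test_that("single datum and constant fields interpolate exactly", {
  set.seed(42)
  D1 <- random_spd()
  fr <- identity_frames(3)
  data <- list(coords = rbind(c(0.5, 0.2, 0.5)),
               tensors = rbind(sym_to_vec6(D1)),
               frames = identity_frames(1))
  target <- list(coords = rbind(c(0.1, 0.8, 0.9), c(0.5, 0.2, 0.5)),
                 frames = identity_frames(2))
  res <- hfc_interpolate(data, target, hfc_kernel(0.3))
  for (j in 1:2) {
    expect_lt(max(abs(vec6_to_sym(res$tensors[j, ]) - D1)), 1e-12)
  }
  ## identical tensors at many points reproduce the common tensor anywhere
  data2 <- list(coords = matrix(runif(30), 10),
                tensors = matrix(rep(sym_to_vec6(D1), each = 10), 10),
                frames = identity_frames(10))
  res2 <- hfc_interpolate(data2, target, hfc_kernel(0.3))
  expect_lt(max(abs(vec6_to_sym(res2$tensors[1, ]) - D1)), 1e-10)
})

test_that("log-Euclidean weighted mean matches the brute-force oracle", {
  set.seed(43)
  ## two data with equal weights: exp((log D1 + log D2)/2)
  D1 <- random_spd(); D2 <- random_spd()
  data <- list(coords = rbind(c(0.4, 0.2, 0.5), c(0.6, 0.2, 0.5)),
               tensors = rbind(sym_to_vec6(D1), sym_to_vec6(D2)),
               frames = identity_frames(2))
  target <- list(coords = rbind(c(0.5, 0.2, 0.5)), frames = identity_frames(1))
  res <- hfc_interpolate(data, target, hfc_kernel(0.25))
  oracle <- brute_logeuclid_mean(list(D1, D2), c(1, 1))
  expect_lt(max(abs(vec6_to_sym(res$tensors[1, ]) - oracle)) / max(abs(oracle)),
            1e-10)

  ## up to 10 tensors with the kernel's own weights
  n <- 10
  Ds <- replicate(n, random_spd(), simplify = FALSE)
  co <- cbind(runif(n), runif(n), runif(n))
  k <- hfc_kernel(c(0.3, 0.1, 0.3))
  data <- list(coords = co,
               tensors = do.call(rbind, lapply(Ds, sym_to_vec6)),
               frames = identity_frames(n))
  tgt_co <- rbind(c(0.5, 0.5, 0.5))
  res <- hfc_interpolate(data, list(coords = tgt_co,
                                    frames = identity_frames(1)), k)
  w <- hfc_weights(tgt_co, co, k)[1, ]
  oracle <- brute_logeuclid_mean(Ds, w)
  expect_lt(max(abs(vec6_to_sym(res$tensors[1, ]) - oracle)) / max(abs(oracle)),
            1e-10)
})

test_that("log-Euclidean mean of SPD inputs stays SPD for random weights", {
  set.seed(44)
  for (rep in 1:10) {
    n <- sample(2:6, 1)
    Ds <- replicate(n, random_spd(), simplify = FALSE)
    w <- rexp(n)
    M <- brute_logeuclid_mean(Ds, w)
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev > 0))
  }
})

test_that("shrinking bandwidth reduces HFC to the nearest datum", {
  set.seed(45)
  D1 <- random_spd(); D2 <- random_spd()
  data <- list(coords = rbind(c(0.3, 0.2, 0.5), c(0.8, 0.2, 0.5)),
               tensors = rbind(sym_to_vec6(D1), sym_to_vec6(D2)),
               frames = identity_frames(2))
  target <- list(coords = rbind(c(0.4, 0.2, 0.5)), frames = identity_frames(1))
  res <- hfc_interpolate(data, target, hfc_kernel(0.01))
  expect_lt(max(abs(vec6_to_sym(res$tensors[1, ]) - D1)) / max(abs(D1)), 1e-8)
  ## far below underflow the nearest-datum fallback engages, same answer
  expect_message(res2 <- hfc_interpolate(data, target, hfc_kernel(1e-4)),
                 "fallback")
  expect_true(res2$fallback[1])
  expect_lt(max(abs(vec6_to_sym(res2$tensors[1, ]) - D1)) / max(abs(D1)), 1e-8)
})

test_that("tensors are averaged in the local frame, not the scanner frame", {
  ## two data whose tensors are identical in their own rotating frames:
  ## interpolation at an intermediate frame must reproduce the local tensor
  th <- c(0, pi / 2)
  mk_frame <- function(a) {
    list(e_t = c(cos(a), sin(a), 0), e_c = c(-sin(a), cos(a), 0),
         e_l = c(0, 0, 1))
  }
  Dloc <- diag(c(0.5, 1.5, 0.8)) * 1e-3   # in (e_t, e_c, e_l) basis
  rot_tensor <- function(a) {
    fr <- mk_frame(a)
    R <- cbind(fr$e_t, fr$e_c, fr$e_l)
    sym_to_vec6(R %*% Dloc %*% t(R))
  }
  frames2 <- list(e_t = rbind(mk_frame(th[1])$e_t, mk_frame(th[2])$e_t),
                  e_c = rbind(mk_frame(th[1])$e_c, mk_frame(th[2])$e_c),
                  e_l = rbind(mk_frame(th[1])$e_l, mk_frame(th[2])$e_l))
  class(frames2) <- "local_frames"
  data <- list(coords = rbind(c(0.5, 0.1, 0.5), c(0.5, 0.3, 0.5)),
               tensors = rbind(rot_tensor(th[1]), rot_tensor(th[2])),
               frames = frames2)
  mid <- mk_frame(pi / 4)
  target <- list(coords = rbind(c(0.5, 0.2, 0.5)),
                 frames = list(e_t = rbind(mid$e_t), e_c = rbind(mid$e_c),
                               e_l = rbind(mid$e_l)))
  res <- hfc_interpolate(data, target, hfc_kernel(0.3))
  R <- cbind(mid$e_t, mid$e_c, mid$e_l)
  expect_lt(max(abs(vec6_to_sym(res$tensors[1, ]) - R %*% Dloc %*% t(R))) /
              max(Dloc), 1e-10)
})

test_that("kernel optimization honors its argmin contract", {
  syn <- synth_fixture()
  small <- structure(list(slices = syn$dataset$slices[c(4, 5, 6)],
                          meta = syn$dataset$meta), class = "sparse_cdti")
  grid_t <- c(0.2, 0.5)
  grid_c <- c(0.05, 0.2)
  grid_l <- c(0.1, 0.3)
  opt <- hfc_optimize_kernel(small, grid_t = grid_t, grid_c = grid_c,
                             grid_l = grid_l, refine = 1)
  expect_s3_class(opt$kernel, "hfc_kernel")
  ## the returned error is the smallest over everything evaluated
  expect_lte(opt$error, min(opt$trace[, "error"]) + 1e-12)
  expect_error(hfc_optimize_kernel(
    structure(list(slices = syn$dataset$slices[5]), class = "sparse_cdti")),
    "two slices")
})

test_that("spatially constant truth makes the kernel objective flat", {
  ## constant tensors: any bandwidth reconstructs them exactly
  set.seed(46)
  D0 <- random_spd()
  slices <- lapply(1:3, function(si) {
    n <- 25
    co <- data.frame(x = runif(n), y = runif(n), z = si,
                     t = runif(n), c = runif(n), l = si / 4 + runif(n) / 10)
    list(z = si, samples = co,
         tensors = matrix(rep(sym_to_vec6(D0), each = n), n),
         frames = identity_frames(n))
  })
  ds <- structure(list(slices = slices), class = "sparse_cdti")
  opt <- hfc_optimize_kernel(ds, grid_t = c(0.1, 0.5), grid_c = c(0.05, 0.2),
                             grid_l = c(0.1, 0.4), refine = 1)
  expect_lt(diff(range(opt$trace[, "error"])), 1e-6)
  expect_lt(opt$error, 1e-6)
})
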