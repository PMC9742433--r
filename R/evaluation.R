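## Interpolation-quality analyses: leave-one-slice-out error against the
## held-out first eigenvectors, mutual differences between reconstructed
## fields, and helix/transverse angle summaries.

#' Mid-ventricular slice selection
#'
#' The leave-one-out target: the slice whose median longitudinal coordinate
#' is the median across slices, ties broken towards the apex.
#'
#' @param dataset a `sparse_cdti`.
#' @return slice index.
#' @export
mid_ventricular_slice <- function(dataset) {
  med_l <- vapply(dataset$slices, function(s) stats::median(s$samples$l), 0)
  order(med_l)[floor((length(med_l) + 1) / 2)]
}

## assemble train/test splits as plain lists for the method backends
loo_split <- function(dataset, target_slice) {
  train_ix <- setdiff(seq_along(dataset$slices), target_slice)
  train <- dataset_stack(dataset, train_ix)
  test <- dataset_stack(dataset, target_slice)
  list(train = train, test = test)
}

## angles of a stacked split from its tensors' first eigenvectors
stack_fiber_angles <- function(st) {
  f <- eigen_fibers(st$tensors, st$frames)
  list(fibers = f,
       helix = helix_angle(f, st$frames),
       transverse = transverse_angle(f, st$frames))
}

#' Leave-one-slice-out interpolation error
#'
#' Excludes one (by default mid-ventricular) short-axis slice, reconstructs
#' the fiber field from the remaining slices with the requested method, and
#' compares the reconstruction to the held-out slice's first eigenvectors by
#' the absolute angular difference.  Voxels flagged during tensor fitting or
#' with degenerate angles are excluded and counted.
#'
#' @param dataset a `sparse_cdti` with at least 2 slices.
#' @param method `"hfc"`, `"pgd"`, `"pod"`, `"rbm"`, or a function
#'   `f(train, test)` returning an (m x 3) fiber matrix for the test stack
#'   (both arguments as returned by [dataset_stack()]).
#' @param config method options: `kernel` (HFC; optimized on the training
#'   slices when absent), `model` (PGD/POD basis, required for those
#'   methods), and any additional fitting arguments.
#' @param target_slice slice index to hold out; default
#'   [mid_ventricular_slice()].
#' @return list with per-voxel `errors` (degrees), `summary` (median and
#'   percentiles), `n`, `n_excluded`, `method`, `target_slice`.
#' @export
leave_one_slice_out <- function(dataset, method, config = list(),
                                target_slice = NULL) {
  if (length(dataset$slices) < 2L) stop("need at least two slices")
  if (is.null(target_slice)) target_slice <- mid_ventricular_slice(dataset)
  sp <- loo_split(dataset, target_slice)
  train <- sp$train
  test <- sp$test

  ok <- rep(TRUE, nrow(test$samples))
  truth <- eigen_fibers(test$tensors, test$frames)

  fibers <- if (is.function(method)) {
    method(train, test)
  } else {
    reconstruct_fibers(train, test, method, config)
  }
  if (!is.matrix(fibers) || nrow(fibers) != nrow(test$samples)) {
    stop("method did not return one fiber per held-out voxel")
  }
  ok <- ok & rowSums(is.na(fibers)) == 0 & rowSums(is.na(truth)) == 0
  errors <- rep(NA_real_, nrow(test$samples))
  errors[ok] <- line_angle_diff(fibers[ok, , drop = FALSE],
                                truth[ok, , drop = FALSE])
  list(errors = errors[ok],
       summary = angle_percentiles(errors[ok]),
       n = sum(ok), n_excluded = sum(!ok),
       method = if (is.function(method)) "custom" else method,
       target_slice = target_slice,
       fibers = fibers, truth = truth)
}

## dispatch the four built-in reconstruction methods on stacked splits
reconstruct_fibers <- function(train, test, method, config = list()) {
  method <- match.arg(method, c("hfc", "pgd", "pod", "rbm"))
  tr_coords <- as.matrix(train$samples[, c("t", "c", "l")])
  te_coords <- as.matrix(test$samples[, c("t", "c", "l")])
  switch(method,
    hfc = {
      kernel <- config$kernel
      if (is.null(kernel)) {
        ## optimize on the training slices only (nested holdout)
        sub <- structure(list(slices = split_stack_to_slices(train)),
                         class = "sparse_cdti")
        kernel <- hfc_optimize_kernel(sub)$kernel
      }
      hfc_interpolate(
        list(coords = tr_coords, tensors = train$tensors, frames = train$frames),
        list(coords = te_coords, frames = test$frames),
        kernel)$fibers
    },
    rbm = {
      ang <- stack_fiber_angles(train)
      p <- rbm_fit(train$samples$t, ang$helix, ang$transverse)
      rbm_evaluate(p, list(t = test$samples$t), test$frames)
    },
    pgd = {
      if (is.null(config$model)) stop("PGD requires a prebuilt basis in config$model")
      f <- eigen_fibers(train$tensors, train$frames)
      fit <- pgd_fit(config$model,
                     coords = tr_coords,
                     projections = fiber_projections(f, train$frames))
      pgd_evaluate(fit, te_coords, test$frames)
    },
    pod = {
      if (is.null(config$model)) stop("POD requires a prebuilt basis in config$model")
      f <- eigen_fibers(train$tensors, train$frames)
      fit <- pod_fit_gappy(config$model,
                           coords = tr_coords,
                           projections = fiber_projections(f, train$frames))
      pod_evaluate(fit, te_coords, test$frames)
    })
}

## regroup a stacked split back into per-slice structure (for nested holdout)
split_stack_to_slices <- function(st) {
  ids <- unique(st$slice_id)
  lapply(ids, function(id) {
    ix <- st$slice_id == id
    fr <- list(e_t = st$frames$e_t[ix, , drop = FALSE],
               e_c = st$frames$e_c[ix, , drop = FALSE],
               e_l = st$frames$e_l[ix, , drop = FALSE])
    class(fr) <- "local_frames"
    list(z = st$samples$z[which(ix)[1L]], samples = st$samples[ix, , drop = FALSE],
         tensors = st$tensors[ix, , drop = FALSE], frames = fr)
  })
}

#' Mutual angular difference between two fiber fields
#'
#' Distribution of the sign-invariant angle between two reconstructions over
#' a shared point set; symmetric in its arguments, values in [0, 90] degrees.
#'
#' @param fieldA,fieldB (n x 3) fiber matrices over identical points.
#' @return list with `diff` (degrees) and `summary` percentiles.
#' @export
mutual_difference <- function(fieldA, fieldB) {
  fieldA <- as_rows(fieldA)
  fieldB <- as_rows(fieldB)
  if (nrow(fieldA) != nrow(fieldB)) {
    stop("fields must be defined on identical point sets")
  }
  d <- line_angle_diff(fieldA, fieldB)
  list(diff = d, summary = angle_percentiles(d))
}

#' Helix/transverse angle summary of a fiber field
#'
#' Histograms and percentiles of the characteristic angles.  Percentiles use
#' linear interpolation between order statistics; NaN angles (undefined
#' projections) are excluded and counted.
#'
#' @param fibers (n x 3) unit fiber matrix.
#' @param frames `local_frames` over the same points.
#' @param bin_width histogram bin width (degrees), default 5.
#' @return list with per-angle `histogram` (counts, breaks), `summary`
#'   percentiles, and `n_excluded`.
#' @export
angle_summary <- function(fibers, frames, bin_width = 5) {
  fibers <- rbind(fibers)
  if (nrow(fibers) == 0L) stop("empty fiber field")
  h <- helix_angle(fibers, frames)
  tr <- transverse_angle(fibers, frames)
  breaks <- seq(-90, 90, by = bin_width)
  one <- function(a) {
    bad <- !is.finite(a)
    hh <- graphics::hist(a[!bad], breaks = breaks, plot = FALSE)
    list(histogram = list(counts = hh$counts, breaks = hh$breaks),
         summary = angle_percentiles(a[!bad]),
         n_excluded = sum(bad))
  }
  list(helix = one(h), transverse = one(tr))
}

## median and the reported percentiles (linear interpolation, type 7)
angle_percentiles <- function(x) {
  qs <- stats::quantile(x, c(0.05, 0.25, 0.5, 0.75, 0.95), type = 7,
                        names = FALSE, na.rm = TRUE)
  c(median = qs[3L], p5 = qs[1L], p25 = qs[2L], p75 = qs[4L], p95 = qs[5L],
    mean = mean(x, na.rm = TRUE))
}

#' Project fibers onto the local frame axes
#'
#' Scalar projections `f_d = f . e_d` for d in (t, c, l); the representation
#' both low-rank models are built on.
#'
#' @param fibers (n x 3) unit fiber matrix.
#' @param frames `local_frames`.
#' @return (n x 3) matrix with columns `ft`, `fc`, `fl`.
#' @export
fiber_projections <- function(fibers, frames) {
  out <- cbind(ft = rowSums(fibers * frames$e_t),
               fc = rowSums(fibers * frames$e_c),
               fl = rowSums(fibers * frames$e_l))
  out
}
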