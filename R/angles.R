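## Myocardial angle conventions: helix, transverse, sheetlet elevation (E2A),
## and the sign-invariant angular difference between fiber axes.
## All angles are in degrees.

rad2deg <- function(x) x * 180 / pi
deg2rad <- function(x) x * pi / 180

rows_normalize <- function(m) {
  m / sqrt(rowSums(m^2))
}

## promote a vector to a 1 x 3 matrix, stripping dimnames (rbind() would
## otherwise attach the deparsed argument name as a row name)
as_rows <- function(x) {
  x <- rbind(x)
  dimnames(x) <- NULL
  x
}

as_frame_rows <- function(frame, n = NULL) {
  ## accept a `local_frames` object or a single-triad list; return matrices
  f <- list(e_t = as_rows(frame$e_t), e_c = as_rows(frame$e_c),
            e_l = as_rows(frame$e_l))
  if (!is.null(n) && nrow(f$e_t) == 1L && n > 1L) {
    f <- lapply(f, function(m) m[rep(1L, n), , drop = FALSE])
  }
  f
}

#' Helix angle of a fiber direction
#'
#' Angle between the projection of the fiber onto the local
#' longitudinal-circumferential plane and the circumferential axis, in
#' (-90, 90] degrees.  Positive when the fiber and the longitudinal axis
#' point into the same half-space.  A fiber perpendicular to the plane
#' (purely transmural) has no defined helix angle and returns NaN.
#'
#' @param f unit fiber vector(s): length-3 vector or (n x 3) matrix.
#' @param frame local frame (`local_frames` object or single triad list).
#' @param proj_tol projection norm below which the angle is undefined.
#' @return numeric vector of angles (degrees); NaN where undefined.
#' @export
helix_angle <- function(f, frame, proj_tol = 1e-12) {
  f <- as_rows(f)
  fr <- as_frame_rows(frame, nrow(f))
  fc <- rowSums(f * fr$e_c)
  fl <- rowSums(f * fr$e_l)
  ## sign invariance: fibers are axes; fix sign so f.e_c >= 0 first
  flip <- fc < 0
  fc[flip] <- -fc[flip]
  fl[flip] <- -fl[flip]
  pn <- sqrt(fc^2 + fl^2)
  ang <- rad2deg(atan2(fl, fc))
  ang[pn < proj_tol] <- NaN
  ## (-90, 90] convention: exact -90 maps to +90
  ang[!is.nan(ang) & ang <= -90] <- 90
  ang
}

#' Transverse angle of a fiber direction
#'
#' Angle between the circumferential axis and the projection of the fiber
#' onto the local transmural-circumferential plane, in (-90, 90] degrees.
#' Positive when the projection and the transmural axis point into the same
#' half-space.  A purely longitudinal fiber returns NaN.
#'
#' @inheritParams helix_angle
#' @return numeric vector of angles (degrees); NaN where undefined.
#' @export
transverse_angle <- function(f, frame, proj_tol = 1e-12) {
  f <- as_rows(f)
  fr <- as_frame_rows(frame, nrow(f))
  fc <- rowSums(f * fr$e_c)
  ft <- rowSums(f * fr$e_t)
  flip <- fc < 0
  fc[flip] <- -fc[flip]
  ft[flip] <- -ft[flip]
  pn <- sqrt(fc^2 + ft^2)
  ang <- rad2deg(atan2(ft, fc))
  ang[pn < proj_tol] <- NaN
  ang[!is.nan(ang) & ang <= -90] <- 90
  ang
}

## cross-myocyte direction: e_t x proj(f, c-l plane), normalized.
## Returns NA rows where the fiber is (numerically) parallel to e_t.
cross_myocyte_direction <- function(f, fr, tol = 1e-12) {
  proj <- (rowSums(f * fr$e_c)) * fr$e_c + (rowSums(f * fr$e_l)) * fr$e_l
  x <- cbind(fr$e_t[, 2L] * proj[, 3L] - fr$e_t[, 3L] * proj[, 2L],
             fr$e_t[, 3L] * proj[, 1L] - fr$e_t[, 1L] * proj[, 3L],
             fr$e_t[, 1L] * proj[, 2L] - fr$e_t[, 2L] * proj[, 1L])
  nx <- sqrt(rowSums(x^2))
  bad <- nx < tol
  x[bad, ] <- NA_real_
  x[!bad, ] <- x[!bad, , drop = FALSE] / nx[!bad]
  list(x = x, bad = bad)
}

#' Sheet direction realizing a target E2A angle
#'
#' Constructs per-point sheet (s) and sheet-normal (n) directions such that
#' the recomputed sheetlet elevation angle [e2a_angle()] equals
#' `e2a_target` exactly.  The sheet is built in the plane orthogonal to the
#' fiber spanned by the cross-myocyte direction x (the cross product of the
#' transmural axis and the fiber's projection onto the
#' circumferential-longitudinal plane) and the unit component u of e_t
#' orthogonal to the fiber, rotating from x towards +e_t:
#' `s = cos(phi) x + sin(phi) u` with `tan(phi) = tan(E2A)/|u'|` correcting
#' for the obliquity between u and e_t, so that the construction hits the
#' target for any fiber not parallel to e_t.
#'
#' @param f unit fiber vector(s), length-3 or (n x 3).
#' @param frame local frame(s).
#' @param e2a_target target E2A in degrees, in [0, 90].
#' @return list with unit matrices `s` (sheet) and `n` (`= f x s`).
#' @export
sheet_from_e2a <- function(f, frame, e2a_target = 13) {
  f <- as_rows(f)
  n_pts <- nrow(f)
  fr <- as_frame_rows(frame, n_pts)
  if (e2a_target < 0 || e2a_target > 90) {
    stop("'e2a_target' must be in [0, 90] degrees")
  }
  cm <- cross_myocyte_direction(f, fr)
  if (any(cm$bad)) {
    stop("fiber parallel to the transmural axis at row(s): ",
         paste(utils::head(which(cm$bad), 5L), collapse = ", "))
  }
  x <- cm$x
  ## unit in-plane elevation direction: component of e_t orthogonal to f
  u <- fr$e_t - rowSums(fr$e_t * f) * f
  g <- sqrt(rowSums(u^2))          # = |sin(angle(f, e_t))| in (0, 1]
  u <- u / g
  ## obliquity correction: s.e_t = sin(phi) * g, s.x = cos(phi)
  phi <- atan2(tan(deg2rad(min(e2a_target, 90 - 1e-12))), g)
  if (e2a_target >= 90) phi <- rep(pi / 2, n_pts)
  s <- cos(phi) * x + sin(phi) * u
  s <- rows_normalize(s)
  nrm <- cbind(f[, 2L] * s[, 3L] - f[, 3L] * s[, 2L],
               f[, 3L] * s[, 1L] - f[, 1L] * s[, 3L],
               f[, 1L] * s[, 2L] - f[, 2L] * s[, 1L])
  list(s = s, n = rows_normalize(nrm))
}

#' Sheetlet elevation (E2A) angle
#'
#' Angle between the projection of the sheet direction onto the cross-myocyte
#' plane (spanned by the cross-myocyte direction and the transmural axis) and
#' the cross-myocyte direction, reported as an unsigned magnitude in
#' [0, 90] degrees.
#'
#' @param s unit sheet vector(s), length-3 or (n x 3).
#' @param f unit fiber vector(s) defining the cross-myocyte direction.
#' @param frame local frame(s).
#' @param proj_tol projection norm below which the angle is flagged NaN.
#' @return numeric vector of angles (degrees) in [0, 90]; NaN where the sheet
#'   is perpendicular to the cross-myocyte plane.
#' @export
e2a_angle <- function(s, f, frame, proj_tol = 1e-12) {
  s <- as_rows(s)
  f <- as_rows(f)
  fr <- as_frame_rows(frame, nrow(f))
  cm <- cross_myocyte_direction(f, fr)
  x <- cm$x
  sx <- rowSums(s * x)
  st <- rowSums(s * fr$e_t)
  pn <- sqrt(sx^2 + st^2)
  ang <- rad2deg(atan2(abs(st), abs(sx)))
  ang[pn < proj_tol | cm$bad] <- NaN
  ang
}

#' Sign-invariant angle between two axes
#'
#' `arccos(|u.v| / (|u||v|))` in [0, 90] degrees: fibers are axes, so u and
#' -u are the same direction.  The absolute angular difference used for all
#' interpolation-error measures.
#'
#' @param u,v vectors (length-3) or (n x 3) matrices of directions.
#' @return numeric vector of angles in [0, 90] degrees.
#' @export
line_angle_diff <- function(u, v) {
  u <- as_rows(u)
  v <- as_rows(v)
  if (nrow(u) == 1L && nrow(v) > 1L) u <- u[rep(1L, nrow(v)), , drop = FALSE]
  if (nrow(v) == 1L && nrow(u) > 1L) v <- v[rep(1L, nrow(u)), , drop = FALSE]
  nu <- sqrt(rowSums(u^2))
  nv <- sqrt(rowSums(v^2))
  if (any(nu == 0) || any(nv == 0)) stop("zero-length direction vector")
  cosv <- pmin(1, abs(rowSums(u * v)) / (nu * nv))
  rad2deg(acos(cosv))
}

#' Fiber/sheet/normal triad field
#'
#' Validating constructor for a per-point orthonormal microstructure triad.
#'
#' @param f,s unit fiber and sheet matrices (n x 3) with `|f.s| < 1e-8`.
#' @return object of class `fiber_field` with `f`, `s`, and `n = f x s`.
#' @export
fiber_field <- function(f, s) {
  f <- rows_normalize(rbind(f))
  s <- rows_normalize(rbind(s))
  if (nrow(f) != nrow(s)) stop("'f' and 's' must have matching rows")
  if (max(abs(rowSums(f * s))) > 1e-8) {
    stop("fiber and sheet directions are not orthogonal")
  }
  n <- cbind(f[, 2L] * s[, 3L] - f[, 3L] * s[, 2L],
             f[, 3L] * s[, 1L] - f[, 1L] * s[, 3L],
             f[, 1L] * s[, 2L] - f[, 2L] * s[, 1L])
  structure(list(f = f, s = s, n = n), class = "fiber_field")
}
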