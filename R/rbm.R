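## RBM: rule-based fiber reconstruction.  Helix and transverse angles are
## linear functions of the transmural coordinate,
##   alpha(t) = alpha_endo (1 - t) + alpha_epi t,
##   beta(t)  = beta_endo (1 - t) + beta_epi t,
## with the four endpoint parameters fitted to the data by ordinary least
## squares -- the stiffest (4 degrees of freedom) of the four methods.

#' Rule-based model parameters
#'
#' @param alpha_endo,alpha_epi endo/epicardial helix angles (degrees).
#' @param beta_endo,beta_epi endo/epicardial transverse angles (degrees).
#' @return object of class `rbm_params`.
#' @export
rbm_params <- function(alpha_endo, alpha_epi, beta_endo = 0, beta_epi = 0) {
  p <- c(alpha_endo = as.numeric(alpha_endo), alpha_epi = as.numeric(alpha_epi),
         beta_endo = as.numeric(beta_endo), beta_epi = as.numeric(beta_epi))
  if (any(!is.finite(p))) stop("RBM parameters must be finite")
  if (any(abs(p) > 90)) {
    stop("RBM angle parameters must lie in [-90, 90] degrees")
  }
  structure(as.list(p), class = "rbm_params")
}

#' @export
print.rbm_params <- function(x, ...) {
  cat(sprintf("rbm_params: alpha %0.2f -> %0.2f deg, beta %0.2f -> %0.2f deg\n",
              x$alpha_endo, x$alpha_epi, x$beta_endo, x$beta_epi))
  invisible(x)
}

#' Least-squares fit of the rule-based model
#'
#' Independent ordinary least squares of the two linear transmural angle
#' functions in the (1 - t, t) basis; exactly four parameters are estimated.
#' Samples with undefined angles (NaN) are dropped.
#'
#' @param t transmural coordinates of the samples.
#' @param helix_deg,transverse_deg measured angles (degrees).
#' @return an [rbm_params()] object with attribute `n_used`.
#' @export
rbm_fit <- function(t, helix_deg, transverse_deg = NULL) {
  if (is.null(transverse_deg)) transverse_deg <- rep(0, length(t))
  keep <- is.finite(t) & is.finite(helix_deg) & is.finite(transverse_deg)
  t <- t[keep]
  if (length(unique(signif(t, 12))) < 2L) {
    stop("rank-deficient fit: need samples at >= 2 distinct transmural depths")
  }
  X <- cbind(1 - t, t)
  ca <- qr.coef(qr(X), helix_deg[keep])
  cb <- qr.coef(qr(X), transverse_deg[keep])
  clamp <- function(v) pmin(pmax(v, -90), 90)
  p <- rbm_params(clamp(ca[1L]), clamp(ca[2L]), clamp(cb[1L]), clamp(cb[2L]))
  attr(p, "n_used") <- sum(keep)
  p
}

#' Evaluate the rule-based model
#'
#' Builds unit fibers at the requested coordinates by rotating the local
#' circumferential axis by alpha(t) about the transmural axis and then by
#' beta(t) about the longitudinal axis.
#'
#' @param params an [rbm_params()].
#' @param coords `ventricular_coords` or any list with element `t` (values
#'   outside [0, 1] are clamped with a warning).
#' @param frames `local_frames` over the same points.
#' @return unit fiber matrix (n x 3).
#' @export
rbm_evaluate <- function(params, coords, frames) {
  tt <- coords$t
  if (any(tt < -1e-9 | tt > 1 + 1e-9, na.rm = TRUE)) {
    warning("transmural coordinates outside [0, 1] clamped")
  }
  tt <- pmin(pmax(tt, 0), 1)
  alpha <- params$alpha_endo * (1 - tt) + params$alpha_epi * tt
  beta <- params$beta_endo * (1 - tt) + params$beta_epi * tt
  fibers_from_angles(alpha, beta, frames)
}
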