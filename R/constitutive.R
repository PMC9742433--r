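## Material-point constitutive laws of the LV model: orthotropic
## Holzapfel-Ogden passive strain energy with linear scaling A, a volumetric
## penalty enforcing near-incompressibility, and a Guccione-type
## time-varying elastance active tension with length-dependent calcium
## sensitivity.  Stress units follow the parameters: passive moduli in kPa,
## maximal active tension in MPa.

#' Holzapfel-Ogden passive material parameters
#'
#' Defaults are the porcine-calibrated initial values used with this model
#' family: a_iso = 0.0943 kPa, b_iso = 5.874, a_f = 0.311 kPa,
#' a_s = 0.0431 kPa, b_f = 11.271, b_s = 9.772, a_fs = 0.0254 kPa,
#' b_fs = 2.405, with linear personalization scale A and compressibility
#' parameter D = 0.1 (the inverse multiple of the bulk modulus, D = 2/K).
#'
#' @param a_iso,a_f,a_s,a_fs stress-like moduli (kPa), non-negative.
#' @param b_iso,b_f,b_s,b_fs dimensionless exponents, positive.
#' @param A dimensionless linear scaling factor, positive.
#' @param D inverse-stress compressibility parameter (1/kPa scale), positive.
#' @return object of class `ho_params`.
#' @export
ho_params <- function(a_iso = 0.0943, b_iso = 5.874,
                      a_f = 0.311, b_f = 11.271,
                      a_s = 0.0431, b_s = 9.772,
                      a_fs = 0.0254, b_fs = 2.405,
                      A = 1, D = 0.1) {
  p <- list(a_iso = a_iso, b_iso = b_iso, a_f = a_f, b_f = b_f,
            a_s = a_s, b_s = b_s, a_fs = a_fs, b_fs = b_fs, A = A, D = D)
  if (any(unlist(p[c("a_iso", "a_f", "a_s", "a_fs")]) < 0)) {
    stop("stress-like moduli a_* must be non-negative")
  }
  if (any(unlist(p[c("b_iso", "b_f", "b_s", "b_fs")]) <= 0)) {
    stop("exponents b_* must be positive")
  }
  if (p$A <= 0 || p$D <= 0) stop("A and D must be positive")
  structure(p, class = "ho_params")
}

#' Active tension model parameters
#'
#' Defaults as used with this model family: Ca0 = Ca0_max = 4.35 umol/L,
#' B = 4750 1/mm, l0 = 0.75 um, l_r = 1.835 um, and relaxation-line
#' coefficients m = 300, b = -0.38 (t_r = m l + b with l in um and t_r in
#' ms).  T_max, t0 and the sheet fraction n are personalization targets; the
#' defaults here are representative mid-range values.
#'
#' @param T_max maximal developed tension (MPa).
#' @param Ca0,Ca0_max peak and maximal peak intracellular calcium (umol/L).
#' @param B sarcomere-length sensitivity (1/mm; lengths converted from um).
#' @param l0 threshold sarcomere length (um) below which no force develops.
#' @param l_r initial (reference) sarcomere length (um).
#' @param t0 time to peak tension (ms).
#' @param m,b relaxation-line coefficients (ms/um and ms).
#' @param n sheet-direction active stress fraction in [0, 1].
#' @param ramp_delta smoothing width (um) of the low-length force cutoff.
#' @return object of class `active_params`.
#' @export
active_params <- function(T_max = 0.1, Ca0 = 4.35, Ca0_max = 4.35,
                          B = 4750, l0 = 0.75, l_r = 1.835,
                          t0 = 150, m = 300, b = -0.38, n = 0.7,
                          ramp_delta = 0.01) {
  if (n < 0 || n > 1) stop("'n' must lie in [0, 1]")
  if (T_max < 0 || Ca0 <= 0 || Ca0_max <= 0 || B <= 0 || l0 <= 0 || l_r <= 0) {
    stop("active model parameters must be positive")
  }
  structure(list(T_max = T_max, Ca0 = Ca0, Ca0_max = Ca0_max, B = B,
                 l0 = l0, l_r = l_r, t0 = t0, m = m, b = b, n = n,
                 ramp_delta = ramp_delta),
            class = "active_params")
}

## isochoric invariants of C at unit vectors f, s
iso_invariants <- function(C, f, s) {
  J2 <- det(C)
  if (J2 <= 0) stop("right Cauchy-Green tensor must be positive definite")
  J <- sqrt(J2)
  Cb <- J^(-2 / 3) * C
  list(J = J, Cbar = Cb,
       I1 = sum(diag(Cb)),
       I4f = as.numeric(t(f) %*% Cb %*% f),
       I4s = as.numeric(t(s) %*% Cb %*% s),
       I8fs = as.numeric(t(f) %*% Cb %*% s))
}

#' Isochoric Holzapfel-Ogden strain energy density
#'
#' `psi_ic = A a_iso/(2 b_iso) exp(b_iso (I1bar - 3))
#'   + sum_{i=f,s} A a_i/(2 b_i) [exp(b_i (I4ibar - 1)^2) - 1]
#'   + A a_fs/(2 b_fs) [exp(b_fs I8bar^2) - 1]`,
#' in terms of the invariants of the isochoric right Cauchy-Green tensor.
#' The fiber and sheet exponential terms engage only under tension
#' (I4 > 1), the standard convention for this model (collagen fibers do not
#' support compression).
#'
#' @param C right Cauchy-Green tensor (SPD 3x3).
#' @param f,s unit fiber and sheet vectors.
#' @param params an [ho_params()].
#' @return energy density (kPa).
#' @export
ho_isochoric_energy <- function(C, f, s, params = ho_params()) {
  if (max(abs(C - t(C))) > 1e-8 * max(1, max(abs(C)))) {
    stop("C must be symmetric")
  }
  ev <- eigen((C + t(C)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("C must be positive definite")
  iv <- iso_invariants(C, f, s)
  p <- params
  e <- p$A * p$a_iso / (2 * p$b_iso) * exp(p$b_iso * (iv$I1 - 3))
  if (iv$I4f > 1) {
    e <- e + p$A * p$a_f / (2 * p$b_f) * (exp(p$b_f * (iv$I4f - 1)^2) - 1)
  }
  if (iv$I4s > 1) {
    e <- e + p$A * p$a_s / (2 * p$b_s) * (exp(p$b_s * (iv$I4s - 1)^2) - 1)
  }
  e + p$A * p$a_fs / (2 * p$b_fs) * (exp(p$b_fs * iv$I8fs^2) - 1)
}

#' Volumetric penalty energy
#'
#' `psi_vol = (1/D) ((J^2 - 1)/2 - log J)`: zero at J = 1, convex near 1,
#' penalizing volume change with compressibility parameter D (small D means
#' nearly incompressible).
#'
#' @param J Jacobian of the deformation gradient (> 0).
#' @param D compressibility parameter (> 0).
#' @return energy density (kPa for D in 1/kPa).
#' @export
volumetric_energy <- function(J, D = 0.1) {
  if (any(J <= 0)) stop("J must be positive")
  if (D <= 0) stop("D must be positive")
  (1 / D) * ((J^2 - 1) / 2 - log(J))
}

#' Passive Cauchy stress of the Holzapfel-Ogden model
#'
#' Analytic push-forward `sigma = (2/J) F (dPsi/dC) F'` of the total
#' (isochoric + volumetric) energy.
#'
#' @param F deformation gradient (3x3, det F > 0).
#' @param f,s unit fiber and sheet vectors (reference configuration).
#' @param params an [ho_params()].
#' @return symmetric 3x3 Cauchy stress (kPa).
#' @export
passive_cauchy_stress <- function(F, f, s, params = ho_params()) {
  F <- as.matrix(F)
  J <- det(F)
  if (J <= 0) stop("det F must be positive")
  C <- t(F) %*% F
  Cinv <- solve(C)
  iv <- iso_invariants(C, f, s)
  p <- params
  Jm23 <- iv$J^(-2 / 3)
  I <- diag(3)
  ## dPsi/dIbar scalar coefficients
  psi1 <- p$A * p$a_iso / 2 * exp(p$b_iso * (iv$I1 - 3))
  psi4f <- if (iv$I4f > 1) {
    p$A * p$a_f * (iv$I4f - 1) * exp(p$b_f * (iv$I4f - 1)^2)
  } else 0
  psi4s <- if (iv$I4s > 1) {
    p$A * p$a_s * (iv$I4s - 1) * exp(p$b_s * (iv$I4s - 1)^2)
  } else 0
  psi8 <- p$A * p$a_fs * iv$I8fs * exp(p$b_fs * iv$I8fs^2)
  ## dIbar/dC (isochoric projections); iv$I* are already the isochoric ones
  dI1 <- Jm23 * I - (iv$I1 / 3) * Cinv
  ff <- tcrossprod(f)
  ss <- tcrossprod(s)
  fs <- (tcrossprod(f, s) + tcrossprod(s, f)) / 2
  dI4f <- Jm23 * ff - (iv$I4f / 3) * Cinv
  dI4s <- Jm23 * ss - (iv$I4s / 3) * Cinv
  dI8 <- Jm23 * fs - (iv$I8fs / 3) * Cinv
  dPsi_dC <- psi1 * dI1 + psi4f * dI4f + psi4s * dI4s + psi8 * dI8
  ## volumetric: dpsi/dJ * dJ/dC = (1/D)(J - 1/J) * (J/2) C^-1
  dPsi_dC <- dPsi_dC + (1 / p$D) * (iv$J - 1 / iv$J) * (iv$J / 2) * Cinv
  sig <- (2 / iv$J) * F %*% dPsi_dC %*% t(F)
  (sig + t(sig)) / 2
}

#' Total passive energy density
#'
#' Convenience sum of [ho_isochoric_energy()] and [volumetric_energy()]
#' evaluated from a deformation gradient; the finite-difference oracle for
#' [passive_cauchy_stress()].
#'
#' @inheritParams passive_cauchy_stress
#' @return energy density (kPa).
#' @export
passive_energy <- function(F, f, s, params = ho_params()) {
  F <- as.matrix(F)
  J <- det(F)
  if (J <= 0) stop("det F must be positive")
  C <- t(F) %*% F
  ho_isochoric_energy(C, f, s, params) + volumetric_energy(J, params$D)
}

#' Time-varying elastance active tension
#'
#' Guccione-type active fiber tension as a function of the time after
#' activation and the fiber Green-Lagrange strain E_ff:
#' `T = T_max Ca0^2 / (Ca0^2 + ECa50(l)^2) * (1 - cos omega(t, E_ff)) / 2`,
#' with sarcomere length `l = l_r sqrt(2 E_ff + 1)` (um), length-dependent
#' calcium sensitivity `ECa50 = Ca0_max / sqrt(exp(B (l - l0)) - 1)` (B in
#' 1/mm, lengths converted um -> mm), relaxation time `t_r = m l + b` (l in
#' um, t_r in ms), and the three-phase switching function omega: cosine rise
#' over [0, t0), cosine relaxation over [t0, t0 + t_r), zero afterwards.
#' Below the threshold length l0 no force develops; the cutoff is smoothed
#' over `[l0, l0 + ramp_delta]`.
#'
#' @param t time after activation (ms), non-negative.
#' @param E_ff fiber Green-Lagrange strain; `2 E_ff + 1 > 0` required.
#' @param params an [active_params()].
#' @return active tension, same unit as `T_max` (MPa); vectorized over `t`
#'   and `E_ff`.
#' @export
active_tension <- function(t, E_ff = 0, params = active_params()) {
  p <- params
  nmax <- max(length(t), length(E_ff))
  t <- rep_len(t, nmax)
  E_ff <- rep_len(E_ff, nmax)
  if (any(t < 0)) stop("time after activation must be non-negative")
  if (any(2 * E_ff + 1 < 0)) stop("unphysical fiber compression: 2 E_ff + 1 < 0")
  l <- p$l_r * sqrt(2 * E_ff + 1)            # um
  t_r <- p$m * l + p$b                       # ms (l in um)
  ## length-dependent calcium sensitivity; B in 1/mm, lengths um -> mm
  arg <- p$B * (l - p$l0) * 1e-3
  eca50 <- ifelse(arg > 0, p$Ca0_max / sqrt(expm1(arg)), Inf)
  ca_frac <- p$Ca0^2 / (p$Ca0^2 + eca50^2)
  ## low-length switch: no force at l <= l0, smooth ramp over ramp_delta
  ramp <- pmin(pmax((l - p$l0) / p$ramp_delta, 0), 1)
  omega <- ifelse(t < p$t0, pi * t / p$t0,
                  ifelse(t < p$t0 + t_r, pi * (t - p$t0 + t_r) / t_r, 0))
  ct <- (1 - cos(omega)) / 2
  ct[t >= p$t0 + t_r] <- 0
  p$T_max * ca_frac * ct * ramp
}

#' Fiber and sheet stress composition
#'
#' Adds the active contributions to the passive stress: the active stress
#' acts only along the fiber (`T f x f`) and, scaled by the fraction n, along
#' the sheet (`n T s x s`); all other directions carry passive stress only.
#'
#' @param sigma_passive symmetric passive Cauchy stress (3x3).
#' @param T_active active tension scalar (same stress unit as
#'   `sigma_passive`).
#' @param f,s unit fiber and sheet vectors (current configuration).
#' @param n sheet-direction active fraction in [0, 1].
#' @return list with `sigma` (total), `sigma_active` (active part).
#' @export
fiber_sheet_stress <- function(sigma_passive, T_active, f, s, n = 0.7) {
  if (n < 0 || n > 1) stop("'n' must lie in [0, 1]")
  act <- T_active * tcrossprod(f) + n * T_active * tcrossprod(s)
  list(sigma = sigma_passive + act, sigma_active = act)
}
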