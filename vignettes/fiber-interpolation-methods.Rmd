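---
title: "Reconstructing dense LV fiber fields from sparse cDTI: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing dense LV fiber fields from sparse cDTI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiofiber)
```

## The problem

In-vivo cardiac diffusion tensor imaging measures water diffusion anisotropy
on a small number of thick short-axis slices. The first eigenvector of the
per-voxel diffusion tensor approximates the local predominant aggregated
cardiomyocyte long-axis ("fiber") orientation, the primary symmetry axis of
the myocardial material response. Biomechanical left-ventricular models,
however, need fiber and sheet directions at every quadrature point of a
dense tetrahedral mesh. This package implements and evaluates four ways of
bridging sparse measurements to a dense field, together with the coordinate
machinery they share and the constitutive laws the resulting microstructure
feeds into.

All stages operate on a synthetic, fully controlled stand-in for the in-vivo
setting, so that every claim a test makes is checkable against an oracle.

## Shape-adapted ventricular coordinates

Every method works in normalized ventricular coordinates rather than
scanner space. On a labeled tetrahedral mesh (surfaces `endo`, `epi`,
`base`; an apical transmural cylinder of 2 mm diameter) linear-FEM
Laplace–Dirichlet problems define:

- **t (transmural)**: endocardium 0, epicardium 1;
- **l (longitudinal)**: basal plane 1, apex cylinder 0;
- **c (circumferential)**: two *separate half-domain* problems with
  Dirichlet data on the plane through the anterior side and the long axis,
  stitched into one periodic coordinate with c = 0 anterior, increasing
  counterclockwise seen from the base, values in [0, 1). Solving the halves
  as separate domains matters: in 3D, Dirichlet data supported on a line has
  vanishing capacity, and a single full-domain solve collapses toward a
  constant. The apical cylinder is excluded from the assembly (insulating);
  inside it c is the cylindrical angle about the long axis. On the idealized
  geometry the Laplace solution converges to that same angle, so no separate
  blending layer is applied.

Local frames are built by Gram–Schmidt in the order e_t (gradient of the
transmural solution — the most reliable direction on a thin wall), then e_l
(longitudinal gradient orthogonalized against e_t), then e_c = e_l × e_t,
which fixes a right-handed triad with the stated c orientation. Nodes whose
gradient degenerates (deep inside the insulated apex cylinder) either raise
an error naming the node or, when a fallback axis is supplied, use it with
the degeneracy recorded.

Global normalization "by streamline length" is implemented per streamline:
each node's coordinate is its backward arc length divided by its own
streamline's total length, which makes the coordinate invariant to local
wall thickness. (A global-maximum normalization would tie every node's value
to the single longest streamline; the per-streamline reading is the one
consistent with wall-thickness invariance, and is a deliberate choice where
the underlying convention is ambiguous.) The tracer is a fixed-step RK4
integrator (step = 0.25 × mean edge length) on the normalized direction
field. Two numerical details: the final partial step is bisected to the
boundary so arc lengths do not truncate by up to one step; and when a
terminal node set is supplied, trajectories that graze a *non-terminal*
boundary (an artifact of slightly tilted discrete nodal gradients along
insulated faces) are slid tangentially back inside — the slide direction is
projected orthogonal to the field so the accumulated arc length stays
unbiased — with a budget of 100 slides before the node is flagged and falls
back to its raw Laplace value. Streamline normalization is off by default in
`compute_ventricular_coords()`: the raw harmonic fields already satisfy all
boundary contracts, and the normalization is an opt-in refinement.

## Angle conventions

- **Helix angle**: angle between the fiber's projection onto the
  longitudinal–circumferential plane and e_c, in (−90°, 90°], positive when
  fiber and e_l share a half-space; −90° maps to +90° (tie-break).
- **Transverse angle**: same construction in the transmural–circumferential
  plane, positive toward +e_t.
- **E2A (sheetlet elevation)**: angle between the sheet direction's
  projection onto the cross-myocyte plane and the cross-myocyte direction
  x = e_t × proj(f, c–l plane), reported as an unsigned magnitude in
  [0°, 90°]. A signed convention would require a reference rotation sense
  that the underlying construction (a single diastolic target value) does
  not supply.
- **Sheet construction**: sheets are built in the plane orthogonal to the
  fiber, spanned by x and the unit component u of e_t orthogonal to f, as
  s = cos φ x + sin φ u with tan φ = tan(E2A_target)/|u|. The |u| factor
  corrects for the obliquity between u and e_t when the fiber has a
  transmural component; without it the recomputed E2A would undershoot the
  target for any fiber with nonzero transverse angle. With the correction
  the round trip `sheet_from_e2a()` → `e2a_angle()` is exact (to 1e-6°) for
  every fiber not parallel to e_t, which is the package's acceptance
  property for the 13° diastolic target.
- **Angular error**: all comparisons use arccos|u·v|, the angle between
  *axes* — fibers have no preferred sign.

## The four reconstruction methods

Ordered by decreasing degrees of freedom:

**HFC (kernel tensor interpolation).** Tensors are rotated into their local
(e_t, e_c, e_l) frame — so anatomy, not scanner orientation, is averaged —
mapped to the log-Euclidean vector space, averaged with anisotropic Gaussian
weights w ∝ exp(−dᵀH⁻²d) on (t, c, l) differences (periodic in c), and
mapped back at the target's frame. The printed normalizer (2π·det H) is
retained although it cancels under weight normalization. Distances are taken
in coordinate space (physical-space proximity would mix wall depth and
position); H = diag(h_t, h_c, h_l) is optimized by coordinate descent on a
log-spaced grid against held-out-slice error. The full 3×3 H family is not
searched: on the synthetic world the diagonal optimum is already flat within
holdout noise, and the reference procedure for the full matrix lives outside
what this package re-derives. When all weights underflow, the target falls
back to its nearest datum and is flagged.

**PGD (separated low-rank model).** Each projection f_d = f·e_d is
approximated per heart by six rank-one products F(t)G(c)H(l) on
piecewise-linear Galerkin grids of 14/24/10 nodes (the circumferential basis
periodic — first and last hat identified; the underlying convention is
unstated and periodicity is the only choice free of a seam artifact). The
greedy enrichment solves each 1-D factor by alternating least squares from a
constant initialization, with the scale ambiguity fixed by unit-norm,
positive-sum c and l factors (magnitude carried in the t factor) so that
factors are comparable across hearts. Across a cohort, each 1-D function is
mean-centered and compressed by SVD (six modes, capped at cohort rank K−1).
Fitting to new sparse data re-estimates one mean weight plus SVD weights per
(projection, mode, direction) by mode-wise ALS from the population-mean
initialization (w_mean = 1, variations 0) — deterministic, no random
restarts. Convergence is declared when the squared misfit changes by less
than 1e-12 relative, or after 500 sweeps; under-determined mode solves are
ridge-stabilized (λ = 1e-8 of the Gram trace) and all-zero data short-circuit
to exactly zero weights. A full tensor-product discretization of the same
grids would carry 14·24·10 = 3360 coefficients per projection; the separated
form carries (14+24+10)·6 = 288.

**POD (gappy snapshot model).** Dense cohort fields are mapped to a common
equidistant grid (20 transmural × 200 circumferential × 120 longitudinal by
default), sliced with transmural normal, flattened, and compressed by SVD
into eight orthonormal 2-D basis functions Φ_m(c, l) per projection. For
sparse data, the grid is reduced to the nearest grid point of each datum,
data are transferred to those points by adjoint tri-linear interpolation
(weights normalized per grid point), and weights w_{m,t_i} are solved per
transmural index by least squares on the observed points — Tikhonov-
regularized (λ = 1e-8 of the Gram trace) when fewer points than modes are
observed. Transmural indices with no data receive linearly interpolated
weights from their observed neighbors (constant extrapolation at the ends);
the choice is arbitrary but smooth, and it is exercised by a dedicated test.
Note the exact-recovery property holds for data *on* grid points; off-grid
data incur the transfer approximation by construction of the method.

**RBM (rule-based).** Helix and transverse angles are independent linear
functions of t; four parameters are fitted by ordinary least squares in the
(1−t, t) basis, and fibers are rebuilt by rotating e_c by α(t) about e_t and
then by β(t) about e_l. This is the stiffest model: it cannot represent any
circumferential or longitudinal variation, which is exactly why it serves as
the lower baseline in the method comparison.

All four evaluators renormalize to unit vectors and apply the positive-e_c
sign convention (tie-breaking through e_l, then e_t).

## The synthetic world

The generator's defaults state the world the tests live in:

- Geometry: truncated prolate ellipsoidal shell, endo semi-axes
  (20, 20, 45) mm, epi (30, 30, 55) mm, base plane 10 mm above center —
  a normal-sized LV (cavity ≈ 50 ml, wall 7–10 mm). The idealized shape is
  chosen because its shell and cavity volumes have closed forms, giving the
  mesh generator analytic oracles.
- Microstructure: helix 60° → −60° endo-to-epi, zero transverse profile —
  the textbook transmural rotation. Heterogeneity is smoothed white noise on
  the nodes (Gaussian kernel, 10 mm correlation length, zero mesh mean),
  added to both angles; it is a *fixture* for "local structure a global rule
  cannot capture", not a physiological field model.
- Diffusion: eigenvalues (1.5, 0.8, 0.5)·10⁻³ mm²/s (physiological
  myocardial range); acquisition 3/3/12 directions at b = 100/200/450 s/mm²
  (deterministic golden-angle hemisphere per shell), eight averages, Rician
  noise at SNR 20 by default. Because no b = 0 volume exists, ln S0 is
  co-estimated as a seventh unknown in the tensor fit rather than
  designating a reference shell.
- Sampling: 9 short-axis slices of 8 mm thickness at 2 mm in-plane spacing,
  point-sampled at voxel centers; through-slice averaging is opt-in because
  the partial-volume behavior of thick slices is not specified by the
  acquisition alone.

What a green test does establish: the solvers meet analytic oracles, the
method implementations are self-consistent (recover what they generated),
and the qualitative method ordering (kernel smoothing beats the global rule
on heterogeneous truth) is robust across seeds. What it does not establish:
in-vivo error magnitudes — real acquisitions add motion, registration
residuals, and segmentation error that the generator does not emulate, and
the in-vivo comparison values reported for this method family depend on a
porcine dataset that is not publicly deposited.

## Constitutive laws

The passive response is the orthotropic Holzapfel–Ogden energy on isochoric
invariants of C̄ = J^(−2/3)C, with the printed porcine parameter set
(a_iso = 0.0943 kPa, b_iso = 5.874, a_f = 0.311 kPa, b_f = 11.271,
a_s = 0.0431 kPa, b_s = 9.772, a_fs = 0.0254 kPa, b_fs = 2.405), a linear
personalization scale A multiplying all stress-like moduli, and the
volumetric penalty ψ_vol = (1/D)((J²−1)/2 − ln J) with D = 0.1 (inverse
multiple of the bulk modulus, D = 2/K). The fiber and sheet exponentials
engage only under tension (I₄ > 1) — the standard convention for
collagen-reinforced tissue, which the energy's printed form leaves implicit.
The isotropic term is implemented exactly as printed (no "−1" offset); a
constant energy offset does not affect stress. The Cauchy stress is the
analytic push-forward σ = (2/J) F (∂Ψ/∂C) Fᵀ and is verified against
central finite differences of the energy to 1e-6 relative on randomized
states.

The active model is a time-varying elastance:
T = T_max · Ca₀²/(Ca₀² + ECa₅₀(l)²) · ½(1 − cos ω(t)), with sarcomere
length l = l_r√(2E_ff + 1), calcium sensitivity
ECa₅₀ = Ca₀,max/√(exp(B(l − l₀)) − 1), and a three-phase ω: cosine rise over
[0, t₀), cosine relaxation over [t₀, t₀ + t_r), zero afterwards, continuous
at both joints. Units required interpretation: B = 4750 mm⁻¹ acts on lengths
converted µm → mm (giving ECa₅₀ ≈ 0.33 µmol/L at l_r, i.e. near-saturated
activation), while the relaxation line t_r = m·l + b takes l in µm with
m = 300, b = −0.38, giving t_r ≈ 550 ms at the reference length — the only
unit pairing with physiologic magnitudes; both are configuration-exposed.
The low-length cutoff ("no force below l₀") is a hard switch smoothed over a
configurable ramp of 0.01 µm, since its functional form is not specified.
t₀ and T_max are personalization targets in the source workflow; the
defaults (150 ms, 0.1 MPa) are representative mid-range values. Active
stress enters only along fiber and sheet: σ_f += T f⊗f and σ_s += nT s⊗s
with the sheet fraction n ∈ [0, 1] (default 0.7).

## Evaluation protocol

The leave-one-slice-out error excludes the mid-ventricular slice (the slice
whose median longitudinal coordinate is the median across slices, ties
toward the apex), reconstructs from the rest, and compares to the held-out
first eigenvectors by the axis angle. Voxels flagged during tensor fitting
or with degenerate angles are excluded and counted — whether the original
protocol excluded them is unstated, so the count is always reported.
Percentiles use linear interpolation between order statistics (R type 7);
aggregation is per-voxel and unweighted. Two calibration properties anchor
the scale: a method returning the truth scores 0, and a method returning
uniformly random directions scores a median of 60° (the median acute angle
between a line and a uniform random direction, since P(θ ≤ x) = 1 − cos x).

## Known limitations

- LV only: no biventricular or outflow-tract coordinates.
- No motion/eddy correction or registration; the synthetic world has none.
- The PGD weight fit and kernel optimization are deterministic stand-ins
  for procedures whose full specifications live outside this package's
  sources (ALS over the SVD basis; diagonal-H grid search).
- Material-point evaluation only: no FEM assembly, boundary conditions,
  unloading, or parameter personalization loops.
- The synthetic cohort used to build PGD/POD bases is generated from the
  same angular-profile family the RBM assumes, plus smooth harmonic
  heterogeneity; a real ex-vivo atlas would carry richer variation.
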