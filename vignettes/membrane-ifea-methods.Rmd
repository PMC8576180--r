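---
title: "Inverse finite element analysis of a lung surface membrane: models, algorithms, and verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inverse finite element analysis of a lung surface membrane}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulmem)
```

## The problem

Full-field optical measurements (digital image correlation, DIC) of an
inflating lung deliver the displacement of thousands of points on the visible
lobe surface, together with the global pressure–volume loading. `pulmem`
turns such data into *compound material parameters* of a reduced-order
membrane model of the lung surface: the visible lobe is discretized with
3-node membrane triangles (reference thickness 1 mm), inflated quasi-
statically by the recorded pressure acting as a follower load, with the
recorded perimeter displacements applied as boundary conditions so that the
surrounding (invisible) tissue is represented by its measured motion rather
than by artificial supports. Calibrated parameters are *compound* in the
sense that they lump parenchyma, embedded airways, and the visceral pleura
into one surface-projected response; they are not the properties of any one
tissue.

The inverse problem is solved by minimizing the displacement mismatch
between the model and the measurements at five evenly spaced inflation
stages,

$$\Pi(p) \;=\; \frac{1}{2 s}\sum_{n=1}^{5}\bigl\lVert W\,u^{\mathrm{sim}}_n(p)
  - u^{\mathrm{exp}}_n\bigr\rVert^2 \;+\;
  \frac{\alpha}{2}\bigl\lVert \tilde p - \tfrac12 \bigr\rVert^2 ,$$

where $W$ is the sparse k-nearest-neighbor operator that evaluates the
nodal solution at the probe points, the normalizer
$s = n_{\mathrm{probes}} \times n_{\mathrm{stages}} \times
\max\lVert u^{\mathrm{exp}}\rVert^2$ makes $\Pi$ dimensionless, and the
Tikhonov term (weight $\alpha = 10^{-6}$, used only for the heterogeneous
gradient-based path) acts on bound-normalized parameters
$\tilde p = (p - \ell)/(u - \ell)$. All quantities are in mm / kPa / mN
(1 kPa = 1 mN/mm²; 1 cmH₂O = 0.0980665 kPa).

## Constitutive models

Three membrane material laws are implemented, all evaluated per element in a
local frame whose z-axis is the outward normal, whose y-axis is the in-plane
projection of the anterior–posterior direction, and whose x-axis completes
the right-handed triad (the medial–lateral direction, along which fibers are
assumed).

**Homogeneous isotropic hyperelastic** — compressible Mooney–Rivlin,
$W = C_{10}(\bar I_1 - 3) + C_{01}(\bar I_2 - 3) + \frac{1}{D_1}(J-1)^2$,
three unknowns $(C_{10}, C_{01}, D_1)$. The membrane is in plane stress: the
through-thickness stretch $\lambda_3$ is condensed by a safeguarded scalar
Newton/bisection root find (interval tolerance $10^{-12}$) so that the
normal second Piola–Kirchhoff stress vanishes. Small-strain limits:
$\mu_0 = 2(C_{10}+C_{01})$, $K_0 = 2/D_1$. (The bulk modulus is $2/D_1$, not
$2 D_1$: only the reciprocal form is dimensionally consistent with
$D_1$ in kPa⁻¹ and reproduces the ~1.5 MPa scale implied by the calibrated
$D_1 \approx 1.34\times10^{-3}$ kPa⁻¹.)

**Homogeneous anisotropic hyperelastic** — Holzapfel–Gasser–Ogden with
dispersion,
$W = C_{10}(\bar I_1-3) + \frac{1}{D}\bigl(\frac{J^2-1}{2}-\ln J\bigr)
+ \frac{k_1}{2k_2}\bigl[e^{k_2 E_f^2}-1\bigr]$ with
$E_f = \kappa(\bar I_1 - 3) + (1-3\kappa)(\bar I_4 - 1)$,
$\kappa \in [0, 1/3]$. Design choices:

* the membrane formulation constrains $J = 1$, setting the thickness
  stretch from the in-plane deformation; the volumetric term then vanishes
  identically, so `D` is retained in the parameter vector but is *inert* —
  the objective is insensitive to it, and a calibration leaves it wherever
  it started;
* the fiber term is active only when $E_f > 0$ (tension), the standard
  convention for exponential fiber models;
* the $k_2 \to 0$ limit is evaluated through the series form of
  $(e^x - 1)/x$, not by substituting the quadratic law;
* at $\kappa = 1/3$ the fiber term becomes *isotropic* (independent of the
  fiber direction), the sense in which full dispersion "zeroes out" the
  anisotropy.

**Heterogeneous isotropic linear-elastic** — each element carries its own
$(E_e, \nu_e)$ in plane stress; the derived per-element shear modulus
$\mu_e = E_e / (2(1+\nu_e))$ gives the regional stiffness map. This case is
solved geometrically linear in a single step per stage, which is the
$K(p)\,u = f$ structure the adjoint method assumes.

## Forward solver

The hyperelastic forward problem is quasi-static: Newton iteration with
adaptive load incrementation (increment halving on divergence), a residual
tolerance of $10^{-8}$ relative to the increment load norm (absolute floor
$10^{-6}$ mN — the roundoff level of the assembled internal force), and a
backtracking line search. The element tangent is formed by central finite
differencing of the exact element residual, which automatically carries the
material, geometric, and follower-pressure contributions; the residual
itself is exact, so converged states do not depend on this choice. A small
diagonal stabilization ($10^{-6}\times$ the mean tangent diagonal) enters
the iteration matrix only, regularizing the null modes of wrinkling-prone
(compressed or zero-stress) membrane states; a membrane loaded through a
single large step can legitimately converge to a wrinkled metastable
equilibrium, and ramped incrementation is the intended way to track the
physical path. The follower pressure acts on the current configuration
(one third of each deformed triangle's area-normal vector per node).

For the linear heterogeneous operator the stabilization magnitude is
*material-independent* — the unit-modulus reference assembly scaled by a
fixed 500 kPa reference modulus (the midpoint of the default search range).
With a parameter-dependent scale the regularized operator would change with
$p$ and the adjoint gradient would be inexact at about the $10^{-5}$ level;
with the fixed scale, adjoint and central-difference gradients agree to
better than $10^{-6}$ relative. The price is that exact scaling invariance
$(E, f) \to (cE, cf)$ holds for the unregularized operator only.

## Gradients: adjoint versus finite differences

For the heterogeneous case with $N = 2m$ unknowns (914 on the 457-element
mesh), a central-difference gradient costs $2N$ forward solves — 1828 at
that size. The adjoint route costs two: one forward solve $K(p)u = f$ and
one adjoint solve $K(p)\lambda = W^\top (Wu - u^{\mathrm{exp}})/s$ (the
stiffness is symmetric), both with all five stages as simultaneous
right-hand sides of a single factorization. The per-parameter derivative is
assembled analytically element-wise ($\partial K/\partial E_e = K_e/E_e$;
$\partial K/\partial \nu_e$ from the plane-stress matrix derivative) and
contracted as $-\sum_n \lambda_n^\top (\partial K/\partial p_i) u_n$, with
$\lambda$ zero on constrained dofs so that prescribed-boundary terms drop
out correctly.

## Optimizers

*Homogeneous cases*: bounded nonlinear least squares. Levenberg–Marquardt
runs on smoothly bound-transformed parameters
($p = \ell + (u-\ell)\sin^2\theta$) because a plain box projection freezes
parameters that touch a bound mid-run. Because the transform flattens near a
bound, parameters whose optimum *is* a bound (the calibrated $C_{01}$ sits
on its 1 kPa lower bound; $\kappa$ on its 0.33 upper bound) creep slowly, so
each start finishes with an active-set polish — near-bound parameters are
snapped onto the bound and the rest refit — followed by bound probes: each
parameter is trialed at either bound with the interior parameters refit, and
strict improvements are kept. All three phases are generic over parameters
and bounds. Starts are drawn uniformly in the search box
($C_{10}, C_{01}, k_1 \in [1, 200]$ kPa; $D_1, D \in [10^{-4}, 10^{-2}]$
kPa⁻¹; $k_2 \in [0,1]$; $\kappa \in [0, 0.33]$), and the winner is the
lowest objective, ties broken by mean displacement error. Each optimization
trajectory owns its warm-start cache of forward solutions; sharing cached
equilibria across starts would make one start's path depend on another's.

*Heterogeneous case*: bound-constrained quasi-Newton minimization
(L-BFGS-B) in bound-normalized coordinates, driven by the adjoint gradient,
with $\alpha = 10^{-6}$. The Tikhonov reference is the *midpoint* of the
search box: because the normalized objective makes $\alpha$ large relative
to the curvature of intrinsically weak $(E,\nu)$ trade-off directions, a
lower-bound reference would drag weakly informed parameters to the bound,
whereas the midpoint is the unbiased prior within the box. Default bounds:
$E \in [50, 1000]$ kPa, $\nu \in [0.30, 0.49]$.

*Particle swarm*: the velocity update
$v \leftarrow w v + c_1 r_1 (p^{best}-x) + c_2 r_2 (g^{best}-x)$ with
$c_1 = c_2 = 2$, inertia starting at 1.0 and damped by 0.99 per iteration;
velocities are clamped to their bounds before the position update, and a
position that would leave the box has the offending velocity component
zeroed and the position set to the violated bound. Positions initialize
uniformly in the box, velocities uniformly in one tenth of the velocity
bounds. Convergence is declared when the global best improves by less than
$10^{-6}$ of its initial value over a 30-iteration window. Failed forward
solves are penalized ($10^6 \times$ the current global best, $10^{12}$
before one exists) and logged. Study-condition swarm sizes are 24 / 48 /
1000 for the three cases with velocity bounds $\pm 5$, $\pm 5$, $\pm 40$;
desk-scale tests use smaller swarms.

## The synthetic-data generator

No experimental data ship with the package, so verification follows the
parameter-recovery paradigm: simulate data from known ground truth, then
require the calibration to return it. The generator emulates the
experimental pipeline end to end:

* **Geometry** — an open ellipsoidal cap (default semi-axes 60 × 50 × 40 mm,
  polar half-angle 60°, ~100 mm across: the scale of a porcine lobe) with an
  exact element count. Ring sizes grow in proportion to radius
  ($m_r \approx (T/R^2)\,r$, outer ring absorbing the remainder) so that
  element aspect ratios stay balanced at any target count; interior nodes
  are jittered (seeded) to mimic the irregularity of meshes reconstructed
  from stereo cameras. The coarse 457-element and finer ~5000-element counts
  used in practice are both reachable exactly.
* **Loading** — a monotone concave-down ramp from 0 to 2.5 kPa over 2 s
  (the inhalation half of 15 breaths/min). The peak was chosen once: with
  the calibrated shear modulus scale of ~275 kPa and a ~100 mm cap, 2.5 kPa
  produces strains of a few percent up to tens of percent, the range the
  experiment reports. Stage times sit at the five 20% increments of the
  ramp.
* **Probes** — dart-throwing (blue-noise) sampling of ~7000 points on the
  surface, seeded; probe displacements are the forward solution mapped
  through the *same* k = 5 nearest-neighbor operator the objective uses, so
  the noise-free objective is exactly zero at the ground truth and recovery
  tests have a clean oracle. Optional i.i.d. Gaussian noise per component
  emulates DIC measurement error (the stereo system's accuracy scale is
  about 0.1 mm); correlated DIC noise is out of scope.
* **Boundary motion** — the homogeneous scenarios hold the perimeter fixed.
  The heterogeneous scenario instead drives the perimeter with a seeded
  non-proportional displacement series (a monotone base bulge/lift plus an
  independent smooth low-order harmonic perturbation per stage, ~2 mm
  scale). This is not cosmetic: with a clamped perimeter every stage of the
  *linear* model is a scalar multiple of one displacement field, so the 80
  per-element unknowns of a 40-element cap face fewer independent data than
  unknowns and no optimizer can recover them. Recorded experimental boundary
  series are full-rank across stages, and the generator reproduces that
  property.

What passing recovery tests on these scenarios shows is that the inverse
machinery is correct and well-conditioned under the stated conditions; it
does not show that a real lung satisfies the membrane idealization, that
real DIC noise is i.i.d., or that the true tissue is Mooney–Rivlin. Those
are modeling assumptions inherited from the study design.

## Verification battery and problem sizes

The test suite and `run_validate()` exercise, at desk scale:

* analytic oracles — prism/shell volumes, the series solution of the
  pre-tensioned membrane under lateral pressure (2% at a 16 × 16 patch),
  textbook CST stiffness on a two-element patch, closed-form principal
  strains;
* consistency oracles — stress equals the central-difference energy
  derivative to $10^{-6}$ relative; the assembled tangent matches a
  finite-difference Jacobian; adjoint equals finite-difference gradients to
  $10^{-5}$ on a 40-element / 80-parameter case (and the 2-versus-1828
  solve-count contrast is asserted at the 914-parameter size);
* recovery — all seven multi-start runs on the 457-element noise-free
  scenario return $(C_{10}, C_{01}, D_1)$ within 2% with near-zero
  start-to-start spread; the heterogeneous 40-element scenario is recovered
  with an E-field RMSE below 10% of the field range; calibrating the HGO
  law on isotropic data drives $\kappa$ to its 0.33 bound. On that last
  point: the objective is flat to ~$10^{-5}$ relative in
  $(k_1, k_2, \kappa)$ near the optimum and a genuinely shallow local dip
  exists at intermediate $\kappa$, so an individual start can stall there;
  the multi-start winner resolves to the bound, which is exactly the role
  of multiple starts;
* interpolation — 10-fold cross-validated R² of the k = 5 interpolator
  above 0.95 at 7000 probes, degrading monotonically with added noise.

Scenario sizes (457 elements / 7000 probes for homogeneous work, 40
elements / 400 probes for heterogeneous work, 60-element scenarios for
optimizer-level unit tests) are the package's standard desk-scale study
conditions and are fixed in the test helpers.

## Known limitations

* The membrane carries no bending stiffness: wrinkling appears as
  stabilized null modes, and alternative wrinkled equilibria exist under
  compressive loading.
* The heterogeneous case is geometrically linear by design (matching the
  adjoint derivation); at the strains reached near peak inflation the
  neglected geometric nonlinearity is a modeling error of the same order as
  the strain.
* The HGO `D` parameter is not calibratable (inert under the J = 1
  membrane condensation), and `k2` is only weakly identified once the
  dispersion reaches its isotropic bound — both are properties of the
  formulation, reported as such.
* $\nu$ recovery in the heterogeneous case is weaker than $E$ recovery;
  the stiffness map should be read through the derived shear modulus.
* Timings in any published comparison of optimizer cost are
  hardware-specific and are not reproduced here.
```
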