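---
title: "Pipette-aspiration micromechanics of the embryonic ventricular wall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pipette-aspiration micromechanics of the embryonic ventricular wall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pamech)
```

## The measurement and its analysis

Pipette aspiration (PA) probes the passive stiffness of soft, small,
irregular tissues that cannot be cut into test strips.  A flat-tipped glass
pipette (inner radius $r_i = 0.050$ mm, wall 0.035 mm, edge fillet 0.005 mm)
seals against the epicardial surface; vacuum is ramped quasistatically
(0.4 kPa/s, sampled at 15 Hz) and the aspirated center height $L$ is tracked.
The analysis object is the load-deflection curve: aspiration pressure
$\Delta p$ against the normalized aspirated length $\bar L = L / r_i$.

Two complementary stiffness measures are computed.

**Strain energy density (SED).**  The area under the $\Delta p$-vs-$\bar L$
curve, $\int_0^{\bar L_{max}} \Delta p \, d\bar L$, has units
kPa $\times$ (dimensionless) $\equiv$ kJ/m$^3$: the work per unit volume
stored by the aspiration.  It is model-free — no constitutive assumption is
needed — which sidesteps the usual hyperelastic-fitting pitfalls
(over-parameterization, non-identifiability, incomparability across
functional forms).  Two windows are used: $\bar L \in [0, 0.2]$ (maximum
surface strains roughly 0.04–0.06, the near-linear regime) and $[0, 0.4]$
(strains 0.12–0.16).  `compute_sed()` integrates trapezoids between
successive samples in time order, signed, so that measurement jitter in
$\bar L$ cancels instead of inflating the area, and interpolates the
pressure at exactly $\bar L_{max}$ so the result does not depend on where
samples happen to land.  Curves start at $(0,0)$ by subtracting the
first-sample baseline; the raw recordings carry arbitrary small offsets and
the curves are plotted from the origin.

**Inverse finite-element modulus.**  A forward model of the test (below) is
iteratively adjusted until its load-deflection curve best matches a target
curve in least squares, yielding an apparent small-strain tangent modulus
$E$ with physical units, comparable across studies.

Cohort comparisons use one-way ANOVA with Tukey HSD across the three tested
sites (LV, RV, OFT) within a genotype, and pooled-variance t-tests between
genotypes (`Student's t-test' conventionally denotes the pooled form;
Welch is available by flag).  Ratios of group means are reported to 2
significant figures.

## The forward model

`build_model()` + `solve_sweep()` implement an axisymmetric finite-strain
model of the test:

* **Geometry.** A cylinder of wall tissue, radius 0.4 mm, meshed in the
  $r$–$z$ section: a compact layer of thickness $t_c$ on top, perfectly
  bonded to a trabecular layer of thickness $t_{tr}$.  The outer edge is
  fully fixed; aspiration-induced fields decay to a few percent of their
  apex values well before it.  The four reference conditions (control and
  mutant, LV and RV — `group_presets()`) use the confocal-reconstruction
  mean thicknesses and trabecular solid fractions.
* **Material.** Nearly incompressible neo-Hookean:
  $W = \tfrac{\mu}{2}(J^{-2/3} I_1 - 3) + p(J-1) - \tfrac{p^2}{2\kappa}$,
  with $\mu = E / (2(1+\nu))$ and $\kappa = E / (3(1-2\nu))$, $\nu = 0.49$
  for the high water content of embryonic tissue.  The pressure-like field
  $p$ is an independent unknown (mixed $u$–$p$ formulation) to avoid
  volumetric locking.  The trabecular layer is an effective medium: both
  $\mu$ and $\kappa$ (equivalently $E$ at fixed $\nu$) are multiplied by the
  trabecular solid fraction.  A `"linear"` law (St. Venant–Kirchhoff
  deviator with the same mixed volumetric treatment) is provided for the
  linear-elastic comparison; it is still analyzed at finite deformation,
  which is what produces its concave-upward load-deflection curve.
* **Elements.** 6-node quadratic triangles for displacement with a
  continuous linear pressure field (Taylor–Hood), the axisymmetric analogue
  of quadratic simplex elements with a mixed formulation.  The default mesh
  has about 1100 elements, graded toward the pipette edge annulus; a
  `refine` multiplier scales the target element size (`refine = 2` halves
  it and changes the center deflection by well under 1%).
* **Boundary conditions.** Symmetry on the axis; suction of magnitude
  $\Delta p$ on the free surface inside the lumen ($r < r_i$) as a follower
  pressure along the deformed surface normal (a fixed-direction option
  exists for sensitivity checks — it reverses the sign pattern of the apex
  strains and is not the physical choice for a fluid load); a roller
  (zero vertical displacement, traction-free radial sliding) where the
  pipette tip is in flat contact; fixed outer edge; free bottom.
* **The edge fillet.** The pipette tip carries a 0.005-mm fillet on both
  wall corners.  Flat contact therefore spans the wall annulus *reduced by
  the fillet radius at each edge*, and over the fillet spans the surface is
  supported by a vertical elastic foundation whose stiffness per unit area
  ramps linearly from zero (at the lumen edge) to an effectively rigid
  value (where flat contact begins), assembled consistently over the
  quadratic surface edges.  This smears the fillet into a graded roller:
  it removes the stress singularity of a sharp free-to-pinned transition
  (which otherwise collapses the sub-edge elements at modest suction) while
  keeping the constraint bilateral — no contact search, no lift-off, per
  the stated roller idealization.  A small penalty on each fillet-span
  midside node's deviation from the linear interpolant of its corner
  neighbors suppresses a spurious tangential slip mode of the quadratic
  surface edges; it adds no stiffness to smooth fields.  The foundation
  scale (400 $\mu/f$) is chosen so the foundation deflection under kPa
  tractions is below $10^{-4}$ of the aspirated height; apex strains move
  by only a few percent when this scale is halved or doubled.
* **Solution.** Load stepping from 0 to 3.5 kPa in 0.2-kPa increments.
  Each level is solved by modified Newton iteration: the sparse LU
  factorization of the finite-difference tangent is reused across
  iterations and load steps and refreshed when the contraction rate decays,
  with a backtracking line search on the residual norm; convergence is
  declared only on the exact residual (relative tolerance $10^{-8}$).
  Divergence triggers increment halving, and a stubborn level triggers a
  rescue that converges beyond the target and comes back down onto it —
  sharp local folds of the discretized path (element-scale snap-throughs
  near the contact edge) are leapt rather than walked into.

**Truncated sweeps.**  Under follower suction a soft neo-Hookean wall has a
genuine aspiration instability: beyond a critical pressure (about
$1.7\,\mu$ of the compact layer for these geometries) equilibrium is lost
and the sweep ends early, with a warning, at the last converged step.  The
two control models therefore stop near $\bar L \approx 0.52$–$0.54$ (1.2 and
2.8 kPa) rather than completing the nominal 3.5-kPa ramp; the mutant models
complete.  All reported quantities (SED windows to $\bar L = 0.4$, apex
strains at $\bar L = 0.2$ and 0.4, curve linearity, inverse fits over
$\bar L \le 0.4$) live inside the converged range, and curve statistics are
computed over the range each model actually reaches.

**Scale invariance.**  For fixed geometry and $\nu$, the deformation at
pressure $\Delta p$ under modulus $E$ equals the deformation at
$\Delta p / c$ under $E / c$.  The package exploits this only in the
synthetic-data generator (mapping a group-level forward curve onto
jittered per-specimen moduli); the inverse fit performs genuine forward
solves at each trial modulus.

## The inverse fit

`fit_modulus()` minimizes the squared deflection misfit at the model's
pressure steps (pressure is the controlled variable in both experiment and
model) over the window $\bar L \le 0.4$ — the same deformation range the
trend and SED analyses use, safely inside every model's converged range.
One forward solve at a reference modulus seeds the bracket through
deflection–compliance proportionality; Brent minimization on $\log E$
refines it to 0.01 kPa within bounds $[0.1, 100]$ kPa, expanding the
bracket if the minimum lands on an edge.  A fit costs about 10–13 forward
solves.  Steps are equally weighted; the objective is unimodal over the
bracket for these models.  Noise-free roundtrips recover the generator
modulus to well under 1%, and the recovered mutant/control ratios are 2.1
(LV) and 3.9 (RV).

## The synthetic cohort generator

No raw recordings accompany the study, so `simulate_cohorts()` inverts the
measurement chain through the forward model.  Its defaults are the study
conditions: four group/region conditions with the reference geometries and
fitted moduli, $n = 10$ specimens each, a 0.4 kPa/s ramp sampled at 15 Hz,
and the ramp ending once $\bar L$ passes 0.5 (the operator aspirates past
the analyzed range; this also guarantees every specimen supports the
0–0.4 SED window).  Two stochastic ingredients:

* **Measurement noise.** Additive iid Gaussian noise on the tracked
  deflection, $\sigma = 0.0005$ mm ($\approx 1\%$ of $r_i$).  No noise
  magnitude is reported for the original tracking; this default puts
  cohort linear-fit $R^2$ in the high 0.9s, consistent with the reported
  0.96–0.97 means.
* **Biological variability.** A lognormal multiplicative jitter on each
  specimen's modulus, $\sigma_{\log} = 0.25$, truncated at $2\sigma$ so
  every specimen's ramp can span the analyzed range within the pressure
  cap; this puts cohort SED standard errors on the order of the measured
  ones.

All randomness flows from one explicit seed; per-specimen seeds are
recorded in the manifest.  What the generator does *not* emulate: the
curvature of the real heart surface, tissue anisotropy and viscoelasticity,
seal leakage, tracking outliers, and the visibly nonlinear tail of some
real curves.  Green tests therefore demonstrate internal consistency of the
pipeline under the stated statistical structure, not agreement with new
experimental recordings.

`simulate_voxel_stack()` plants a trabecular-meshwork-like binary field
(smoothed white noise thresholded at the requested solid fraction) for the
morphometry utilities, which otherwise consume binary multi-page TIFF
masks: shrinkage/foreshortening correction (in-plane lengths divided by
0.80 for clearing shrinkage; z additionally by 0.81 for refractile
foreshortening — the two factors commute, only the documentation fixes an
order), solid fractions, and labeled chamber volumes.

## Numerical choices and limitations

* Element tangents are assembled by forward differencing the exact element
  residual ($h = 10^{-7}$); with quadratic elements and smooth laws the
  resulting Jacobian is accurate to $\sim 10^{-9}$ relative and preserves
  Newton convergence while keeping the kernels auditable.
* Apex strains are reported as Green strain components of the material
  point initially at $(r, z) = (0, 0)$, using the on-axis limit
  $F_{\theta\theta} \to F_{rr}$; reported quantities at exact $\bar L$
  targets interpolate linearly between bracketing load steps.
* The computed apex strains at $\bar L = 0.4$ sit within about 10–13% of
  the published reference solution, and within 3–6% at $\bar L = 0.2$; the
  residual gap is dominated by how the edge fillet is idealized (graded
  roller here, resolved arc geometry there), to which apex strains are
  mildly sensitive.
* Problem sizes: the default mesh (~1100 quadratic triangles, ~5300
  unknowns) solves a full sweep in seconds to about a minute; unit tests
  use a 0.7× mesh for speed and the acceptance checks use the default
  density.
* The roller is a fixed bilateral constraint: no lift-off, no spreading of
  the contact annulus with load.  A geometric (meshed) fillet arc with
  true unilateral contact is the natural next refinement and is out of
  scope here.
* One modulus is fitted per condition: the compact and trabecular layers
  share $E$ (scaled by solid fraction), $\nu$ is fixed, and anisotropy,
  viscoelasticity, residual stress and active tension are not modeled.
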