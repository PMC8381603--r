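---
title: "Inverse characterization of left-ventricular growth: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inverse characterization of left-ventricular growth: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Cardiomyocytes grow in two principal modes: in series (sarcomeres added
along the cell, lengthening it) and in parallel (widening it).  At organ
scale these produce eccentric hypertrophy — chamber dilation — and
concentric hypertrophy — wall thickening.  `cardiogrow` implements a
non-invasive way to estimate the two microscopic growth coefficients from
two macroscopic observations of the left ventricle (LV): a pre-growth
geometry and a post-growth geometry.  A finite-element model grows the
pre-growth LV under candidate parameters, and Bayesian optimization finds
the parameter pair whose grown shape best matches the post-growth target by
the DICE overlap score.  Because imaging data cannot ship with a package,
an idealized-LV generator stands in for segmented geometries; every stage
of the pipeline is exercised on synthetic data.

# Kinematic growth model

The total deformation gradient factors multiplicatively,
\(F = F^e F^g\).  Only the elastic part \(F^e\) generates stress.  The
growth tensor is transversely isotropic about the local fiber direction
\(f\):

\[
F^g = (1+\alpha_f)\, f \otimes f + (1+\alpha_n)\,(s \otimes s + n \otimes n),
\]

with sheetlet \(s\) and sheet-normal \(n\).  \(\alpha_f\) is longitudinal
growth, \(\alpha_n\) transverse growth, both on \([0,1]\) (1 doubles the
size in that direction), and \(\det F^g = (1+\alpha_f)(1+\alpha_n)^2\).

The elastic response is the Holzapfel–Ogden invariant-based energy with
isotropic, fiber, sheet and fiber–sheet coupling terms, evaluated on the
elastic invariants \(I_1^e, I_{4f}^e, I_{4s}^e, I_{8fs}^e\), using the
swine parameter set (`material_params()`: a = 1.05 kPa, b = 7.542,
a_f = 3.465 kPa, b_f = 14.472, a_s = 0.481 kPa, b_s = 12.548,
a_fs = 0.283 kPa, b_fs = 3.088).  Stresses are in kPa throughout; the
alternative MPa reading of the "a" parameters is rejected because the
printed values carry kPa units and because an end-diastolic pressure of
10 mmHg (1.33 kPa) is only a meaningful preload against a kPa-scale
stiffness.  Design choices around the printed formula:

* the exponent grouping of the anisotropic terms is read as
  \(\exp[b_i (I_{4i}-1)^2] - 1\), which is the standard form of the cited
  constitutive family and gives zero anisotropic energy at the reference;
* the fiber and sheet terms are tension-only by default (Macaulay bracket
  on \(I_4 - 1\)); `material_params(macaulay = FALSE)` selects the
  unconditional printed form;
* near-incompressibility is enforced with a volumetric penalty
  \(\tfrac{\kappa}{2}(\ln J^e)^2\), \(\kappa = 1000\) kPa, with the
  isochoric split applied to \(I_1\).

`pk2_stress()` returns the analytic second Piola–Kirchhoff stress
\(S = 2\,\partial\psi/\partial C\) pulled back through \(F^g\); it is
verified against finite differences of `strain_energy()` in the test
suite.

# Idealized LV geometry and fibers

`generate_idealized_lv()` meshes the wall between two prolate spheroids
(endocardial long/short semi-axes, apex and equator wall thicknesses
interpolated transmurally) truncated by a flat basal plane.  The long axis
is +z with the base at high z; `truncation_fraction` is the fraction of the
endocardial long axis kept below the basal plane (0.75 by default — a
typical LV; 0.5 truncates at the equator and yields the hemispherical
shell used as a thick-sphere benchmark).  The apex is closed with a
butterfly (O-grid) block layout: a structured square core surrounded by
transition rings, avoiding the degenerate collapsed hexahedra that break
explicit stable-increment estimates.  All generated meshes pass a
2×2×2 Gauss-point Jacobian-positivity sweep, and the enclosed-surface
volume agrees with the summed element volumes to well below 1%.

The default geometry is a young-swine-scale LV: endocardial semi-axes
30 × 15 mm, wall 4 mm at the apex and 7 mm at the equator (4–5 elements
across the wall at a 1.5 mm element edge, the default `element_edge`
sizing).  For interactive and test use, `coarse_lv_spec()` fixes a coarse
16 × 3 × 6 (circumferential × transmural × longitudinal) discretization.

`mesh_from_contours()` builds the same structured topology from a stack of
per-slice endo/epi contours (emulating short-axis segmentation output),
with per-angle quadratic extrapolation of \(r^2(z)\) closing the apex —
exact for spheroidal data.  `smooth_contour_stack()` removes through-slice
discontinuities with least-squares cubic B-splines along z using the
fewest knots that meet a residual budget; a zero budget reproduces the
input exactly, and data already on a smooth quadric are reproduced for any
budget.

Fibers follow the Laplace–Dirichlet rule-based construction restricted to
a single-chamber wall: a transmural harmonic coordinate (0 at endo, 1 at
epi, zero-flux at the base) and an apicobasal one (0 at the apex pole, 1
at the base) define the local transmural and longitudinal directions; the
helix angle interpolates linearly from +60° at the endocardium to −60° at
the epicardium (the paper-family convention leaves the sign open; the
right-handed-at-endo choice is configurable via `angles`).  The sheet
angle is fixed at 0° (sheetlet transmural).  Triads are orthonormal and
right-handed to 1e−9 on every element, and the construction is exactly
equivariant under rotations about the long axis.

# Quasi-static explicit solver

`run_growth_simulation()` integrates the damped equations of motion
(central differences, lumped mass) through two unit pseudo-time steps —
a linear endocardial-pressure ramp to `p_ed` (10 mmHg default, follower
load on deformed facets), then a growth ramp from zero to the target
\((\alpha_f, \alpha_n)\) at constant pressure — followed by a settle tail
at constant load that relaxes the final state to statics.  Intermediate
configurations are emitted at growth fractions {0.2, 0.4, 0.6, 0.8, 1.0};
each is a valid solution at the proportionally scaled parameters and
doubles as a cost-function sample for the optimizer.

Numerical choices that matter:

* **Mean-dilatation (B-bar) volumetric treatment.**  Fully integrated
  trilinear hexahedra lock severely under the κ-penalty; the volumetric
  term therefore uses the element-mean elastic dilatation, the same device
  as the reference C3D8 element.  Without it, transmural refinement
  changes the predicted cavity volume by a factor of two.
* **Mass scaling with tangent tracking.**  Nodal masses are set from a
  diagonal stiffness estimate so the requested increments per step
  (default 12,000) are stable, and are re-estimated every
  `contact_interval` increments from the current elastic invariants —
  the exponential stiffening of the myocardium outruns any fixed
  estimate.  Masses only grow, and momentum is conserved on update (the
  affected velocities scale down), which also brakes nodes entering stiff
  states.  `mass_safety` (default 4) multiplies the estimate.
* **Damping.**  Mass-proportional damping (default 90 per pseudo-time
  unit) gives dynamic relaxation; the pericardial shell, whose inertia is
  physically irrelevant, is overdamped 10×.  The quasi-staticity contract
  is the energy criterion: the peak kinetic/total-energy ratio after the
  early preload transient must stay below 5%, recorded per run in
  `peak_ke_ratio`.
* **Rigid-mode control.**  The basal plane is fixed longitudinally
  (u_z = 0); residual in-plane rigid modes are removed by projecting net
  translation and z-rotation out of the basal-ring velocities each
  increment.  Point pins were rejected: they bias symmetric ring expansion
  into a spurious lateral drift.
* **Increment-halving convergence.**  Halving the pseudo-time increment
  changes final configurations by well under 0.5% on the shipped
  examples.

# Pericardial constraint

The pericardium is a quadrilateral shell conforming to the epicardium at
generation time (`build_pericardium()`, E = 10 MPa, assumed thickness 1 mm,
ν = 0.3), with its basal ring fixed longitudinally.  Contact is a
frictionless normal penalty, pressure = `penalty_slope` × overclosure
(the p = 2h rule in model units, default 2 kPa/mm).  The implementation
uses node-to-nearest-facet search with clamped closest-point projection,
a vector-spring force on the penetration vector (continuous across facet
seams and contact onset), and a strain-free adjustment of initial
overclosures due to mesh faceting.

By default the shell acts as a *fixed* contact surface
(`build_pericardium(rigid = TRUE)`).  The dynamic membrane alternative
(`rigid = FALSE`, tension-field St. Venant–Kirchhoff, no bending) is
implemented but not the default: without bending stiffness its drum mode
concentrates hundreds of kPa at the apex once meridians stretch tens of
percent, producing mesh-dependent crushing.  A 10 MPa × 1 mm membrane is
radially stiff (under 3% compliance at the contact pressures reached
here), so the fixed surface preserves the intended restraint while keeping
the forward model consistent under mesh refinement.

# Shape metrics

`mask_from_nodes()` voxelizes a point cloud by depositing a separable
cubic B-spline kernel of width 4 voxels at each point (normalized so an
isolated point peaks at 1), thresholding at 0.25 and closing with a
spherical structuring element of diameter 6 voxels.  The specified kernel
and threshold spill a fixed sub-1.5-voxel margin beyond the true surface;
both sides of every DICE comparison share it, so the score is unaffected.
The pipeline samples element interiors (trilinear lattice, spacing half a
voxel) rather than mesh nodes alone, so mask solidity is independent of
mesh resolution; masks default to 2 mm isotropic voxels at desk scale
(configurable; finer spacing sharpens the DICE landscape at linear cost).
`dice()` is the plain voxel-count overlap.  `rigid_register()` is
principal-axes-initialized ICP with Kabsch updates (no scaling or shear);
during optimization the simulated geometry is registered to the target's
surface point cloud, and a fitted transform is kept only when it does not
reduce the DICE — registration can only help.

# Bayesian optimization

`optimize_growth()` follows the fixed protocol: three initialization
simulations at (0,1), (1,0), (1,1); each simulation contributes its five
growth checkpoints as cost samples at the proportionally scaled
parameters; then ten rounds of Gaussian-process fit → upper-confidence-
bound proposal → simulation → scoring.  The surrogate is a Matérn-5/2 GP
with per-dimension length scales (bounded to [0.1, 10] on the unit
square), standardized outputs, and noise variance estimated by marginal
likelihood with a floor of 1e−4 absorbing voxelization noise;
hyperparameters are optimized from a fixed grid of multi-starts so the
whole loop is reproducible under one seed.  The acquisition is maximized
on a deterministic 101 × 101 grid with lexicographic tie-breaking.

The exploration weight defaults to `beta = 10` and enters the acquisition
as \(\mu + \sqrt{\beta}\,\sigma\), the scaling used by the reference UCB
implementations of the field's optimization libraries; the plain
\(\mu + \beta\sigma\) reading at \(\beta = 10\) makes the acquisition
variance-dominated for the entire budget (13 simulations) and degrades the
estimate to the best point of a space-filling sample.
`bo_settings(beta_scale = "linear")` restores the plain reading.

# Synthetic validation

`generate_synthetic_target()` produces ground-truth targets with an
inverse-crime guard: generation uses a finer mesh and 5× smaller
pseudo-time increments than inversion.  The generation mesh
(`refined_lv_spec()`, 16 × 4 × 9) refines the transmural and longitudinal
edges but keeps the inversion model's circumferential count.  The reason
is deliberate: under pericardial restraint, strong growth places the soft
wall in circumferential compression, and meshes with ≥24 circumferential
elements can resolve an endocardial post-buckling branch that a 16-element
mesh cannot represent.  Crossing that branch between generation and
inversion is not "noise" — it makes the two forward maps disagree at every
parameter pair (cross-model DICE ≈ 0.65) and the inverse problem unsolvable
at desk scale.  Same-branch refinement keeps cross-model DICE ≈ 0.98 at
the true parameters while still perturbing every discretization quantity.

The desk-scale suite (`default_suite("desk")`) runs one geometry at the
two reference growth combinations — longitudinal-dominant (0.9, 0.3) and
transverse-dominant (0.1, 0.3); the full suite (3 geometries × 6
realizations, the two printed combinations plus four pairs drawn uniformly
on [0.1, 0.9]² under a fixed seed and reused across geometries) is
available behind `default_suite("full")` and is sized for an unattended
run rather than an interactive one.  Problem sizes used by the shipped
examples and tests: 336-element inversion meshes, 640-element generation
meshes, 12,000 increments per pseudo-time step (60,000 for generation),
2 mm masks.

What passing the synthetic suite does and does not show: the generator
emulates smooth truncated-spheroid ventricles with axisymmetric walls,
idealized rule-based fibers, a single hemodynamic load level and
forward-model discretization differences as the only noise source.  Real
CMR-derived ventricles add segmentation error, through-slice artifacts,
asymmetric shape detail and material heterogeneity; recovery accuracy on
the synthetic suite is therefore an upper bound on what the same pipeline
can do on imaging data.

Identifiability at desk scale is anisotropic in a way the DICE objective
makes explicit: transverse growth thickens the wall, to which the overlap
of two thin wall masks is very sensitive, while longitudinal growth under
a pericardial constraint changes the outline only mildly.  Near the
optimum the DICE landscape is a gently curved ridge whose top ~0.2% is
below the voxelization noise floor, so the best sample of the 13-simulation
protocol typically lands within ~0.05 of the truth in each coefficient
rather than on the acquisition-grid point itself; normalized errors are
correspondingly larger for small-growth cases whose ground-truth norm is
small.  The validation harness reports exactly what it computes.

# Known limitations

* Single-chamber idealized geometry; no septal or right-ventricular
  interaction, no DTI-derived fibers.
* The elastic membrane pericardium has no bending; the rigid-surface
  default trades its (small) radial compliance for refinement-consistent
  contact.
* No self-contact: extreme parameter corners (e.g. α_f = α_n = 1 under
  the pericardium) can close the lumen; the simulations remain stable and
  the resulting masks are still scored, but the geometries are outside
  the model's physical range.
* Growth is spatially homogeneous with two global coefficients, and the
  growth path is a single proportional ramp.
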