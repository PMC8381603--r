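# cardiogrow

Inverse characterization of left-ventricular (LV) myocardial growth from
shape. Cardiomyocytes grow in two modes — in series (lengthening the cell)
and in parallel (widening it) — which at organ scale produce eccentric
(chamber-dilating) and concentric (wall-thickening) hypertrophy. Given a
pre-growth LV geometry and a post-growth target shape, `cardiogrow`
estimates the two growth coefficients that best explain the observed
remodeling, for researchers in cardiac biomechanics who want a fully
scripted, data-free testbed for this class of inverse problems.

## The model

The total deformation gradient decomposes multiplicatively, F = Fᵉ Fᵍ,
with a transversely isotropic growth tensor

    Fᵍ = (1 + α_f) f⊗f + (1 + α_n)(s⊗s + n⊗n),

where (f, s, n) is the local fiber/sheetlet/sheet-normal triad, α_f is
longitudinal and α_n transverse growth (both in [0, 1];
det Fᵍ = (1+α_f)(1+α_n)²). Only Fᵉ generates stress, through the
Holzapfel–Ogden anisotropic hyperelastic energy with swine parameters
(kPa scale) and a volumetric penalty. The forward problem is solved by a
quasi-static explicit (dynamic-relaxation) finite-element solver on an
idealized truncated-prolate-spheroid LV with rule-based ±60° helix fibers,
a 10 mmHg end-diastolic preload, and a pericardial penalty-contact
constraint (p = 2h).

The inverse problem maximizes the DICE overlap between the voxelized
grown LV and the target mask over (α_f, α_n), using a Matérn-5/2
Gaussian-process surrogate with an upper-confidence-bound acquisition
(β = 10), three corner initializations, ten iterations, and five
intermediate growth checkpoints harvested from every simulation as extra
cost samples.

## Worked example

Generate a synthetic post-growth target at known parameters (on a finer
mesh with finer increments than the inversion model, so the inverse
problem is not solved with its own discretization), then recover the
parameters:

```r
library(cardiogrow)

case   <- synthetic_case(growth_params(0.9, 0.3))   # ground truth
target <- generate_synthetic_target(case)           # refined forward run
fit    <- estimate_growth(target)                   # BO inversion
print(fit)
#> Myocardial growth estimate (FE + Bayesian optimization)
#>   alpha_f (longitudinal): 1.000
#>   alpha_n (transverse):   0.240
#>   best DICE score: 0.973
#>   simulations: 13 (65 samples)
coef(fit)
#>  alpha_f  alpha_n
#>     1.00     0.24
normalized_error(case$ground_truth, growth_params(coef(fit)[1], coef(fit)[2]))
#> [1] 0.1232
plot(fit)      # GP posterior-mean DICE heatmap with samples and estimate
```

The printed estimate is the sample with the highest DICE score among the
65 cost-function evaluations: the grown model overlaps the target at
DICE 0.973, and the recovered pair deviates from the (0.9, 0.3) truth by
about 0.1 in the weakly observable longitudinal direction — under a
pericardial constraint, wall thickness (transverse growth) dominates the
shape signal, so α_n is recovered much more tightly than α_f.

A forward simulation alone:

```r
mesh   <- generate_idealized_lv(coarse_lv_spec())
fibers <- assign_fibers(mesh)
shell  <- build_pericardium(mesh)
sim    <- run_growth_simulation(mesh, fibers, material_params(), shell,
                                boundary_conditions(), solver_settings(),
                                growth_params(0.5, 0.2))
print(sim)
#> LV growth simulation
#>   target growth: alpha_f = 0.500, alpha_n = 0.200
#>   peak KE/total energy: 3.19%  (converged: TRUE)
#>   checkpoints: 5 at fractions 0.2, 0.4, 0.6, 0.8, 1
```

A command-line front end with `simulate`, `optimize` and
`synth-experiment` subcommands is installed at `inst/cli/cardiogrow`.

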