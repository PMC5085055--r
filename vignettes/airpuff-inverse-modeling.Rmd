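---
title: "Reconstructing corneal hyperelastic properties from air-puff deformation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing corneal hyperelastic properties from air-puff deformation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Non-contact tonometers of the Corvis ST type fire a short air pulse at the
cornea and film the deformation with a high-speed Scheimpflug camera
(140 frames over the ~30 ms event, about 4330 frames/s). The exported
quantities — the anterior-surface profile at highest concavity (HC) and the
apex displacement trace — depend on corneal stiffness, but they are
*deformation* parameters, not material parameters. `airpuffr` implements the
inverse route from such measurements to inherent hyperelastic constants: a
forward axisymmetric finite-element (FE) model of the air-puff test, a
scalar merit function built from standard deformation metrics, and an
adaptive surrogate-based optimizer that identifies the material parameters
minimizing the mismatch. A uniaxial tensile-test simulator provides the
cross-validation currency, the equivalent Young's modulus.

The package is written around hydrogel contact-lens phantoms (lathed
spherical "model corneas" mounted in an artificial chamber at a
water-column-controlled IOP of 15 mmHg), for which ground truth is
accessible; everything applies unchanged to excised corneas mounted the
same way.

## Constitutive model

The cornea is an incompressible two-parameter Mooney-Rivlin solid,

$$W = C_{10}(\bar I_1 - 3) + C_{01}(\bar I_2 - 3) + \tfrac{\kappa}{2}(J-1)^2,$$

with $\bar I_1 = J^{-2/3} I_1$, $\bar I_2 = J^{-4/3} I_2$ the isochoric
invariants of the left Cauchy-Green tensor and $J = \det F$. The volumetric
penalty $\kappa$ (default $1000\,\mu$ with $\mu = 2(C_{10}+C_{01})$)
enforces near-incompressibility in a pure-displacement formulation; at that
setting the measured volume change of the corneal material at peak load is
below $10^{-4}$, and whether the deviatoric term uses full or isochoric
invariants is numerically irrelevant (the two differ at order $(J-1)$).
The exact incompressible uniaxial solution
$P(\lambda) = 2(\lambda - \lambda^{-2})(C_{10} + C_{01}/\lambda)$
serves as a closed-form oracle for the FE engine, and its initial slope
$E = 6(C_{10}+C_{01})$ defines the small-strain equivalent modulus.

Viscoelasticity and anisotropy are deliberately out of scope: hydrogel
phantoms show almost no rate dependence (their temporal deformation profiles
track the pulse symmetrically), and only a single meridian is imaged, so a
2-D isotropic elastic model is the appropriate complexity.

## Forward model

**Geometry and mesh.** The phantom is a spherical shell of uniform
thickness: posterior radius 8.60 mm, anterior radius posterior + thickness
(8.95 / 9.05 / 9.15 mm for 350 / 450 / 550 um). `build_mesh()` maps a
structured quadrilateral grid (default 4 elements through the thickness x
100 along the meridian) between the two arcs from the apex to the clamp
aperture (5.5 mm radius). The holder is modeled as a stiff linear-elastic
flange (E = 1500 MPa, Poisson 0.3) continuing the same structured grid 2 mm
beyond the aperture with shared nodes (bonded contact) and a fully fixed
outer edge. This choice replaces a geometrically detailed clamp ring: what
the reconstruction is sensitive to is the clamped-periphery boundary
condition, which a flange four orders of magnitude stiffer than the cornea
reproduces; the aperture radius and flange width remain configurable.

**Element technology.** 4-node bilinear axisymmetric quadrilaterals with
selective reduced integration: the deviatoric energy is integrated with the
2x2 Gauss rule and the volumetric penalty at the element centroid only.
This removes volumetric locking (a clamped thin circular plate of
near-incompressible material bends within ~4% of Kirchhoff plate theory at
a 60 x 3 grid) while residual and stiffness remain exact derivatives of the
discrete energy — the Newton tangent, including the unsymmetric
follower-pressure load stiffness, matches finite differences of the
residual to ~1e-11.

**Loads.** The IOP acts as a uniform follower pressure on the wetted
posterior surface. Prescribed-pressure fluid elements, as used with
commercial solvers, are statically equivalent to exactly this load, so no
fluid degrees of freedom are carried; a volume-conserving closed cavity is a
non-goal (the chamber is connected to a water column holding the pressure
constant). The nominal geometry is stress-free; load step one inflates to
IOP and all air-puff displacements are reported relative to the inflated
state, which is what the instrument images before the pulse.

**Air pulse.** The instrument's true pressure footprint is proprietary to
its calibration; the package ships a parameterized stand-in
$$p(r, t) = p_{peak}\, e^{-r^2/2\sigma^2} \sin^2(\pi t/T),$$
with $\sigma$ = 1.5 mm, $T$ = 30 ms and $p_{peak}$ = 4.5 kPa. The peak was
calibrated once so that the nine phantom combinations (three materials of
manufacturer moduli 0.16 / 0.30 / 0.38 MPa, three thicknesses) span
deformation amplitudes of roughly 0.55-1.6 mm, the envelope such phantoms
exhibit under a Corvis-type pulse; at 10 kPa the softest phantom would
deform over 3 mm. All three pulse parameters are configuration-exposed and
a tabulated radial footprint can be substituted, so a properly measured
instrument profile drops in without code changes. Until one is supplied,
absolute (C10, C01) values reconstructed from *real* instrument exports
carry this instrument-calibration uncertainty; synthetic-data validation is
unaffected because generator and fitter share the pulse.

**Quasi-statics.** Each frame is a converged equilibrium solve at the
instantaneous pulse pressure (Newton with automatic load-step halving, at
most 5 halvings, scaled residual below 1e-6). Inertia is omitted: the
phantom response tracks the pulse closely and symmetrically, so the elastic
quasi-static treatment is consistent; it also makes the response a monotone
function of the instantaneous load, which the fast highest-concavity path
exploits (only the pulse-peak frame needs solving inside the inverse loop).
Frame-to-frame solves warm-start from a linear extrapolation of the two
previous states, which cuts a full 140-frame sweep to ~20 s at the default
mesh.

## Deformation metrics and merit

From a record, `compute_metrics()` evaluates the four standard parameters:
DA (apex displacement at HC), PDA (mean displacement interpolated at
exactly +/-2 mm lateral at HC), CPR = DA/PDA, and THC (time to HC). The
discrete peak of the apex trace is refined by a local quadratic fit (window
of two frames each side), which is exact for noiseless symmetric traces at
the instrument's frame rate and suppresses frame noise otherwise.

The inverse merit is
$$\Phi = |DA_m - DA_{sim}| + w\,|CPR_m - CPR_{sim}|, \qquad w = 1/3.$$
The down-weighting of the dimensionless CPR term resolves an ambiguity in
how the two residuals are combined; any positive $w$ has the same zero-merit
optimum whenever an exact fit exists, so the choice only matters under
model mismatch. $w$ is configurable.

`profile_rms()` (RMS difference of resampled profiles, spatial window
+/-4 mm) and `correspondence()` (100 minus the mean relative deviation over
a uniform strain grid, with a 1% floor guarding the zero-stress origin)
quantify the agreement plots; the central +/-4 mm window and the
correspondence definition are the package's own, documented choices since
neither is standardized.

## Inverse identification

`fit_material()` runs an efficient-global-optimization-style loop over
$(C_{10}, C_{01})$, bounds [0.005, 2] MPa each:

1. an initial Latin-hypercube design in log-parameter space (plausible
   moduli span a decade) is evaluated by full FE simulation;
2. an ordinary Kriging surrogate (Gaussian kernel, likelihood-selected
   common length scale on the unit box, interpolating nugget 1e-8) is fit
   to log(merit + 1e-4) — the log transform tames the dynamic range near
   the optimum;
3. a real-coded genetic algorithm (tournament selection, blend crossover,
   Gaussian mutation, elitism; 40 x 50 by default) minimizes the surrogate;
4. the GA optimum is verified by one FE run and appended to the design;
   when it duplicates an existing sample the loop evaluates the maximum
   predictive-variance point instead, so it keeps exploring.

The loop stops when an FE-verified merit drops below the tolerance (default
0.005) or the FE budget (default 80) is exhausted; every random component
draws from one seeded stream, so results are bit-reproducible. Forward
solves that fail to converge are logged and penalized with a large finite
merit rather than aborting. The reported merit is recomputed by a final
audit FE run at the fitted point.

**Identifiability.** DA pins down an overall stiffness very well, but the
(DA, CPR) pair separates $C_{10}$ from $C_{01}$ only weakly: the merit
surface has a long, nearly flat valley along which the split varies while
$6(C_{10}+C_{01})$ is essentially constant (points with 20-40% different
individual constants can agree in DA to less than a micrometre). The
equivalent modulus is therefore the identified — and validated — quantity,
which is exactly why the tensile cross-validation compares moduli rather
than individual constants. Reconstructions at the three phantom thicknesses
recover the same modulus with a coefficient of variation of a few percent.

## Tensile cross-validation

`simulate_tensile()` produces the nominal stress-engineering strain curve
of a strip specimen (defaults: 12 mm free length, 3 x 0.55 mm section,
strains 0-0.4) from the closed form; an FE mode stretches an axisymmetric
rod of equal cross-section area between prescribed end displacements — a
homogeneous uniaxial state does not depend on the cross-section shape, so
the rod reproduces the strip exactly and cross-checks the engine against
the closed form (agreement < 0.1%). `equivalent_youngs_modulus()` is the
0-to-0.1-strain secant ("average slope" over that range); an OLS-slope
variant is provided behind a flag and agrees to about 1% at this curvature.
Loading rate is recorded as metadata only (elastic model); the stop rules
of strip experiments (maximum extension, maximum force) are available as
curve truncation helpers.

## Synthetic data

`synthetic_study()` + `generate_airpuff_measurement()` emulate the
instrument: 140 frames over 30 ms, i.i.d. Gaussian displacement noise per
sampled surface point (default sigma 0.010 mm, approximating sub-pixel
segmentation error of a 640x480 Scheimpflug frame spanning ~10 mm; the
instrument's true noise figure is not published, so this is configurable).
The first noisy frame becomes the reference, so the displacement trace
starts at exactly zero, and the apex value of each frame is estimated from
a +/-0.25 mm lateral window — emulating sub-pixel apex estimation — which
keeps the recovered DA stable to ~0.003 mm across replicate noise draws.
Tensile measurements carry multiplicative Gaussian stress noise (default
2%); note that a secant modulus read from one noisy sample inherits that
noise level, so single-curve moduli scatter by ~2% while remaining
unbiased. What the generator does *not* emulate: segmentation bias,
whole-eye movement, viscoelastic asymmetry of the temporal profile, and the
instrument's true pulse footprint — so passing recovery tests demonstrate
correctness of the inverse machinery under the package's forward model, not
instrument-calibrated accuracy on real eyes.

## Numerical choices and problem sizes

* Default mesh 4 x 100 (cornea) + 10 flange columns; DA changes by < 1%
  when both resolutions double, and the meshed cross-section area matches
  the annular-cap formula to < 0.1%.
* Newton tolerance 1e-6 (scaled residual); inflation in 4 increments, each
  pulse frame from a warm start with automatic halving as a fallback.
* The test suite and the acceptance script run recovery studies with
  10 initial samples + up to 25 FE evaluations per fit, which reaches
  merits of ~2e-3 on noiseless targets in well under a minute per fit at
  the default mesh; these sizes are the package's chosen trade-off between
  statistical strength and runtime.
* Degenerate inputs: non-positive Jacobians, inconsistent sphere radii and
  unknown configuration keys are configuration errors; solver divergence
  raises a typed non-convergence condition carrying the last converged load
  fraction (exit code 3 at the CLI); duplicate surrogate samples are
  collapsed; constant-merit designs yield a constant surrogate.

## Limitations

* Elastic, isotropic, axisymmetric: no viscoelasticity (real corneas show
  asymmetric temporal profiles the model cannot produce), no fiber
  anisotropy, no patient-specific topography.
* The air-pulse footprint is a calibrated stand-in; absolute constants from
  real exports require substituting a measured footprint table.
* (C10, C01) are individually identifiable only weakly from (DA, CPR); use
  the equivalent modulus downstream.
* No contact mechanics: loads that would bring the posterior surface to
  self-contact are outside the validated range.
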