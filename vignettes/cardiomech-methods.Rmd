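---
title: "Reduced-order subject-specific cardiac mechanics: models, calibration and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reduced-order subject-specific cardiac mechanics: models, calibration and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiomech)
```

`cardiomech` implements the complete modeling chain used for
subject-specific beating-heart simulations — passive and active myocardium,
infarct homogenization, fiber-architecture analysis, multi-stage
calibration, a closed-loop circulation, and 16-segment strain validation —
around a reduced-order ventricle instead of a 3-D finite-element solve.
This vignette is the package's own account of the science: the models and
their assumptions, the parameters that matter, the numerical choices, what
the synthetic generators do and do not emulate, and the known limitations.

## Passive myocardium with infarct homogenization

Myocardium is modeled as an orthotropic exponential hyperelastic material.
With `C = F'F`, `I1 = tr C`, fiber/sheet invariants `I4f = f0·C f0`,
`I4s = s0·C s0` and the coupling invariant `I8fs = f0·C s0`, the isochoric
energy is

$$\Psi_{iso} = \frac{\bar a}{2b}\,e^{b(I_1-3)}
 + \sum_{i=f,s}\frac{\bar a_i}{2b_i}\left[e^{b_i(I_{4i}-1)^2}-1\right]
 + \frac{\bar a_{fs}}{2b_{fs}}\left[e^{b_{fs}I_{8fs}^2}-1\right],$$

and near-incompressibility is enforced by
$\Psi_{vol} = \tfrac1D\left(\tfrac{J^2-1}{2}-\ln J\right)$.

Tissue health enters through the homogenized coefficients
$\bar a_i = a_i\,A\,[h + (1-h)p]$: `h = 1` is healthy tissue, `h = 0` fully
infarcted scar, and intermediate values form the border zone. The
pathological ratio defaults to `p = 4.56`, the stiffness ratio of
late-stage scar to remote tissue estimated from in vivo porcine infarct
mechanics; the literature range is roughly 2–10, and `p` is a plain
argument of `passive_params()`. The subject multipliers `A` (all a-type
terms) and `B` (all b-type terms) are what the Klotz-curve calibration
adjusts.

Default coefficients are the calibrated human tri-axial shear set
(`a = 1.05` kPa, `b = 7.542`, `a_f = 3.465` kPa, `b_f = 14.472`,
`a_s = 0.481` kPa, `b_s = 12.548`, `a_fs = 0.283` kPa, `b_fs = 3.088`).

Two conventions are genuinely open in this family of models and are exposed
as switches, with the following defaults:

* **Invariant split.** The isochoric split $\bar I_1 = J^{-2/3}I_1$ is
  applied to the isotropic term only; the anisotropic invariants are
  unsplit. Splitting `I4` terms is known to produce spurious fiber response
  under volumetric deformation, which is why the unsplit form is common
  practice (`isochoric_split = TRUE` controls the `I1` treatment).
* **Tension-only fibers.** The `I4` terms contribute only when the
  corresponding direction is extended (`I4 > 1`), the original convention
  for this law; collagen fibers do not support compression
  (`tension_only = TRUE`).

The units of `D` deserve a note: for $\Psi_{vol}$ to be an energy density
`D` must carry inverse-stress units. It is taken as MPa^-1 with default
`0.2`, giving a bulk modulus `2/D = 10` MPa, roughly 10^3 times the largest
linear coefficient; values outside (0.02, 20) trigger a warning because
extreme penalties produce either spurious compressibility or ill-conditioned
stress. Exponent arguments are capped at 700: beyond that the evaluation
aborts naming the offending term, surfacing pathological parameters instead
of silently overflowing.

The Cauchy stress is the analytic push-forward $\sigma = J^{-1} F S F'$
with $S = 2\,\partial\Psi/\partial C$; tests verify it against central
finite differences of the energy (relative error below 1e-6 over random
deformations), exact zero stress at the reference, and objectivity under
random rotations.

**Simple shear convention.** Mode `"ij"` displaces the faces with normal
`e_i` along `e_j`, i.e. `F = I + gamma e_j (x) e_i`, and reports the
work-conjugate component `sigma_ij`. Shear-data publications disagree on
this naming; with the convention used here, modes `fs` and `fn` stretch the
fiber direction and are the stiffest, followed by the sheet modes and the
normal modes, matching the qualitative ordering of orthotropic myocardium
shear data.

## Active contraction

Active tension follows a time-varying elastance law,

$$T_a(t, l) = T_{max}\,\frac{Ca_0^2}{Ca_0^2 + ECa_{50}^2(l)}\;
  \frac{1-\cos\omega(t,l)}{2}\; h,$$

with length-dependent calcium sensitivity
$ECa_{50}(l) = Ca_{0max}/\sqrt{e^{B(l-l_0)}-1}$ and sarcomere length tied
to fiber stretch, $l = l_R\sqrt{I_{4f}}$. The activation phase rises as
$\omega = \pi t/t_0$ for $0 \le t < t_0$ and descends through a relaxation
window of duration $t_r = m\,l + b$; outside the window $\omega = 0$ and no
tension develops. Multiplying by `h` makes contractility directly
proportional to tissue health, so fully infarcted tissue generates no
force. Total stress adds `Ta` along the deformed fiber direction and a
fraction `n_s` along the deformed sheet direction.

Parameter defaults: the calcium and length constants
(`Ca0 = Ca0max = 4.35` uM, `B = 4.75` um^-1, `l0 = 1.58` um,
`lR = 1.85` um) are literature values for mammalian myocardium. The timing
constants are package choices sized so a complete twitch fits the 480 ms
active phase: time to peak `t0 = 220` ms and relaxation duration
`t_r = 80 l + 50` ms (about 210–230 ms at physiological sarcomere
lengths). All are arguments of `active_params()`. Sarcomere lengths at or
below `l0` return zero tension with a warning rather than an error, so
transient compressive states do not abort a simulation.

## The reduced-order ventricle

The ventricle is a thick-walled truncated prolate ellipsoid whose
endocardial and epicardial surfaces are geometrically similar (a common
long-to-short-axis ratio `e`), truncated by a basal plane. Similarity is
what makes the kinematics clean: a fixed axial scaling maps the wall onto a
spherical shell, where the deformation is taken as the classical
incompressible thick-sphere inflation `r'^3 = r^3 + k` composed with an
isochoric global long-axis stretch `diag(lamL^-1/2, lamL^-1/2, lamL)`, and
mapped back. Two degrees of freedom remain: cavity volume `V` (through
`k = a_endo^3 (V/V0 - 1)`) and long-axis stretch `lamL`.

This family has three properties worth stating precisely:

* it is **exactly isochoric pointwise** (`J = 1` everywhere, to round-off),
  so the wall is kinematically incompressible and the volumetric penalty
  never fights the kinematics;
* it is **injective at any inflation** — no shell crossing or apex
  inversion even at the large cavity expansions subject calibration
  requires (end-diastolic volumes of 3 or more times the unloaded volume);
* in the **spherical degenerate case** it reproduces the classical
  incompressible thick-sphere solution exactly, which the tests use as a
  closed-form oracle.

The cost of exact incompressibility within a two-parameter family is that
the deformed base "plane" warps slightly (the basal ring stays planar; the
wall cross-section above it does not), and transmural shear is the map's
own rather than an equilibrium field.

Pressure and the long-axis stretch come from virtual work: at fixed `V`,
`lamL` solves $\partial W_{int}/\partial\lambda_L = 0$ (the contraction of
the nominal stress with $\partial F/\partial\lambda_L$, integrated over the
wall quadrature), and the cavity pressure is the work conjugate
$P = \partial W_{int}/\partial V$. Both derivatives of `F` are analytic.
At `V = V0` with no active tension, `F = I` and `P = 0` exactly. The
quadrature uses 5 transmural x 8 longitudinal Gauss points and 1
circumferential station (axisymmetric tissue); infarct fields break
axisymmetry, and then 8–16 circumferential stations are used. Weights
reproduce the analytic wall volume essentially exactly (the volume element
is polynomial in the quadrature coordinates); the constructor enforces
agreement to 0.5%.

The fiber rule is linear in the transmural coordinate, +60 degrees
(endocardium) to -60 (epicardium) by default, overridable by any function
`alpha(s)`; the sheet direction is radial. Torsion is not a kinematic
degree of freedom — strain validation gets torsion from the analytic motion
generator instead.

Preset geometries solve the endocardial radius for the subject unloaded
cavity volumes (17.5 ml normal, 47.1 ml heart failure) at fixed shape
ratios: long axis twice the short axis, basal truncation at 70% of the
endocardial radius above center, 9 mm equatorial wall for the LV. No RV
geometry or RV pressure-volume data exist for these subjects, so the RV is
a stated assumption: the same machinery with a 6 mm wall and an unloaded
volume of 0.7 x the LV's, sized so the two chambers deliver matched stroke
outputs in the closed loop. The RV shares the LV material.

The long-axis shortening report (`lvls`) is
`100 (L_ED - L_ES)/L_ED` from the deformed endocardial base-to-apex
length; ventricular elongation reports negative values.

## Closed-loop circulation

Three linear compliance compartments — systemic arteries (SA), systemic
veins (SV) and a single pulmonary compartment (P) — close the loop around
the two ventricles. Each compartment obeys `P = (V - V0)/kappa`, and the
five connections (P to LV through the mitral resistance, LV to SA through the
aortic valve, SA to SV through the systemic vasculature, SV to RV through the
tricuspid resistance, RV to P through the pulmonary valve) carry the Ohmic
unidirectional flow `Q = max(dP, 0)/R`. Ventricular inflow is additionally
gated shut during the entire 480 ms active phase; outflow is always
pressure-gated. The 480 + 300 ms phases give a 780 ms cycle, i.e. 77 bpm.

Integration is explicit Euler with `dt = 1` ms by default, using pairwise
volume transfers so total blood volume is conserved to round-off
regardless of step size. One millisecond resolves the fastest dynamics in
the loop comfortably — halving `dt` changes the converged stroke volume by
well under 0.5% (tested) — and `dt` is a plain argument of
`circulation_params()` for anyone who wants finer steps or convergence
studies.

The default compliances and resistances (`kappa` = 1, 40, 8 ml/mmHg for
SA, SV, P; `R` = 40, 50, 2100, 40, 100 mmHg ms/ml for mitral, aortic,
systemic, tricuspid, pulmonary) are package values sized to give
physiological pig pressures (arterial roughly 70–105 mmHg, venous
4–6 mmHg) and a self-consistent limit cycle at the normal-profile stroke
volume; the subjects' own values were not published. Initial conditions
load each compartment to its end-diastolic pressure by inverting the
compliance relation, and the ventricles to the volumes at which their
passive pressure equals the target end-diastolic pressures. The default
initial compartment pressures (78, 5, 7.5 mmHg) are the model's own
converged end-diastolic values, so the first calibrated beat starts close
to the limit cycle it will settle into — mirroring the physiological-ED
initialization the modeling chain prescribes.

## Three-stage calibration

All three stages use bounded Levenberg-Marquardt least squares
(`minpack.lm::nls.lm`, box constraints, `ftol` 1e-10, at most 200
iterations); the trust-region-reflective optimizer used in the original
MATLAB workflow is not available in R, and for these smooth low-dimensional
problems the two families behave equivalently.

**Stage 1 — shear.** The eight passive coefficients minimize the summed
squared stress differences over all six simple-shear modes. Because a
uniform cube under affine boundary displacement deforms homogeneously, the
forward model is a single material-point evaluation (the tests verify
equivalence with a 27-cell homogeneous assembly). One identifiability
property matters for interpreting fits to noisy data: the amplitude and
exponent of each anisotropic term trade off along a ridge, so a single
dataset with 1% multiplicative noise pins down the curve (R^2 > 0.999) and
the isotropic pair `(a, b)` to a couple of percent, while `(a_s, b_s)` and
`(a_fs, b_fs)` can wander tens of percent along the ridge. Averaging
replicate datasets — the standard experimental practice — restores full
recovery: with 25 averaged replicates all eight parameters return within
5% from ±30% perturbed starts (tested).

**Stage 2 — passive scaling.** `(A, B)` minimize the squared pressure
differences along the passive inflation curve against a Klotz-type
single-beat EDPVR, plus a squared end-diastolic-volume term. The EDPVR uses
the normalized-volume power law `P = An Vn^Bn` with the empirical human
constants `An = 28.2`, `Bn = 2.79` kept in one overridable block, and the
volume at 30 mmHg placed so the curve passes exactly through the measured
(EDV, EDP) anchor. The reduced geometry has no shared septum, so the
trans-septal load from simultaneous RV pressurization is applied as a
ramped additive pressure offset `ts_weight * rv_edp * (V - V0)/(EDV - V0)`
on the LV forward model (default weight 0.1) — a documented approximation.
The objective spans many decades in `(A, B)` because the exponential law
reacts violently to large inflation, so the optimizer works in log
parameters and starts from the best point of a coarse log-grid scan; this
removes the bound-sticking that plain LM exhibits from a (1, 1) start.

**Stage 3 — active.** `(Tmax, n_s)` minimize
`(SV - SV*)^2 + 0.2 (LVLS - LVLS*)^2` with the first simulated closed-loop
beat as the forward model, matching the calibrate-on-beat-1 procedure; the
long-axis term is deliberately low-weighted (its role is to exclude
parameter sets that produce ventricular elongation, and the default target
is 15%, the low end of the physiological 15–20% range). With two residuals
and two parameters the fit is typically exact unless `n_s` hits a bound, in
which case the stroke-volume match absorbs a small compromise — the same
behavior the full-FE workflow reports between calibrated and converged
beats.

## Synthetic data: what it does and does not emulate

Every input class has a seeded generator that emits machine-readable ground
truth alongside the data, so the pipeline tests never depend on the
generators' internal choices.

* `gen_dt_grid`: diffusion tensors on a voxel grid whose primary
  eigenvector follows the transmural inclination-angle rule, with
  eigenvalues (1.0, 0.7, 0.5)e-3 mm^2/s, orientation noise as a rotation
  about a random axis with Gaussian angle (5 degrees SD default), and a
  seeded fraction of isotropic background voxels that the FA > 0.12 gate
  must reject. It emulates tensor geometry and orientation dispersion —
  not MRI physics (no Rician noise floors, eddy currents or b-value
  effects).
* `gen_infarct`: an ellipsoidal scar blob rasterized to a binary mask,
  with ground-truth `h` from the same trilinear rule the tissue-field
  module uses. Real infarct geometry is far more irregular; the blob tests
  the homogenization plumbing, not segmentation realism.
* `gen_shear_data`: forward six-mode curves plus multiplicative Gaussian
  noise — a stand-in for tri-axial shear experiments on myocardial cubes
  over the 0–0.5 shear range.
* `gen_motion_sequence`: an analytic endocardial ellipsoid with prescribed
  circumferential shortening, base-anchored long-axis shortening and linear
  apex twist, ramped by a half-cosine over the frames; ground-truth segment
  strains come from dense arc-length quadrature of the analytic map,
  independent of the spline machinery under test. It does not emulate
  speckle-tracking noise, dropout or through-plane motion.
* `gen_targets`: the printed subject profiles (normal: EDV 57.8 ml,
  SV 30.9 ml, EF 53.4%, RV EDP 4 mmHg; heart failure: EDV 103.0 ml,
  SV 33.0 ml, EF 32.0%, RV EDP 8 mmHg). The LV end-diastolic pressures are
  package assumptions (10 and 20 mmHg — the failing subject's EDP was
  roughly double the normal one's) and are flagged as such.

Passing tests therefore demonstrate that the algorithms recover known
ground truth under controlled conditions; they do not certify performance
on clinical images or noisy echo data.

## Fiber fields and strain mapping: conventions

* Transmural depth is the normalized coordinate of the similar-ellipsoid
  shell through a point, mapped to [-1, +1] (endocardium to epicardium).
* Tensor interpolation decomposes each of the 8 neighboring voxels into
  eigenvalues (the invariants) and an orientation quaternion, averages both
  with trilinear weights — eigenvector sets sign-aligned to the
  largest-weight neighbor first — and reassembles `R diag(lambda) R'`. This
  is an approximation of the cited invariant-interpolation scheme, whose
  exact invariant set is not published.
* The fiber sign ambiguity (+-e_f) is resolved against the local
  circumferential direction; inclination angles are folded into (-90, 90]
  and fibers within 1e-6 of radial are flagged undefined and excluded from
  statistics.
* AHA sectors are anchored at the anterior RV insertion (sector 1 starts
  there, angles counterclockwise in the apical view); the apical cap is the
  most apical ninth of the long axis.
* The 16-segment strain model uses landmark-anchored segments (not
  area-equal ones): basal/mid/apical thirds with 6/6/4 sectors. Control
  nodes are a 3x3 parametric grid per segment snapped to nearest vertices
  at ED and tracked by vertex identity; engineering strains come from
  natural cubic splines (chord-length parameterization, 64-point arc
  sampling — doubling the sampling changes strains by less than 0.01%).
  Global strains are area-weighted means of segment strains by default
  (`weighted = FALSE` gives plain means); how the reference echo tool
  aggregates is not published, so both are available.

## Numerical choices and degenerate inputs

* Long-axis equilibrium: warm-started damped secant iteration with
  fallback to bracketed root finding; non-convergence raises an error
  carrying the residual history. The residual tolerance is scaled by
  `a x wall volume` so it is dimensionless across geometries.
* Valve gating introduces flow discontinuities; explicit Euler at 1 ms
  simply steps across them, and the dt-robustness test bounds the effect.
* Trilinear interpolation at grid edges clamps to the nearest voxel with a
  warning; tensor interpolation with all 8 neighbors invalid raises a
  "no tissue support" error rather than inventing tissue.
* Empty region/depth bins in transmural profiles are reported as NaN rows
  with a warning, not dropped silently.
* Degenerate landmarks (coincident base/apex, radial RV-insertion
  projection below 1e-9) are errors.

## Known limitations

* The reduced-order ventricle replaces a full 3-D FE solve: regional
  stress/strain heterogeneity, papillary muscles, valve-ring boundary
  conditions, pericardial constraint and atria are out of scope, and
  published volumetric stress/strain tables from full-FE subject models are
  not reproducible here.
* Torsion is prescribed (in the motion generator), not predicted.
* The circulation has no inertances, atrial chambers, baroreflex or
  regurgitant flow.
* Viscoelasticity and damping are omitted: the reduced model is quasistatic,
  so the Rayleigh/Prony machinery a dynamic FE model needs has no role.
* The trans-septal coupling is a pressure offset, not a mechanical septum.
* Calibrated `(A, B, Tmax, n_s)` values are specific to this reduced
  kinematics and are not expected to coincide numerically with values
  calibrated through a full FE model, even for identical targets; what is
  preserved is the calibration logic and the fidelity of each fit to its
  own targets.
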