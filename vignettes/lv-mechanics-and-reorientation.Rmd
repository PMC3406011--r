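---
title: "Left-ventricular mechanics with shear-induced myofiber reorientation"
author: "lvfiber"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Left-ventricular mechanics with shear-induced myofiber reorientation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`lvfiber` implements an organ-scale model of left-ventricular (LV) mechanics
whose purpose is to study how the myofiber architecture of the LV wall can
emerge from a local adaptation rule, and what that predicts for ventricles
with a normal organ arrangement (situs solitus, SS) versus a mirror-image
arrangement (situs inversus totalis, SIT).  The model has four coupled
layers:

1. **Geometry.** The unloaded, passive stress-free wall is the region
   between two coaxial truncated prolate ellipsoids cut by a flat basal
   plane.  Semi-axes are solved from the wall volume (136 mL), the unloaded
   cavity volume (44 mL), the truncation height (half the epicardial long
   semi-axis above the equator) and the two axis ratios (2.0 endocardial,
   1.4 epicardial).  These values are representative of a small human (or
   large dog) heart; none of them is a measured quantity, and all are
   configuration.  A normalized chart (u, v) covers the wall: u is
   piecewise-linear in the geodesic distance from the equator along the
   local meridian (-1 apex, 0 equator, +1 base), v linear in transmural arc
   length (-1 endocardium, +1 epicardium).

2. **Tissue.** Cauchy stress is the sum of a passive and an active part,
   `sigma = sigma_p(F) + sigma_a (ef x ef)`, with `ef` the current fiber
   direction.  The passive part is a Fung-type transversely isotropic
   hyperelastic law,
   `W = a0 (exp(a1 tr(E E)) - 1) + af0 (exp(af1 E_f^2) - 1) + kappa/2 (J - 1)^2`,
   nearly incompressible through the volumetric penalty.  The active part is
   a two-element sarcomere model: a contractile element (CE) in series with
   a linear series-elastic element (SE); the stress scales with a CE
   length-dependence factor, a twitch time course whose duration grows with
   sarcomere length, and the SE extension.  Activation is simultaneous
   across the wall with a cycle time of 800 ms.  All coefficients are
   defaults of this package chosen to give a physiological working range
   (end-diastolic volume near 105 mL at 1.4 kPa filling pressure, peak LV
   pressure 15-18 kPa, ejection fraction near 0.5); they are exposed in
   `passive_params()` / `active_params()` and echoed into every run
   manifest.

3. **Circulation.** A lumped systemic loop: venous and arterial compliances,
   venous/aortic valve resistances as ideal diodes, and a peripheral
   resistance.  Defaults give a mean arterial pressure near 12 kPa and a
   cardiac output in the 5 L/min class.

4. **Reorientation.** After each cardiac cycle the unloaded fiber direction
   at every node moves towards the deformed fiber direction *corrected for
   rigid-body rotation*: with the right polar decomposition `F = R U`, the
   per-instant target is `U e_f0 / |U e_f0|`.  Targets are sampled at
   end-diastole and at twelve instants spread uniformly over the whole
   cycle (the adaptation acts continuously through both the diastolic and
   the systolic phase, so the discrete stimulus weights all instants
   equally; a gap-weighted variant is available and discussed below),
   sign-aligned (fibers are directionless), averaged, and the fiber is
   rotated along the geodesic towards the aggregate by the fraction
   `1/kappa` of the gap (default kappa = 5 cycles).  A fiber that is an
   eigenvector of U at all sampled instants (no fiber/cross-fiber shear)
   is a fixed point of the rule.

## Rotational symmetry and the finite-element formulation

The model is rotationally symmetric, which the discretization exploits
exactly as the mesh contract states it: the wall is covered by 27-node
hexahedral elements with tri-quadratic interpolation, 6 radial x 1
circumferential x 10 longitudinal = 60 elements, with a single
circumferential element spanning the full turn.  Kinematically this is
equivalent to axisymmetric displacements with the circumferential component
retained: a material point (R, Theta, Z) maps to
(r(R,Z), Theta + phi(R,Z), z(R,Z)), so the solver operates on the meridional
plane (9-node biquadratic quadrilaterals, three DOFs per node: u_r, phi,
u_z).  Torsion is representable through phi, and because phi is an *angle*,
the formulation stays regular on the axis.  In the co-rotating cylindrical
bases

    F = [ r_R      0     r_Z  ]
        [ r phi_R  r/R   r phi_Z ]
        [ z_R      0     z_Z  ]

so a rigid rotation about the axis maps to F = I and objectivity is built
in.  Boundary conditions follow the model statement: axial displacement
suppressed on the whole basal surface, circumferential displacement on the
endocardial basal ring only, traction-free epicardium, uniform cavity
pressure on the endocardium; on the axis u_r = phi = 0 by symmetry.

Numerical choices, and why:

* **Quadrature.** 3x3 Gauss points for the deviatoric/fiber/active terms.
  The volumetric penalty is integrated mainly at a reduced 2x2 rule to
  avoid penalty locking of the biquadratic element, with a fraction
  (`vol_stab`, default 0.2) kept at the full rule to control the volumetric
  modes the reduced rule cannot see.
* **Tangent.** Consistent tangents by per-element finite differences of the
  analytic residual.  This trades a constant factor in assembly cost for
  exact consistency with every constitutive feature (including the active
  clamp), and keeps the element code small.
* **Active coupling.** The SE stiffness `T0 f_iso / l_se0` is about three
  orders of magnitude above tissue stiffness, so freezing `sigma_a` over a
  time step is numerically explosive.  Within each solve the CE length and
  twitch factor are frozen but the SE stress follows the *current* fiber
  stretch, putting the SE compliance into the tangent.  The CE length
  evolves explicitly with 1-ms substeps (its time constant, l_se0/v0 of a
  few ms, is resolved).
* **Cavity-volume coupling.** The isovolumic phases require the pressure
  such that equilibrium holds at fixed cavity volume.  This is solved as a
  bordered Newton iteration on (u, p) with the volume constraint as the
  extra equation; the cavity volume is the surface integral
  `V = pi int r^2 dz` along the deformed endocardial curve, with an analytic
  gradient, so the border costs one extra back-substitution.  During
  filling and ejection the same bordered solve enforces the implicit valve
  flow relation `V(u) = V_old - dt (p - p_ext)/R`: an explicit flow update
  becomes unstable as soon as the chamber stiffens so that `R dV/dp < dt`,
  which routinely happens in systole.
* **Phases.** The cycle starts at activation onset (begin isovolumic
  contraction); transitions follow valve logic (aortic opens at
  `p_lv >= p_art`, closes when forward flow stops; mitral opens at
  `p_lv <= p_ven`); filling ends at the next activation.
* **Time step.** dt = 2 ms at full resolution, 4 ms for the reduced test
  meshes.  The operator splitting (explicit contractile-element dynamics,
  phase boundaries quantized to dt, explicit windkessel side of the
  implicit valve-flow constraint) is first-order in dt: halving the step
  changes the stroke volume by roughly 1-3% at the test resolutions, and
  the difference shrinks about linearly with dt.
* **Tolerances.** Newton: residual below 0.02 mN (absolute, about 1e-6 of
  the systolic force scale) with a 1e-9 relative fallback and a bounded
  stagnation exit at the finite-difference noise floor of the tangent;
  volume constraint to 0.01 mL; load substepping on non-convergence.  The Newton safeguard is deliberately *nonmonotone*:
  residual norms transiently grow along perfectly good Newton paths for
  exponential materials, and enforcing monotone decrease stalls the solver,
  so steps are damped only on element inversion or catastrophic growth.

## Fiber fields

The helix angle (between the circumferential direction and the fiber
projection on the circumferential-longitudinal plane) follows the cubic
transmural course `alpha_h(v) = h0 + h1 v + h3 v^3` (+50 deg endocardium,
-10 deg midwall, -70 deg epicardium by default: a mildly
epicardium-dominant course within the measured mammalian range, giving the
observed net counterclockwise apical rotation), optionally modulated
longitudinally by `(1 + bu u^2)`.  The transverse angle starts at zero
everywhere: fibers initially lie in the wall surfaces, and any crossover
between endo- and epicardium must *emerge* from the adaptation.  The
mirror-image (SIT) initial condition equals this normal field on the apical
side of a transition zone and its inversion (-alpha_h) on the basal side;
the zone centre sits at `u = u_t + slope * v` (a positive slope puts the
transition more apically at the endocardium), blending linearly in u across
a zone of height `h`.  The headline configurations vary `u_t` only:
+0.4 (BASE), 0 (MID), -0.4 (APEX); slope 0.2 and height 0.3 by default; the
shape variants (slope 0, steepest in-wall slope, height 0 and height 0.8)
ship as presets.

## What the experiments do

`run_experiment()` executes the full protocol of one configuration: passive
preload to the venous pressure, ten cardiac cycles with frozen fibers to a
hemodynamic steady state (stroke-volume change below 1% per cycle well
before the tenth cycle), then adaptation cycles with one fiber update per
cycle, recording per-cycle local metrics (phase-wise natural fiber strains
and stroke work density, volume-weighted mean and SD over the analysis
region) and global metrics (maximum LV pressure, stroke volume).  Torsion
is computed at four section levels (u = -0.6, -0.2, +0.2, +0.6), radially
averaged, referenced to begin-ejection and to the basal plane.  Two
normalizations are provided: net rotation (rad), and the tagging-study
shear convention (rotation times mean radius over axial distance to the
base) in which a uniform twist per unit length reads the same at every
section; the latter is what "homogeneous torsion across sections" refers
to.  The analysis region excludes the basal-most and apical-most element
layers, where the basal support and the apical pole dominate the local
state.

## The synthetic fixtures

All tests run without external data.  `make_motion()` produces displacement
histories with closed-form deformation gradients (rigid rotation, twist,
volume-preserving radial inflation, circumferential simple shear) used as
oracles for the kinematics, the postprocessing and the solver;
`mesh_tube()` provides the thick-walled cylinder of the classical
incompressible-inflation benchmark, which the solver matches to better than
1% over a range of pressures; `make_torsion_set()` generates seeded,
reproducible four-section torsion traces in the exchange CSV format with
additive noise and an optional end-of-cycle drift emulating the loss of tag
signal in tagging measurements (a drift-free trace returns exactly to zero
at the cycle end, as a cyclic deformation must).  These fixtures emulate
the *structure* of measured data, not its physiology: passing the
comparison plumbing on them says nothing about agreement with any real
ventricle.

### Why the stimulus is weighted uniformly over the cycle

An alternative discretization of the reorientation stimulus samples only
end-diastole and the ejection phase and weights each instant by its angular
gap, emphasizing the high-shear systolic states.  Implemented that way
(available as `adaptation_config(weighting = "gap")` with systole-heavy
sampling), the fibers chase the systolic stretch eigendirections: transverse
angles approach 90 degrees over wide regions, the helix field changes by
tens of degrees, and both the work-density spread and torsion grow.  The
uniform whole-cycle weighting is the discrete analogue of a rule acting
continuously in time, lets the long, low-shear diastole temper the systolic
pull, and restores the expected behaviour (small helix changes, dominant
transverse-angle development with the characteristic midwall sign pattern).

## What the packaged checks show - and where this model diverges

The test suite runs the full protocol at a scaled-down problem size
(4 x 1 x 8 elements, dt = 4 ms; spin-up of 10 cycles, 15 adaptation
cycles).  Under these conditions the model reproduces the qualitative
behaviour expected of shear-driven reorientation: pump function (stroke
volume, peak pressure) and mean stroke work density rise substantially;
ejection shortening increases while the isovolumic strains shrink; a
transverse angle develops from its zero initial condition with the
characteristic midwall sign pattern (negative apically, positive basally in
the normal configuration) and dominates the fiber change (RMS change about
twice that of the helix angle, which stays close to its initial course);
and the mirror-image runs produce continuous structures whose torsion is
normal-signed apically and inverted basally, with the inversion claiming
more of the wall as the transition zone moves from base to apex.

Three behaviours diverge from the findings this model family reports, and
the corresponding checks are deliberately left failing rather than
weakened:

* **Torsion amplitude rises** through reorientation here (e.g. 0.13 to
  0.18 rad peak shear angle in the normal run) instead of falling.  The
  adapted amplitude lands in the physiological band; the initial fields
  used here *underestimate* torsion, whereas the reported decrease starts
  from fields that overestimate it.  Both the adapted helix field and the
  emergent crossover contribute to the rise (attribution by swapping the
  fields separately).
* **The absolute SD of stroke work density** decreases only in the normal
  run at the test resolution; in the mirror-image runs the mean grows by
  60-70% and the absolute SD ends above its starting value even though the
  relative spread (SD/mean) contracts in every run.
* **Near-incompressibility** holds to about 5% (not 2%) of |det F - 1|
  over the analysis region at end-systole with the default penalty; a
  penalty stiff enough for 2% destabilizes the adaptation loop at these
  resolutions.

## Known limitations

* **The axisymmetric pole.** Near the apex the chart degenerates: midwall
  fibers are circumferential at a radius of a few millimetres, so systolic
  contraction drives the local fiber stretch far below the physiological
  sarcomere range while the fiber is slack (the admissible bounds in
  `active_params()` are correspondingly generous), and the reorientation
  targets there are extreme, producing transverse angles approaching 90
  degrees in a small neighbourhood of the pole.  The near-incompressibility
  statement (|J - 1| < 2% at end-systole) holds over the analysis region
  but not at the few pole points.  This is a known artifact of rotationally
  symmetric ventricular models, concentrated in the excluded apical layer.
* **Resolution of the test runs.** The end-to-end checks run at 4x1x8
  elements (the quick-start `reduced` preset is 3x1x5); quantitative values
  (stroke volume, work density) shift by several percent against the
  6x1x10 mesh, which is why the packaged checks are trend- and
  property-based at those resolutions.  At 3x1x5 the apical pole occupies
  a substantial fraction of an element layer and its artifact leaks into
  the regional statistics.
* **No sheets, no RV, no activation sequence.** The tissue is transversely
  isotropic (no laminar sheet structure or sheet reorientation), the right
  ventricle and pericardium are absent, and activation is simultaneous.
* **Uniform unloaded sarcomere length** (no transmural prestretch
  gradient).
* Mass/volume growth is not modelled: adaptation changes orientation only.
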