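---
title: "Modelling the elasticity-curvature illusion: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the elasticity-curvature illusion: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`tactillusion` studies a tactile phenomenon: a small, compliant sphere
(shear modulus 10 kPa, radius 4 mm) and a large, stiff sphere (90 kPa, 8 mm)
pressed against a fingertip produce nearly identical skin-borne (cutaneous)
signals, and so feel alike when the finger is held still — while a sphere that
differs only in radius (10 kPa, 8 mm) feels clearly different.  The two
lookalike stimuli nevertheless require very different finger travel to reach
the same contact force, so proprioception (the sense of finger position)
disambiguates them as soon as the finger moves actively.  The package
implements the full computational side of that study: a layered hyperelastic
finite-element model of fingertip-sphere contact, the measurement analytics
used around it (ink-print contact areas, force-rate extraction from
indentation traces), the same-different psychophysics with sensitivity under
the differencing rule, and seeded synthetic-data generators so that every
stage can be exercised and validated without human data.

This vignette records the modelling choices, their rationale, and the limits
of what the synthetic validation shows.

## Contact mechanics model

### Constitutive law

All soft materials use a compressible Neo-Hookean strain energy
$$\Psi = C_{10}(\bar I_1 - 3) + \tfrac{1}{D_1}(J-1)^2,
\qquad \bar I_1 = J^{-2/3}\,\mathrm{tr}(F^TF), \quad J = \det F,$$
with initial shear modulus $G = 2C_{10}$ and bulk modulus $K = 2/D_1$.  A
single modulus $G$ parameterises each material's elasticity, which is the
quantity varied across stimuli (10/50/90 kPa) and fitted for the skin layers.

Skin is conventionally treated as nearly incompressible.  We note that one
printed source relation for the bulk modulus would make $K$ five orders of
magnitude *softer* than $G$, which is non-physical for tissue; the package
instead defaults to $K = 10^5\,G$ (`kappa_ratio` in
`default_layer_stack()`), i.e. a Poisson ratio of effectively 0.5.  Because
bilinear elements at that ratio make the crushed-apex Newton problems very
stiff numerically, the simulation pipeline (`study_config()`) runs at
$K = 10^3\,G$ (Poisson ratio 0.4995): across the stimulus grid the computed
travels and cue profiles agree with the $10^5$ setting to three significant
digits, while the solves are about twice as fast and converge for every
stimulus up to 2 N.  This is a numerical-conditioning choice, not a material
one, and both ratios are exposed in the configuration.

### Geometry

The fingertip is a parameterised layered quarter-dome of soft tissue over a
rigid core, solved in an axisymmetric formulation (contact normal to the pad)
with a plane-strain variant used for the deflection step of the material
calibration.  The dome radius is derived from the cue-sampling contract: the
epidermal-dermal interface — 470 µm beneath the surface, where the relevant
mechanoreceptor end-organs live — carries exactly 111 equally spaced nodes
covering 0 to 15.2 mm of arc in the default configuration, which fixes the
outer radius at $15.2/(\pi/2) + 0.47 \approx 10.15$ mm, a realistic pad
radius.  Layer thicknesses (epidermis 0.470 mm, dermis 1.2 mm, subcutaneous
3.0 mm) are configuration defaults; only the epidermis thickness is pinned by
the interface depth, the others are plausible placeholders.

Default layer shear moduli are anchored to published layered fingertip
models (Young's moduli 0.136/0.080/0.034 MPa for epidermis/dermis/
subcutaneous at near-incompressibility, i.e. $G = E/3 \approx 45/22/9$ kPa).
The calibration module can refit them from deflection and force-displacement
targets; the synthetic targets shipped with the analysis are generated at
known moduli precisely so the two-step fit can be validated by recovery.

The stimulus tip is a hemisphere whose flat central section is attached to a
rigid driver plate, meshed on a smooth elliptic square-to-quarter-disc
mapping so no degenerate elements appear at the contact pole.  Every surface
edge in the contact region is at most 0.25 mm and interior edges at most
1.0 mm (both configurable).  The Poisson ratio of the tip material is 0.475,
mimicking nearly incompressible rubber.

One attachment detail is deliberately different from a fully bonded tie: with
both displacement components of the flat face tied to the plate, the glued
rim corner concentrates strain so strongly once the soft 10 kPa-4 mm sphere
flattens past its own radius (which the measured contact areas say it must,
at 2 N) that the quasi-static solve stalls around 1.5 N.  The default
`plate_tie = "frictionless"` ties the normal component only and lets the face
slip radially; `"bonded"` remains available.  At the loads where both
converge, the cue profiles under the two ties are nearly identical — the
difference is confined to the rim region away from the contact.

### Elements and volumetric locking

Both bodies use 4-node quadrilaterals with an F-bar (centroid-Jacobian)
treatment: the isochoric energy term is integrated at the 2×2 Gauss points
with the local deformation gradient, the volumetric term with the element-
centroid Jacobian over the element volume.  The nodal force is the exact
analytic gradient of that discrete energy, so the discrete system is
conservative — external work along an equilibrium path equals stored energy,
which the tests verify to 1%.  Element tangents are formed by central finite
differences of the exact force (8×8 per element, in compiled code); Newton
convergence is quadratic enough in practice and the implementation stays
simple and correct by construction.  Quadratic triangles would be the other
conventional choice; a single robust quadrilateral for both bodies keeps the
two-body contact machinery uniform, and the mesh-refinement and Hertz checks
bound the discretisation error directly.

### Contact and force control

Contact is frictionless node-to-segment penalty, applied symmetrically
(fingertip surface nodes against the stimulus surface polyline *and* stimulus
surface nodes against the fingertip surface) so that neither surface can fold
between the other's nodes when their resolutions differ.  The penalty
pressure stiffness auto-scales to $100\,G_{\text{soft}}$ per slave-node
spacing, keeping penetrations around $10^{-3}$ of an element edge at working
pressures; penalty energy stays below a few percent of the stored energy and
is reported per state.  The contact tangent is the exact local Hessian of the
penalty energy, obtained by finite differences of its closed-form gradient
for each active slave — the cheap frozen-normal approximation loses the
normal-rotation terms and makes Newton chatter near convergence at large
squash.

Loading is displacement-controlled through the rigid driver (the plate in
passive mode, the fingertip core in active mode); an outer secant loop on the
driver travel hits each scheduled normal force within 1% (configurable), with
adaptive sub-stepping and an energy/residual line search inside each Newton
solve.  Stopping follows a relative force residual of $10^{-3}$ (against the
current contact force) or a displacement increment below $10^{-6}$ mm.
Passive and active modes differ only in which body is driven; by frame
invariance the solutions at equal force agree to solver tolerance, which the
tests check and which holds to ~0.2% in travel.

### Cue extraction

Cutaneous cues are sampled per the interface contract: the value at an
interface node is the arithmetic mean of the element field over all elements
adjacent to that node (stress scalar: von Mises by default, the normal
component as an option, since the source figures do not name the plotted
measure); strain energy density uses the same rule; surface deflection is the
inward normal displacement of the epidermis surface nodes.  Profiles are
reported against the *reference* arc-length coordinate (material points), so
different stimuli are compared at the same skin locations.  The
dimensionless `cue_distance` between two profiles is the RMS difference over
the common range divided by the pooled RMS — 0 for identical profiles,
symmetric, and invariant to a common rescaling.

The proprioceptive cue is the active-mode force-displacement curve: the
fingertip travel required to reach each force.

## Verification strategy

* **Constitutive level.**  The strain energy is checked against an
  arbitrary-precision symbolic evaluation on frozen deformation gradients,
  and the analytic Cauchy stress against finite differences of the energy
  (stress power identity).
* **Element level.**  The assembled nodal force matches finite differences of
  the assembled energy to ~1e-9 relative; reference states are exactly
  stress-free.
* **Solver level.**  A near-rigid sphere (substrate modulus × 10⁴) pressed
  into a single-layer slab at small strain (mean strain ≈ 0.2 a/R < 5%)
  reproduces the Hertz contact radius and peak pressure within 5%; the
  contact radius and peak pressure are extracted by the classic $p^2$ vs
  $r^2$ linearisation of the Hertzian pressure profile (the symmetry-axis
  node is excluded from the fit because its penalty tributary area
  degenerates there).  Work-energy balance holds to 1%; modulus-force
  homogeneity (scaling all moduli and loads together leaves displacements
  unchanged) holds to discretisation tolerance.
* **Study level.**  With the default calibration, the cue distance between
  the illusion pair (10 kPa-4 mm vs 90 kPa-8 mm) is smaller than between the
  small-compliant sphere and the distinct sphere (10 kPa-8 mm) for interface
  stress, SED and surface deflection at every load in {0.25, 0.5, 1, 2} N,
  while the force-displacement curves of the pair stay separated (the
  small-compliant sphere needs ≥20% more travel at 2 N).

### Problem sizes

The verification and acceptance runs use deliberately reduced meshes chosen
once: the illusion grid runs at 56 interface nodes with 1/2/3 element rows
per layer and a 0.35 mm stimulus fine edge (≈330 + ≈150 elements per
two-body problem); the Hertz benchmark at a 0.08 mm surface mesh near the
axis (≈1600 + ≈600 elements); the calibration recovery at 21 interface
nodes.  Mesh-refinement checks bound the profile changes under halving the
element size; the full-resolution 111-node mesh is used for the structural
contracts and is available throughout via the configuration.

## Measurement analytics

**Contact area.**  Ink-print images are analysed by ROI-gated colour
thresholding (pixels whose RGB distance from paper white exceeds a
threshold), connected-component cleaning (speckle removal and small-hole
filling at a 25-pixel default), Moore-neighbour boundary tracing of the
largest component's exterior outline (interior holes are not subtracted),
pixel scaling from a 5.0 cm reference bar, and the shoelace (Gauss) formula.
The analyst's centre-radius selection is replaced by explicit sidecar values
for reproducibility; the reference bar length in pixels is annotated in the
sidecar, with auto-detection of the longest dark horizontal run as a
fallback.  On synthetic images with known area the pipeline recovers
0.5-2.0 cm² blobs within 3% at 0.005 cm/px (the residual bias is the
half-pixel erosion of a boundary traced through pixel centres).

**Traces.**  Force and laser channels are smoothed by a window-100 moving
average (window truncated at the trace ends).  The loading ramp is the
longest contiguous run of first differences above 20% of the peak rate
(ascending limb only); because the moving average rounds the ramp corners
into shoulders of reduced slope, samples below 90% of the run's median rate
are trimmed from the ends before the ordinary-least-squares force-rate fit —
on clean piecewise-linear ramps the trim is a no-op and detected boundaries
are exact.  Net displacement is the absolute difference of the displacement
channel between the ramp landmarks.  Recovery is unbiased within 2% across
the protocol rates {0.5, 1, 2} N/s down to 20 dB SNR.

## Psychophysics

The same-different task is scored under the differencing rule: per trial the
observer draws one noisy internal observation per interval (unit variance,
means separated by $d'$ on different-pairs) and responds "different" when
$|x_2 - x_1|$ exceeds a criterion.  Hit and false-alarm rates follow
$$F = 2\Phi(-k/\sqrt2), \qquad
H = \Phi\!\big(\tfrac{d'-k}{\sqrt2}\big) + \Phi\!\big(\tfrac{-d'-k}{\sqrt2}\big).$$
Inversion is numerical rather than table lookup: $k$ follows in closed form
from $F$, and $d'$ by root finding on the hit-rate equation ($d'=0$ when
$H \le F$); the Monte-Carlo observer validates the equivalence.  Observed
rates of 0 or 1 are corrected to $1/(2N)$ and $1 - 1/(2N)$ (standard
practice; the source is silent).  Per-condition sensitivity is reported both
ways — from pooled counts and as the unweighted mean of per-pair $d'$
(per-pair hit rates against the condition's false-alarm rate) — because the
pooling used originally is not fully specified.

The design utilities enumerate all $n^2$ ordered pairs (9 for the three
illusion spheres), present each pair 2 (passive tasks) or 3 (active task)
times per participant in seeded randomised order, and score percent correct
against the 75% same-different detection threshold.

The synthetic session generator assigns each condition an observer
sensitivity spanning chance to high (defaults 0.4 / 1.2 / 2.4 / 3.5 for
passive-same, passive-inverse, passive-direct and active force-rate tasks),
mirroring the qualitative ordering of the study's conditions; the human
percentages themselves are participant-dependent and are *not* treated as
recoverable truth.

## Statistics

Aggregation across participants uses the sigmoidal membership normalisation:
a logistic centred at each sample's mean with growth rate 1, mapping raw cue
values into (0, 1) while preserving ranks; it is applied per cue, per task
and per participant.  Group comparisons use the Mann-Whitney U test
(two-sided, $\alpha = 0.05$, midranks for ties; $U = \min(U_a, U_b)$), with
the p value computed by *full enumeration* of group assignments whenever
$nm \le 64$ and by the tie- and continuity-corrected normal approximation
otherwise.  Effect sizes are absolute Cohen's $d$ with the Bessel-corrected
pooled SD; intervals are percentile bootstrap with 1000 iterations (the
simplest interval consistent with the stated procedure), seeded for
reproducibility.  No multiple-comparison correction is applied, matching the
described analysis.

## What the synthetic validation does and does not show

The generators emulate the *structure* of the study's data: protocol
waveforms with additive Gaussian sensor noise, a laser channel driven through
the model's force-displacement relation, elliptical ink blobs with speckle
and boundary jitter plus an exact reference bar, and full factorial
same-different sessions from the differencing observer.  Passing tests
therefore show that the algorithms are correct and self-consistent — that
calibration recovers generating moduli, the area pipeline recovers known
areas, d' inversion inverts the observer that generated the data, and the
contact model reproduces the illusion ordering *given this fingertip
parameterisation*.  They cannot show that real skin obeys the Neo-Hookean
stack, that real ink spreads like the synthetic blobs (no smearing, ridges,
or partial transfer are modelled), or that human observers follow the
differencing rule; the human percentages and measured areas of the original
study are participant-dependent quantities that the package deliberately does
not claim to reproduce.

## Known limitations

* Quasi-static and elastic only: no viscoelasticity, no rate dependence, no
  friction; the experimental 30° finger orientation is idealised to normal
  contact on the axisymmetric pad.
* The fingertip outline is a parameterised dome, not a phalanx-derived
  geometry; non-epidermal layer thicknesses are placeholders.
* Bilinear F-bar quadrilaterals at extreme squash (contact radius beyond the
  stimulus radius, tissue compressed toward the rigid core) eventually stall.
  The shipped configurations solve the illusion comparisons to 2 N; the
  stiffest-and-smallest grid corner (90 kPa, 4 mm) concentrates the deepest
  tissue crush and can stop short of the top load, in which case the grid run
  reports it as a per-stimulus failure and continues.
* Penalty contact admits ~µm penetrations; contact pressures are recovered
  from penalty gaps and are least accurate at the symmetry axis.
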