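---
title: "Anatomy-induced scroll-wave drift in idealised atrial geometries: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anatomy-induced scroll-wave drift in idealised atrial geometries: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the electrophysiological model and its assumptions, the numerical
choices, the synthetic geometries and what they stand in for, and the
limits of what the package's tests can show.

## The question

Re-entrant electrical waves — spirals in two dimensions, scrolls in
three — underlie many atrial tachyarrhythmias.  In a homogeneous,
isotropic slab a stable rotor stays where it was created.  Real atria
are not homogeneous slabs: wall thickness varies continuously, thick
muscular ridges (crista terminalis, pectinate muscles) run along the
endocardium, and some pectinate muscles detach from the wall to form
*bridges* that touch it only at their two ends (junctions J1 and J2).
The package isolates each of these anatomical features in an idealised
voxel geometry and asks what it alone does to an otherwise stationary
rotor: does the rotor drift, in which direction, how fast, and does the
excitation pattern stay monomorphic?

## Ionic model

Cellular excitation is the Courtemanche–Ramirez–Nattel (CRN) human
atrial myocyte: 21 state variables (membrane potential, 15
Hodgkin–Huxley-type gates, 5 intracellular concentrations).  With
default parameters (`cell_params()`) the package reproduces the
published control behaviour: resting potential −81.2 mV, quiescence at
rest, APD90 ≈ 300 ms at 1 Hz pacing.

Sustained re-entry requires a shortened, flattened action potential.
The remodelled variant (`af_params()`) applies, on top of control:

* L-type Ca²⁺ conductance reduced to 35 % (`scale_gCaL = 0.35`),
* rapid and slow delayed-rectifier K⁺ conductances increased ninefold
  (`scale_gKr = scale_gKs = 9`),
* an acetylcholine-activated potassium current

  \[ I_{KACh} = C_m \cdot \frac{10}{1 + 9.13/[\mathrm{ACh}]^{0.477}}
     \cdot \Big(0.052 + \frac{0.45}{1 + e^{(V+59.53)/17.18}}\Big)
     \cdot (V - E_K), \]

  with \([\mathrm{ACh}] = 0.0035\,\mu\)mol/L and \(E_K\) the Nernst
  potential from the dynamic intracellular K⁺ (the CRN convention,
  extracellular K⁺ = 5.4 mM).  The exponent is typeset ambiguously in
  the source literature (0.47 vs 0.477…); the package defaults to the
  0.477 constant family and exposes it (`ach_exponent`), along with the
  two curve constants (`cach_offset`, `cach_amp`), so the choice is
  auditable.

A deliberate caveat, stated here because the package's acceptance
checks compute it: in this independent reimplementation the remodelled
parameter set produces a *shorter* action potential (APD90 ≈ 52 ms at
bcl 300 ms) and correspondingly *faster* re-entry (cycle length ≈
80 ms, dominant frequency ≈ 12.5 Hz, core ≈ 7.4 mm) than the
electrophysiological values reported alongside this parameter set in
the source study (106 ms, 9.2 Hz, 8 mm).  The control model verifies
against its published behaviour, each remodelling component shifts the
AP in the expected direction, and the gap is not a discretisation
artifact (it widens at dx = 0.1 mm), so the package implements the
parameter set as stated and reports the numbers it actually computes.
The core qualitative physics — a stationary, monomorphic,
non-meandering rotor in the homogeneous sheet with an ~8 mm core, and
thickness-driven drift in the structured walls — survives the
difference, but not all of it does: consequences of the faster,
more strongly tension-driven rotor are catalogued under *Known
limitations*.

## Tissue model and numerics

Tissue is the isotropic monodomain equation
\(C_m \partial_t V = -I_{ion} + D \nabla^2 V\) with no-flux boundaries,
\(D = 0.07\) mm²/ms.  Space is discretised on a Cartesian grid
(dx = 0.33 mm) with the 7-point Laplacian assembled by the method of
weights: a neighbour contributes \(1/dx^2\) iff it is tissue, and the
centre weight is minus the sum of the neighbour weights.  Every stencil
row therefore sums to zero, which makes the discrete diffusion operator
exactly conservative — the test suite checks \(\sum_i (\nabla^2 V)_i = 0\)
to machine precision, and that the stencil is grid-exact on quadratics.

Time stepping is Rush–Larsen for the gates (exponential update toward
the voltage-dependent steady state, which keeps every gate in [0, 1] by
construction) and forward Euler for the potential and concentrations,
dt = 0.01 ms — far below the explicit stability bound
\(dx^2/6D \approx 0.26\) ms.  Voltage-dependent rate expressions are
tabulated on a 0.05 mV grid with linear interpolation; a scalar
reference path (`crn_currents()`) evaluates the published expressions
directly and the suite checks the two paths against each other.
Diffusion acts on V only, and reaction and diffusion are advanced in a
single explicit pass (no operator splitting), matching the simple
forward-Euler description of the solver being emulated.

Two solver conventions worth noting:

* cached Nernst potentials are refreshed every 10 steps (0.1 ms);
  concentrations drift on second time scales, so the error is
  negligible, and the interval is a config field (`nernst_every`),
* activation times are recorded as linearly interpolated upward
  crossings of −50 mV, the same threshold used for the filament
  isosurface and for cycle-length detection.

A measured property of this discretisation that matters for
interpretation: at dx = 0.33 mm the 7-point stencil under-reads the
solitary-wave speed.  The model's continuum conduction velocity at
D = 0.07 mm²/ms is 0.40 mm/ms (recovered in the suite at dx = 0.1 mm),
while the same wave on the 0.33 mm study grid travels at ≈ 0.33 mm/ms
(control) and ≈ 0.30 mm/ms (remodelled, whose upstroke is slightly
blunted).  The package reports conduction velocity at the grid it is
asked to use and does not correct it toward the continuum value.

## Idealised geometries (the synthetic data)

`geom_*()` builders voxelise the idealised anatomies; a voxel is tissue
iff its centre lies inside the continuous solid.  In-plane coordinates
sit on grid nodes (so a 25 mm side at dx = 0.33 mm has
round(25/0.33)+1 = 77 nodes); through-wall layers are voxel-centred (a
3 mm wall is 9 layers).  All builders assert that the result is a
single 6-connected component.

* **sheet2d** — 25 × 25 mm monolayer; the homogeneous control
  experiment.
* **wedge** — wall tapering linearly from 3 mm to zero ("gradually
  reduced" is not quantified in the source; linear is the simplest
  monotone taper and the slope is a builder argument).
* **ridge** — 3 mm wall with a 2 × 2 mm strip of extra thickness
  spanning the full y extent, centred in x.
* **pm1** — flat wall plus a semicircular bridge (tube ∅ 2 mm, arc
  length 14 mm, radius 14/π ≈ 4.46 mm) in a plane perpendicular to the
  wall.  The junction chord (≈ 8.9 mm) is much shorter than the bridge,
  so wavefronts always enter the bridge from both ends and collide
  inside it: the bridge is electrically inert.
* **pm2** — hemispherical wall (outer ∅ 30 mm, 3 mm thick, convex face
  epicardial) with a straight 8 mm bridge near the apex.  The stated
  dimensions are mutually inconsistent as literally drawn: an 8 mm
  chord of the 12 mm-radius endocardial sphere dips only 0.69 mm below
  the surface, so a 2 mm-thick straight tube on the chord would touch
  the wall along its entire length and would not be a bridge at all.
  The builder therefore stands the bridge axis off the wall by 1 mm
  (argument `offset`) and joins it to the wall with short radial stubs
  at its ends — a free-standing pectinate muscle with two compact
  junctions and ≈ 0.7 mm of mid-span clearance.  The along-wall
  geodesic between the junctions (≈ 8.2 mm) remains longer than the
  bridge.
* **pm3** — pm2 plus a 2 mm surface ridge following the endocardial
  great circle from J1 to J2; removing the ridge voxels recovers pm2
  exactly.

Junction voxels are defined mechanically: any bridge voxel 6-adjacent
to wall, and any wall voxel 6-adjacent to bridge.  The epicardial flag
marks the flat face opposite the endocardial structures, or the convex
face of the hemispheres; tips are only ever reported there.

Arbitrary external voxel masks can be supplied through the same
`voxel_geometry` container (`read_geometry()` accepts any legacy-VTK
structured-points file with a `tissue` scalar), but the package makes
no claims about anatomies it did not generate.

## Scroll-wave initiation by phase distribution

`record_cycle()` paces a 33 mm strand at bcl 300 ms until consecutive
mid-strand action potentials agree to < 1 ms in APD90, then records the
full 21-variable state at the midpoint over one cycle (1 ms sampling,
phase 0 re-anchored to the upstroke).  `apply_phase_distribution()`
assigns each voxel the library state at its Archimedean phase

\[ \varphi(r, \theta) = \mathrm{frac}\big(s\,\theta/2\pi + r/\lambda\big),
   \qquad s = \pm 1, \]

whose level sets are Archimedean spirals of pitch \(\lambda\) (default:
the pulse wavelength CV × period of the library).  The phase is
constant through the wall, so the newborn filament is transmural; on
the curved PM2/PM3 walls the in-plane coordinates are projections onto
the tangent plane at the chosen centre (`sphere_frame()`).  The exact
3D extension used in the source study is unpublished; the
transmural-constant choice is the natural one and is stated here as an
assumption.  Chirality is the sign \(s\); mirroring the initiation in y
maps one chirality onto the other exactly, a property the test suite
verifies on a small sheet together with the (floating-point-approximate)
mirror equivariance of the whole pipeline.

## Filament extraction and tip analysis

The filament is the broken-line intersection of the isosurfaces
\(V = -50\) mV and \(o_i = 0.5\) (the transient-outward inactivation
gate lags V by a quarter cycle, so the two surfaces cross on the
rotation axis).  The named marching-cubes variant in the source
literature resolves case ambiguities with consistent tables;
this implementation achieves the same crack-free broken line by
splitting every grid cube into six Kuhn tetrahedra sharing the main
diagonal.  Within a tetrahedron both fields are linear, each isosurface
is a plane, and their intersection is a segment clipped to the
tetrahedron by four half-space tests; shared faces carry identical
diagonals, so segments from adjacent cubes meet exactly and are linked
into polylines by endpoint identity.  Tetrahedral decomposition is
ambiguity-free by construction, which is why it was preferred over
transcribing 256-entry case tables; the analytic-line oracle in the
suite bounds the deviation at under one voxel.  On single-layer sheets
the same construction one dimension down yields the spiral tip points
directly.

Per snapshot (every 10 ms) the epicardial endpoints of the polylines
are reduced to one tip.  The tip analytics follow the source protocol:

* `rotation_period()` — dominant frequency of the detrended tip x
  oscillation;
* `average_tip_trace()` — centroid of the raw tips over consecutive
  one-period windows, removing the circular core motion;
* `classify_drift()` — start-to-end displacement of the averaged trace,
  after discarding the first two rotation windows as the initiation
  transient, linearly rescaled to the 40 s reference duration and
  compared with the 10 mm criterion (equivalently a 0.25 mm/s rate).
  Motion above the criterion whose path length exceeds its net
  displacement sixfold is *excluded* as "not interpretable as
  continuous drift" — the ratio is a config value, since the source
  rule is qualitative;
* `core_diameter()` — twice the RMS distance of raw tips from their
  centroid over the final rotations.

## Trace analytics

The power spectrum is a single-taper periodogram of the mean-removed
probe trace, zero-padded fourfold to the next power of two; the
dominant frequency is the global maximum above 0.5 Hz.  No smoothing is
applied, and the raw (pre-padding) resolution is attached to the
result.  Cycle lengths are interpolated −50 mV upstroke intervals, and
the recurrence map is the point set (CL\(_n\), CL\(_{n+1}\)).  The
morphology rule makes the visual mono/polymorphic judgement of the
source study testable: *polymorphic* iff at least two non-harmonic
spectral peaks carry ≥ 20 % of the dominant peak's power.  Breakthrough
detection is likewise a defined heuristic standing in for a visual
call: a local minimum of the epicardial activation-time map whose 2 mm
ring activates ≥ 2 ms later and which is not connected to the map
border through voxels activated within 2 ms of the event; all three
thresholds are arguments.

## Scenarios, problem sizes and the drift laws

`run_scenario()` chains geometry → cycle library → phase distribution →
monodomain run → tip tracking → trace analytics, deterministically.
Desk-scale presets simulate 4 s for the 2D sheet (dt = 0.01 ms) and
1.2–2 s for the 3D geometries at dt = 0.025 ms — still ten times
below the stability bound; step-halving leaves APD90 within 1 ms and
conduction velocity within a few per cent, and the drift behaviours are
expressed within the first second after the transient.  The wedge
preset is short (1.2 s) because its rotor reaches the thin end and
annihilates within about a second; PM1 is the longest (1.6 s) because
resolving the 0.25 mm/s stationarity threshold against the rotor's
~0.5 mm bounded meander needs the most averaging.  The full-scale
presets reproduce the 40 s protocol unchanged (`scale = "full"`).

`assert_drift_laws()` evaluates, on a named set of scenario results:
(a) the wedge rotor drifts from the thick toward the thin end — the
signature of positive filament tension, which shortens the transmural
filament by moving it to thinner wall; (b) ridge drift is predominantly
ridge-parallel (|parallel| > 2 |perpendicular|) and reverses when the
rotor is seeded on the other side of the ridge; (c) ridge drift is
faster than wedge drift; (d) PM3 is polymorphic with long/short
cycle-length alternation (negative lag-1 correlation); (e) PM1 rotors
are stationary.  The chirality half of the ridge reversal law follows
from the mirror argument above: reflecting x maps a rotor of one
chirality on one side onto the opposite chirality on the other side
while preserving the along-ridge displacement, so opposite sides
drifting oppositely (checked by simulation) plus mirror equivariance
(checked on the small sheet) imply opposite chiralities drift
oppositely; no third full ridge run is spent on it.

## What the synthetic geometries do and do not emulate

The builders emulate exactly the gross features whose effects are being
measured — thickness gradients, abrupt ridges, detached bridges with
junctions, wall curvature — under the deliberate idealisations of the
study: no fibre orientation, no anisotropy, no diffusion heterogeneity,
no fibrosis, a single remodelling state, and one rotor at a time.
Passing the drift-law tests therefore shows that each isolated feature
is *sufficient* to cause its drift behaviour in this model family; it
does not show how the behaviours compose in a realistic atrium, nor
predict patient-specific dynamics.  The realistic-anatomy experiment of
the source study (hundreds of 40 s runs on a whole-atrium mask) is out
of scope, though external masks can be loaded through the geometry
container.

## Package shape

Core containers (geometries, field states, snapshot stacks) are plain
S3 objects around a compiled kernel, as is usual for simulators;
everything naturally tabular — tip traces, probe traces, spectra,
recurrence maps, drift reports, scenario summaries — is a tibble, with
`tidy()`/`glance()` methods on every result type and
`autoplot()`/`plot_*()` ggplot2 views, so analysis output drops
directly into dplyr/ggplot2 pipelines.

## Known limitations

* The remodelled-model discrepancy described under *Ionic model*: the
  stated parameter set is implemented faithfully but does not reproduce
  the published APD/frequency anchors; all reported numbers are the
  package's own computations.
* Coarse-grid conduction: velocities at dx = 0.33 mm are ~20 % below
  continuum; resolution-sensitive quantities (CV, rotor frequency,
  core size) should be compared across grids before quantitative use.
* The exclusion rule for erratic drift and the breakthrough detector
  are defined heuristics for qualitative judgements; their thresholds
  are exposed rather than claimed to be canonical.
* Desk-scale durations (1.2–4 s) demonstrate the drift behaviours but
  cannot observe slow phenomena the 40 s protocol could (late
  anchoring, equilibrium stand-off distances from junctions);
  `scale = "full"` exists for that purpose.
* Measured consequences of the remodelled-model discrepancy for the
  drift laws, computed by the acceptance suite and reported as they
  are: (i) the wedge rotor drifts *faster* (~13 mm/s) than the ridge
  rotor (~5 mm/s), inverting the expected speed ordering — the
  hyper-excitable rotor's filament tension is strong enough that the
  staircase-voxelised taper outpaces the ridge mechanism, and the
  wedge rotor reaches the thin edge and annihilates within about a
  second; (ii) the PM1 rotor is not perfectly stationary but creeps at
  ~0.5 mm/s toward the junction thickness bumps, exceeding the
  10 mm-per-40 s criterion; (iii) PM3 shows the expected periodic
  AP-amplitude modulation at the probe, but within a desk-scale window
  its secondary spectral peaks stay below the 20 % polymorphism rule
  and its cycle lengths do not alternate.  The wedge direction, the
  ridge-parallel drift and its reversal with initiation side, and all
  2D sheet properties behave as expected.
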