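# atriadrift

Monodomain simulation of anatomy-induced scroll-wave drift in idealised
human atrial geometries.

Re-entrant electrical waves (spirals in 2D, scrolls in 3D) sustain many
atrial tachyarrhythmias.  In a homogeneous slab of tissue a stable
rotor stays put, so any systematic motion observed in an anatomically
structured wall must be caused by the anatomy itself.  `atriadrift` is
for computational electrophysiologists who want to isolate those
causes: it builds voxelised idealisations of atrial features — a wedge
of tapering wall thickness, an endocardial ridge, pectinate-muscle
bridges that touch the wall only at their two junctions — creates a
rotor at a prescribed location and chirality, and quantifies the
rotor's drift from its filament-tip trajectory.

The model is the Courtemanche–Ramirez–Nattel (CRN) human atrial
myocyte (21 state variables) with atrial-fibrillation remodelling
(g_CaL × 0.35, g_Kr and g_Ks × 9) plus an acetylcholine-activated
potassium current

    I_KACh = Cm · 10/(1 + 9.13/[ACh]^0.477)
                · (0.052 + 0.45/(1 + e^{(V+59.53)/17.18})) · (V − E_K),

embedded in the isotropic monodomain equation
Cm ∂V/∂t = −I_ion + D ∇²V (D = 0.07 mm²/ms) on a Cartesian grid
(dx = 0.33 mm) with no-flux boundaries by the method of weights.
Gates advance by Rush–Larsen, everything else by forward Euler
(dt = 0.01 ms), in a compiled kernel.  Rotors are initiated by the
phase-distribution method (one recorded propagating cycle distributed
over an Archimedean spiral phase map); scroll filaments are extracted
as the broken-line intersection of the V = −50 mV and o_i = 0.5
isosurfaces and reduced to epicardial tips, whose rotation-averaged
trace classifies the rotor as stationary, drifting (more than 10 mm
per 40 s), or excluded.

## A worked example

A 2D reentry experiment on the 25 × 25 mm homogeneous sheet — initiate
a rotor at the centre, run 4 s, and analyse the tip trace and a probe
electrode:

```r
library(atriadrift)

sheet <- geom_sheet(25, 25, dx = 0.33)
lib   <- record_cycle(af_params(), bcl = 300)   # steady strand cycle
init  <- apply_phase_distribution(sheet, lib, spiral_spec(c(12.5, 12.5)))

cfg <- solver_config(duration = 4000, dt = 0.01, record_interval = 10,
                     probes = matrix(c(6.25, 6.25), nrow = 1))
sim  <- run_tissue(sheet, init, cfg, af_params())

tips   <- track_tips(sim)
period <- rotation_period(tips)
core_diameter(tips, period)
#> [1] 7.675102

classify_drift(average_tip_trace(tips, period))
#> <drift_class> stationary: 0.24 mm over 3760 ms (0.10 mm/s; 3.8 mm per 40 s)

trace <- probe_trace(sim)
p <- psd(trace$V_mV[trace$t_ms >= 1000], dt_sample = 1)
dominant_frequency(p)
#> [1] 12.51221
classify_morphology(p)
#> [1] "monomorphic"
```

The rotor is stationary and monomorphic with a circular core about
7.7 mm across.  Note the honest caveat documented in the methods
vignette (`vignettes/scroll-wave-drift.Rmd`): with the remodelling
parameters exactly as stated above, this independent reimplementation
rotates faster (~12.5 Hz, cycle length ~80 ms) than the 9.2 Hz /
106 ms reported in the study the package re-implements, while the
unmodified control model reproduces its published values.  The numbers
printed here are what the code computes.

The 3D drift experiments are packaged as presets:

```r
wedge <- run_scenario(scenario_spec("wedge"))
glance(wedge)      # one-row tibble: period, frequency, core, drift, ...
wedge$drift
#> <drift_class> drifting: 10.49 mm over 653 ms (13.40 mm/s; 536.0 mm per 40 s)
# direction (0.79, 0.61, 0.01): toward the thin end, at an angle to the
# thickness gradient as perturbation theory predicts

laws <- assert_drift_laws(list(
  wedge = wedge,
  ridge_left  = run_scenario(scenario_spec("ridge", site = "left")),
  ridge_right = run_scenario(scenario_spec("ridge", site = "right")),
  pm1 = run_scenario(scenario_spec("pm1")),
  pm3 = run_scenario(scenario_spec("pm3"))))
```

Every result type has `tidy()`/`glance()` methods and
`autoplot()`/`plot_*()` ggplot2 views; a thin command-line front end
over the same functions lives in `inst/cli/atriadrift.R`
(`geometry`, `init`, `run`, `track`, `analyze`, `scenario`).

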