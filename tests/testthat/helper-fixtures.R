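# Shared fixtures.  The expensive simulations (cycle library, the 2D
# reentry run, the 3D drift scenarios) are deterministic, so they are
# computed once per test session and reused across files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(key, fn) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- fn()
  .fixtures[[key]]
}

af_cycle_library <- function() {
  fixture("lib_af", function() record_cycle(af_params()))
}

# the 2D homogeneous-sheet reentry of the remodelled model, 3 s at the
# study grid, with tip trace and probe analytics
sheet_reentry <- function() {
  fixture("sheet_reentry", function() {
    sheet <- geom_sheet(25, 25, 0.33)
    lib <- af_cycle_library()
    init <- apply_phase_distribution(sheet, lib,
                                     spiral_spec(c(12.5, 12.5)))
    cfg <- solver_config(duration = 3000, dt = 0.01, record_interval = 10,
                         probes = matrix(c(6.25, 6.25), nrow = 1))
    sim <- run_tissue(sheet, init, cfg, af_params())
    tips <- track_tips(sim)
    period <- rotation_period(tips)
    trace <- probe_trace(sim)
    steady <- trace[trace$t_ms >= 1000, ]
    list(sim = sim, tips = tips, period = period,
         avg = average_tip_trace(tips, period),
         trace = trace, steady = steady,
         psd = psd(steady$V_mV, dt_sample = 1),
         rec = cycle_lengths(steady$V_mV, dt_sample = 1))
  })
}

drift_scenario <- function(key) {
  fixture(paste0("scenario_", key), function() {
    spec <- switch(key,
                   wedge = scenario_spec("wedge"),
                   ridge_left = scenario_spec("ridge", site = "left"),
                   ridge_right = scenario_spec("ridge", site = "right"),
                   pm1 = scenario_spec("pm1"),
                   pm3 = scenario_spec("pm3"))
    run_scenario(spec)
  })
}

# short strand run of the remodelled model with activation recording;
# duration scales with the expected wave speed (CV ~ sqrt(D))
strand_cv_sim <- function(D = 0.07, dx = 0.33, dt = 0.01, length = 33) {
  key <- paste("strand", D, dx, dt, length, sep = "_")
  fixture(key, function() {
    g <- geom_strand(length, dx)
    dur <- 60 + length / (0.25 * sqrt(D / 0.07))
    cfg <- solver_config(duration = dur, D = D, dt = dt,
                         record_interval = NA,
                         stim = list(sites = seq_len(max(3, round(1 / dx))),
                                     amplitude = -2000, start = 0,
                                     duration = 2, n = 1),
                         record_activation = TRUE, act_max = 4L)
    run_tissue(g, uniform_state(g), cfg, af_params())
  })
}
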