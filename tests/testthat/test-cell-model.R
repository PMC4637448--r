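# Ionic-model unit tests: the IKACh formulas, the scalar current path,
# the Rush-Larsen integrator, pacing and APD measurement.

test_that("IKACh ligand activation follows its saturating dose curve", {
  expect_identical(ikach_open(0), 0)
  # frozen from direct scalar evaluation of 10 / (1 + 9.13 / ach^0.477)
  expect_equal(ikach_open(0.0035), 0.0732582, tolerance = 1e-5)
  expect_lt(abs(ikach_open(1e15) - 10), 1e-4)
  ach <- 10^seq(-5, 2, length.out = 80)
  expect_true(all(diff(ikach_open(ach)) > 0))
  expect_error(ikach_open(-1), "ach")
})

test_that("IKACh voltage dependence is a decreasing sigmoid in (0.052, 0.502)", {
  expect_equal(ikach_voltage(-59.53), 0.052 + 0.45 / 2, tolerance = 1e-12)
  # frozen from direct scalar evaluation at V = -80 mV
  expect_equal(ikach_voltage(-80), 0.3971543, tolerance = 1e-5)
  expect_equal(ikach_voltage(1e4), 0.052, tolerance = 1e-9)
  V <- seq(-120, 60, by = 1)
  cv <- ikach_voltage(V)
  expect_true(all(diff(cv) < 0))
  expect_true(all(cv > 0.052 & cv < 0.502))
  expect_error(ikach_voltage(NaN), "finite")
})

test_that("IKACh current vanishes at the K+ reversal potential and at zero ACh", {
  s <- cell_state_rest()
  e_k <- 26.712338 * log(5.4 / s[["K_i"]])
  s_at_ek <- s; s_at_ek[["V"]] <- e_k
  expect_equal(ikach_current(s_at_ek, af_params()), 0, tolerance = 1e-9)
  expect_identical(ikach_current(s, cell_params(ach = 0)), 0)
  # composition of the two scalar terms at V = -80
  s80 <- s; s80[["V"]] <- -80
  expect_equal(ikach_current(s80, af_params()),
               100 * ikach_open(0.0035) * ikach_voltage(-80) * (-80 - e_k),
               tolerance = 1e-9)
})

test_that("control model is quiescent at rest and currents assemble correctly", {
  s <- cell_state_rest()
  # |dV/dt| = |I_ion|/Cm < 0.01 mV/ms at the published resting state
  expect_lt(abs(total_current(s, cell_params())) / 100, 0.01)
  # L-type conductance scaling is exactly linear in the current
  s0 <- s; s0[["V"]] <- 0
  ical <- function(p) {
    cur <- crn_currents(s0, p)
    cur$pA[cur$current == "I_CaL"]
  }
  expect_equal(ical(af_params()), 0.35 * ical(cell_params(ach = 0.0035)),
               tolerance = 1e-12)
  # a non-finite state is reported as a numerical failure naming a current
  bad <- s; bad[["V"]] <- NaN
  expect_error(crn_currents(bad), "numerical failure")
})

test_that("quiescent stepping holds the resting state and keeps gates bounded", {
  s <- cell_state_rest()
  out <- step_cell(s, cell_params(), dt = 0.01, n_steps = 1000L)
  expect_lt(abs(out[["V"]] - s[["V"]]), 0.1)
  gates <- out[c("m", "h", "j", "oa", "oi", "ua", "ui", "xr", "xs",
                 "d", "f", "fCa", "u", "v", "w")]
  expect_true(all(gates >= 0 & gates <= 1))
  # Rush-Larsen pulls boundary gate values back inside [0, 1]
  edge <- s
  edge[c("m", "h", "oa")] <- c(1, 0, 1)
  out2 <- step_cell(edge, af_params(), n_steps = 100L)
  g2 <- out2[c("m", "h", "oa")]
  expect_true(all(g2 >= 0 & g2 <= 1))
})

test_that("a uniform tissue equals the single-cell integrator voxel by voxel", {
  g <- geom_sheet(2, 2, 1)          # 3 x 3 nodes, no spatial structure
  cfg <- solver_config(duration = 5, D = 0.07, dt = 0.01,
                       record_interval = NA, nernst_every = 1L)
  sim <- run_tissue(g, uniform_state(g), cfg, af_params())
  cell <- step_cell(cell_state_rest(), af_params(), dt = 0.01,
                    n_steps = 500L)
  # uniform state: diffusion is identically zero, all voxels identical
  expect_equal(max(sim$final_state[, "V"]) - min(sim$final_state[, "V"]), 0)
  expect_equal(unname(sim$final_state[1, ]), unname(as.numeric(cell)),
               tolerance = 1e-12)
})

test_that("pacing converges and APD90 step-halves to within 1 ms", {
  p1 <- pace_to_steady(af_params(), bcl = 300, n_beats = 10, dt = 0.01)
  p2 <- pace_to_steady(af_params(), bcl = 300, n_beats = 10, dt = 0.005)
  expect_true(p1$steady)
  expect_lt(abs(p1$apd90 - p2$apd90), 1)
  # degenerate protocol: a single beat is just one stimulated AP from rest
  p3 <- pace_to_steady(af_params(), bcl = 300, n_beats = 1)
  expect_gt(max(p3$trace$V_mV), 0)
  expect_error(pace_to_steady(af_params(), bcl = 300, n_beats = 2,
                              stim_amp = -1),
               "stimulus failure")
})

test_that("APD90 matches the closed form on a triangular pulse", {
  # rise -80 -> +20 over 100 ms, fall back over 100 ms; 90 % repolarisation
  # of the 100 mV amplitude is at -70 mV, reached at t = 190 ms
  dt <- 0.1
  tt <- seq(0, 200, by = dt)
  V <- ifelse(tt <= 100, -80 + tt, 20 - (tt - 100))
  expect_equal(apd90(V, dt), 190, tolerance = 0.01)
  expect_error(apd90(rep(-80, 100), dt), "flat|upstroke")
})

test_that("tabulated integrator path agrees with the scalar current path", {
  # one step of the integrator must advance V by -dt * Iion / Cm where
  # Iion comes from the independent scalar evaluation
  s <- cell_state_rest()
  s[["V"]] <- -30; s[["d"]] <- 0.5; s[["f"]] <- 0.8; s[["oa"]] <- 0.3
  total <- total_current(s, af_params())
  out <- step_cell(s, af_params(), dt = 0.01)
  expect_equal(out[["V"]] - s[["V"]], -0.01 * total / 100,
               tolerance = 2e-3)
})
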