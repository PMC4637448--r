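# Phase-distribution initiation: cycle library, Archimedean phase map,
# spiral formation and chirality on a small sheet.

test_that("the strand cycle library is steady, closed and upstroke-aligned", {
  lib <- af_cycle_library()
  expect_equal(lib$period, 300)
  expect_gte(nrow(lib$states), 100)
  V <- lib$states[, "V"]
  expect_lt(min(V), -78)          # diastolic samples present
  expect_gt(max(V), -10)          # excited samples present
  # phase 0 is the upstroke: the first few samples rise steeply
  expect_gt(V[3] - V[1], 20)
  expect_gt(lib$cv, 0.2)
})

test_that("Archimedean phase winds once and has pitch lambda", {
  sp <- spiral_spec(c(0, 0), "anticlockwise", lambda = 10)
  # pitch: moving one lambda radially leaves the phase unchanged
  expect_equal(archimedean_phase(3, 4, sp), archimedean_phase(9, 12, sp),
               tolerance = 1e-12)
  # winding: one full turn changes the phase by exactly one (the sign
  # encodes the chirality convention: the label names the rotor's
  # rotation sense, which is opposite to the arm's winding sense)
  th <- seq(0, 2 * pi, length.out = 400)[-400]
  phi <- archimedean_phase(5 * cos(th), 5 * sin(th), sp)
  dphi <- diff(phi)
  dphi <- dphi - round(dphi)      # unwrap
  expect_equal(abs(sum(dphi)), 1 - 1 / 399, tolerance = 0.02)
  # chirality flip mirrors the phase field in y
  sp_cw <- spiral_spec(c(0, 0), "clockwise", lambda = 10)
  expect_equal(archimedean_phase(3, 4, sp_cw), archimedean_phase(3, -4, sp),
               tolerance = 1e-12)
  # centre convention
  expect_identical(archimedean_phase(0, 0, sp), 0)
})

test_that("phase distribution assigns library states with phase 0 at the centre", {
  g <- geom_sheet(12, 12, 0.33)
  lib <- af_cycle_library()
  sp <- spiral_spec(c(5.94, 5.94))
  st <- apply_phase_distribution(g, lib, sp)
  expect_equal(nrow(st), g$n_voxels)
  centre <- nearest_voxel(g, c(5.94, 5.94))
  expect_equal(unname(st[centre, ]), unname(lib$states[1, ]))
  # every assigned state is a library row
  expect_true(all(st[, "V"] %in% lib$states[, "V"]))
})

test_that("initiation produces a rotor at the prescribed centre with the right chirality", {
  # large enough that the rotor core (~7 mm) survives away from the edges
  g <- geom_sheet(19.8, 19.8, 0.33)
  lib <- af_cycle_library()
  run1 <- function(chir) {
    init <- apply_phase_distribution(g, lib, spiral_spec(c(9.9, 9.9), chir))
    cfg <- solver_config(duration = 500, dt = 0.01, record_interval = 10)
    sim <- run_tissue(g, init, cfg, af_params())
    track_tips(sim)
  }
  tips_ccw <- run1("anticlockwise")
  # after about one rotation the singularity is near the prescribed centre
  t1 <- tips_ccw[tips_ccw$t_ms >= 80 & tips_ccw$t_ms <= 160, ]
  expect_gt(nrow(t1), 0)
  expect_lt(min(sqrt((t1$x - 9.9)^2 + (t1$y - 9.9)^2)), 5)
  # signed area swept about the mean: positive for anticlockwise rotation
  swept <- function(tp) {
    x <- tp$x - mean(tp$x); y <- tp$y - mean(tp$y)
    n <- nrow(tp)
    sum(x[-n] * y[-1] - x[-1] * y[-n])
  }
  tips_cw <- run1("clockwise")
  late_ccw <- tips_ccw[tips_ccw$t_ms >= 200, ]
  late_cw <- tips_cw[tips_cw$t_ms >= 200, ]
  expect_gt(swept(late_ccw), 0)
  expect_lt(swept(late_cw), 0)
  # mirror equivariance: the clockwise run is the y-mirror of the
  # anticlockwise run (initiation is exactly mirrored; the dynamics
  # preserve it up to round-off growth)
  expect_equal(tips_cw$x, tips_ccw$x, tolerance = 0.05)
  expect_equal(tips_cw$y, 2 * 9.9 - tips_ccw$y, tolerance = 0.05)
})
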