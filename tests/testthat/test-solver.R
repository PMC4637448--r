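# Monodomain solver: no-flux stencil structure, grid-exact Laplacian,
# conservation, stability guard, determinism.

block_geom <- function() geom_ridge(3, 3, 3, 1, 0, 0.5)  # 7x7x6 block

test_that("stencil weights follow the method of weights", {
  g <- block_geom()
  W <- build_weights(g)
  expect_true(any(W$n_neighbours == 6))        # interior voxels
  expect_true(all(W$n_neighbours >= 3))        # corners of the block
  # monolayer sheet: interior voxels have 4 neighbours
  Ws <- build_weights(geom_sheet(5, 5, 0.5))
  expect_true(any(Ws$n_neighbours == 4))
  expect_true(all(Ws$n_neighbours <= 4))
})

test_that("Laplacian is zero on constants and grid-exact on quadratics", {
  g <- block_geom()
  W <- build_weights(g)
  expect_equal(max(abs(laplacian(rep(3.7, g$n_voxels), W))), 0)
  co <- geom_coords(g)
  lap <- laplacian(co[, "x"]^2, W)
  # interior voxels (all 6 neighbours present): exactly 2, to round-off
  interior <- W$n_neighbours == 6
  expect_true(any(interior))
  expect_lt(max(abs(lap[interior] - 2)), 1e-9)
})

test_that("the diffusion operator conserves total voltage to machine precision", {
  g <- block_geom()
  W <- build_weights(g)
  set.seed(42)
  V <- stats::rnorm(g$n_voxels, -60, 30)
  s <- sum(laplacian(V, W))
  expect_lt(abs(s), 1e-8 * g$n_voxels)
})

test_that("the stability bound is enforced and uniform rest stays uniform", {
  g <- geom_sheet(5, 5, 0.33)
  expect_error(
    run_tissue(g, uniform_state(g),
               solver_config(duration = 1, dt = 0.3), af_params()),
    "unstable")
  cfg <- solver_config(duration = 2, dt = 0.01, record_interval = NA)
  sim <- run_tissue(g, uniform_state(g), cfg, af_params())
  expect_equal(max(sim$final_state[, "V"]), min(sim$final_state[, "V"]))
})

test_that("identical configurations give bit-identical results", {
  g <- geom_strand(25, 0.33)
  cfg <- solver_config(duration = 30, dt = 0.01, record_interval = 10,
                       stim = list(sites = 1:3, amplitude = -2000,
                                   start = 0, duration = 2, n = 1))
  s1 <- run_tissue(g, uniform_state(g), cfg, af_params())
  s2 <- run_tissue(g, uniform_state(g), cfg, af_params())
  expect_identical(s1$snap_V, s2$snap_V)
  expect_identical(unclass(s1$final_state), unclass(s2$final_state))
})

test_that("duration zero echoes the initial state as a single snapshot", {
  g <- geom_sheet(3, 3, 0.33)
  st <- uniform_state(g)
  sim <- run_tissue(g, st, solver_config(duration = 0), af_params())
  expect_length(sim$snap_t, 1)
  expect_equal(sim$snap_V[, 1], unname(st[, "V"]))
})

test_that("conduction velocity scales as the square root of diffusion", {
  # cable-theory self-similarity: quartering D and halving dx rescales
  # the whole problem, so the measured CV must halve.  (At a fixed
  # coarse dx the law breaks down: the D/4 front is narrower than a
  # voxel and lattice pinning collapses its speed.)
  cv1 <- measure_cv(strand_cv_sim(D = 0.07, dx = 0.33))
  cv2 <- measure_cv(strand_cv_sim(D = 0.07 / 4, dx = 0.165))
  expect_equal(cv1 / cv2, 2, tolerance = 0.05)
})

test_that("CV measurement is insensitive to the probe fractions", {
  sim <- strand_cv_sim(D = 0.07)
  cv_a <- measure_cv(sim, c(0.25, 0.75))
  cv_b <- measure_cv(sim, c(0.30, 0.70))
  expect_lt(abs(cv_a - cv_b) / cv_a, 0.02)
})

test_that("refining the grid converges the solitary-wave CV to 0.4 mm/ms", {
  # the 0.33 mm study grid under-reads the continuum speed; at 0.1 mm the
  # wave travels at the model's physical 0.4 mm/ms
  cv_fine <- measure_cv(strand_cv_sim(D = 0.07, dx = 0.1))
  cv_coarse <- measure_cv(strand_cv_sim(D = 0.07, dx = 0.33))
  expect_equal(cv_fine, 0.4, tolerance = 0.05)
  expect_lt(cv_coarse, cv_fine)
})
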