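# Trace analytics: spectra, recurrence maps, morphology rule and
# breakthrough detection on constructed inputs.

test_that("the periodogram finds pure and mixed tones", {
  dt <- 1
  tt <- seq(0, 3999, by = dt)
  x <- sin(2 * pi * 9 * tt / 1000)
  p <- psd(x, dt)
  expect_equal(dominant_frequency(p), 9, tolerance = 0.1)
  x2 <- x + 0.4 * sin(2 * pi * 4.5 * tt / 1000)
  p2 <- psd(x2, dt)
  expect_equal(dominant_frequency(p2), 9, tolerance = 0.1)
  pk <- attr(p2, "peaks")
  expect_true(any(abs(pk$freq_hz - 4.5) < 0.2))
  expect_warning(psd(x[1:1500], dt), "resolution")
})

test_that("cycle lengths come from interpolated threshold crossings", {
  dt <- 1
  tt <- seq(0, 2000, by = dt)
  # sawtooth-like AP train with a 106 ms period crossing -50 upward
  V <- -80 + 100 * (((tt / 106) %% 1) < 0.5)
  rec <- cycle_lengths(V, dt)
  cls <- attr(rec, "cycle_lengths")
  expect_true(all(abs(cls - 106) < 1.5))
  expect_equal(nrow(rec), length(cls) - 1)
  # alternans 90/130 forms two off-diagonal clusters
  ct <- cumsum(rep(c(90, 130), 8))
  Va <- rep(-80, 2200)
  for (t0 in ct) Va[t0:(t0 + 40)] <- 20
  reca <- cycle_lengths(Va, 1)
  cla <- attr(reca, "cycle_lengths")
  expect_equal(sort(unique(round(cla))), c(90, 130))
  expect_lt(stats::cor(cla[-length(cla)], cla[-1]), 0)
  expect_error(cycle_lengths(rep(-80, 1000), 1), "upstrokes")
})

test_that("morphology rule separates single-tone, harmonic and two-tone spectra", {
  dt <- 1
  tt <- seq(0, 3999, by = dt)
  mono <- psd(sin(2 * pi * 9 * tt / 1000), dt)
  expect_equal(classify_morphology(mono), "monomorphic")
  # strong non-harmonic secondary at 60 % relative power
  two <- psd(sin(2 * pi * 9 * tt / 1000) +
             sqrt(0.6) * sin(2 * pi * 5.2 * tt / 1000), dt)
  expect_equal(classify_morphology(two), "polymorphic")
  # a harmonic at 18 Hz does not count against monomorphy
  harm <- psd(sin(2 * pi * 9 * tt / 1000) +
              0.6 * sin(2 * pi * 18 * tt / 1000), dt)
  expect_equal(classify_morphology(harm), "monomorphic")
})

test_that("a radiating target pattern is a breakthrough; a planar sweep is not", {
  g <- geom_sheet(12, 12, 0.33)
  vx <- geom_voxels(g)
  centre <- c(5.94, 5.94)
  r <- sqrt((vx$x - centre[1])^2 + (vx$y - centre[2])^2)
  target <- tibble::tibble(voxel = seq_len(nrow(vx)), x = vx$x, y = vx$y,
                           z = vx$z, t_act = 100 + r / 0.4)
  ev <- detect_breakthrough(target, g)
  expect_equal(nrow(ev), 1)
  expect_lt(sqrt((ev$x - centre[1])^2 + (ev$y - centre[2])^2), 0.7)
  sweep <- tibble::tibble(voxel = seq_len(nrow(vx)), x = vx$x, y = vx$y,
                          z = vx$z, t_act = 100 + vx$x / 0.4)
  expect_equal(nrow(detect_breakthrough(sweep, g)), 0)
})

test_that("spectral and recurrence views of a periodic train agree", {
  dt <- 1
  tt <- seq(0, 3999, by = dt)
  per <- 110
  V <- -80 + 100 * (((tt / per) %% 1) < 0.4)
  p <- psd(V, dt)
  rec <- cycle_lengths(V, dt)
  f_rec <- 1000 / mean(attr(rec, "cycle_lengths"))
  expect_lt(abs(dominant_frequency(p) - f_rec) / f_rec, 0.05)
})
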