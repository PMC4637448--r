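# Filament extraction against analytic fields, tip selection, rotation
# averaging, drift classification and core-size estimation.

slab <- function() geom_ridge(10, 10, 3, 1, 0, 0.5)  # 21x21x6 slab

linear_fields <- function(g, x0, y0) {
  co <- geom_coords(g)
  list(V = -50 + (co[, "x"] - x0), oi = 0.5 + (co[, "y"] - y0))
}

test_that("the broken-line filament recovers an analytic straight line", {
  g <- slab()
  f <- linear_fields(g, 4.3, 5.1)
  fil <- extract_filament(f$V, f$oi, g)
  expect_gt(nrow(fil), 2)
  expect_equal(length(unique(fil$filament)), 1)
  # every vertex within one voxel of the true line x = 4.3, y = 5.1
  dev <- sqrt((fil$x - 4.3)^2 + (fil$y - 5.1)^2)
  expect_lt(max(dev), 0.5)
  # transmural: it spans the slab thickness
  expect_gt(diff(range(fil$z)), 3 - 2 * 0.5)
  # arc length no more than twice the wall thickness
  len <- sum(sqrt(diff(fil$x)^2 + diff(fil$y)^2 + diff(fil$z)^2))
  expect_lt(len, 2 * 3)

  # tips: the epicardial (bottom-face) endpoint only
  tp <- filament_tips(fil, g)
  expect_equal(nrow(tp), 1)
  expect_equal(c(tp$x, tp$y), c(4.3, 5.1), tolerance = 0.5)
  expect_lt(tp$z, 1)
})

test_that("no filament is reported when an isosurface is absent", {
  g <- slab()
  co <- geom_coords(g)
  fil <- extract_filament(rep(0, g$n_voxels), 0.5 + (co[, "y"] - 5), g)
  expect_equal(nrow(fil), 0)
  expect_equal(nrow(filament_tips(fil, g)), 0)
})

test_that("swapping the roles of the two fields leaves the line unchanged", {
  g <- slab()
  f <- linear_fields(g, 4.3, 5.1)
  fil1 <- extract_filament(f$V, f$oi, g)
  # express the same surfaces with the fields' roles exchanged
  fil2 <- extract_filament(-50 + (f$oi - 0.5), 0.5 + (f$V + 50), g)
  p1 <- fil1[order(fil1$z), c("x", "y", "z")]
  p2 <- fil2[order(fil2$z), c("x", "y", "z")]
  expect_equal(as.matrix(p1), as.matrix(p2), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("2D singularity points and their x-mirror behave consistently", {
  g <- geom_sheet(10, 10, 0.5)
  co <- geom_coords(g)
  V <- -50 + (co[, "x"] - 4.2)
  oi <- 0.5 + 0.3 * (co[, "y"] - 6.1)
  fil <- extract_filament(V, oi, g)
  expect_gt(nrow(fil), 0)
  expect_equal(mean(fil$x), 4.2, tolerance = 0.3)
  expect_equal(mean(fil$y), 6.1, tolerance = 0.3)
  # mirroring both fields in x mirrors the singularity
  n <- dim(g)[1]
  mirr <- function(v) {
    a <- field_array(v, g)[, , 1]
    (a[rev(seq_len(n)), ])[g$mask[, , 1]]
  }
  fil_m <- extract_filament(mirr(V), mirr(oi), g)
  Lx <- (n - 1) * 0.5
  expect_equal(mean(fil_m$x), Lx - 4.2, tolerance = 0.3)
  expect_equal(mean(fil_m$y), 6.1, tolerance = 0.3)
})

test_that("rotation period is recovered from synthetic circular tip motion", {
  tt <- seq(0, 1000, by = 10)
  f0 <- 1 / 106   # cycles per ms
  tips <- tibble::tibble(t_ms = tt,
                         x = 10 + 4 * cos(2 * pi * f0 * tt),
                         y = 10 + 4 * sin(2 * pi * f0 * tt),
                         z = 0)
  expect_equal(rotation_period(tips), 106, tolerance = 2)
  still <- tibble::tibble(t_ms = tt, x = 5, y = 5, z = 0)
  expect_error(rotation_period(still), "stationary")
})

test_that("rotation averaging collapses circles and preserves linear drift", {
  tt <- seq(0, 2000, by = 10)
  per <- 100
  circ <- tibble::tibble(t_ms = tt,
                         x = 10 + 4 * cos(2 * pi * tt / per),
                         y = 10 + 4 * sin(2 * pi * tt / per), z = 0)
  avg <- average_tip_trace(circ, per)
  d <- classify_drift(avg, discard = 0)
  expect_lt(d$displacement, 0.5)
  expect_equal(d$classification, "stationary")
  # a drifting rotor: same circle translating at 2 mm/s
  drift <- circ
  drift$x <- drift$x + 0.002 * tt
  avg_d <- average_tip_trace(drift, per)
  cls <- classify_drift(avg_d, discard = 0)
  expect_equal(cls$classification, "drifting")
  expect_equal(cls$rate, 2, tolerance = 0.15)
  expect_gt(cls$direction[1], 0.99)
  # single window degenerates to a single centroid
  one <- average_tip_trace(circ[circ$t_ms < per, ], per)
  expect_equal(nrow(one), 1)
})

test_that("drift threshold arithmetic matches the 10 mm per 40 s criterion", {
  # 0.5 mm/s for 40 s = 20 mm > 10 mm: drifting
  tt <- seq(0, 4000, by = 100)
  avg <- tibble::tibble(window = seq_along(tt) - 1, t_ms = tt,
                        x = 0.0005 * tt, y = 0, z = 0, n = 10)
  expect_equal(classify_drift(avg, discard = 0)$classification, "drifting")
  # a fixed point is stationary
  fixed <- tibble::tibble(window = 0:5, t_ms = 0:5 * 100, x = 3, y = 3,
                          z = 0, n = 10)
  expect_equal(classify_drift(fixed)$classification, "stationary")
  # large but erratic zig-zag motion is excluded, not called drift
  zig <- tibble::tibble(window = 0:8, t_ms = 0:8 * 500,
                        x = c(0, 4, -4, 4, -4, 4, -4, 4, 2), y = 0, z = 0,
                        n = 10)
  expect_equal(classify_drift(zig, discard = 0)$classification, "excluded")
})

test_that("core diameter is twice the RMS radius", {
  tt <- seq(0, 500, by = 10)
  tips <- tibble::tibble(t_ms = tt,
                         x = 4 * cos(2 * pi * tt / 100),
                         y = 4 * sin(2 * pi * tt / 100), z = 0)
  expect_equal(core_diameter(tips), 8, tolerance = 0.1)
  expect_equal(core_diameter(tibble::tibble(t_ms = 0, x = 1, y = 2, z = 3)), 0)
})
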