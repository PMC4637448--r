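#' Record one steady propagating cycle from a paced strand
#'
#' Implements the first half of the phase-distribution initiation
#' protocol: the cell model is paced rapidly to a steady oscillation, the
#' pacing is applied to one end of a 1D strand, and the full ionic state
#' at the strand midpoint is recorded over one steady propagating pulse.
#' The resulting cycle library is indexed by phase, with phase 0 aligned
#' to the upstroke (maximum dV/dt).
#'
#' @param params A [cell_params()] list (typically [af_params()]).
#' @param bcl Pacing cycle length (ms).
#' @param dx Grid spacing (mm).
#' @param dt Integration step (ms).
#' @param D Diffusion coefficient (mm^2/ms).
#' @param strand_length Strand length (mm).
#' @param n_beats Beats to pace; the second-to-last full cycle is
#'   recorded and steadiness is verified against the cycle before it.
#' @param dt_lib Sampling interval of the library (ms).
#' @param tol_apd Steadiness tolerance between consecutive mid-strand
#'   action potentials (ms).
#' @return A `cycle_library`: `states` (L x 21 matrix), `dt_lib`,
#'   `period` (= `bcl`), `cv` (measured solitary-train conduction
#'   velocity, mm/ms), and the generating parameters.
#' @export
record_cycle <- function(params = af_params(), bcl = 300, dx = 0.33,
                         dt = 0.01, D = 0.07, strand_length = 33,
                         n_beats = 8, dt_lib = 1, tol_apd = 1) {
  geom <- geom_strand(strand_length, dx)
  n <- geom$n_voxels
  mid <- as.integer(n %/% 2)           # 0-based middle node
  cfg <- solver_config(duration = bcl * n_beats, D = D, dt = dt,
                       record_interval = NA, probe_dt = NA_real_,
                       stim = list(sites = 1:3, amplitude = -2000,
                                   start = 0, period = bcl, duration = 2,
                                   n = n_beats),
                       record_activation = TRUE, act_max = n_beats + 2L,
                       state_probe = mid + 1L, state_probe_dt = dt_lib)
  cfg$probe_dt <- 0                    # no separate probes needed
  sim <- run_tissue(geom, uniform_state(geom), cfg, params)
  st <- sim$state_probe$states
  tt <- sim$state_probe$t
  cyc <- function(b) st[tt >= (b - 1) * bcl & tt < b * bcl, , drop = FALSE]
  a1 <- apd90(cyc(n_beats - 2)[, "V"], dt_lib)
  a2 <- apd90(cyc(n_beats - 1)[, "V"], dt_lib)
  if (!is.finite(a1) || !is.finite(a2) || abs(a1 - a2) >= tol_apd)
    abort("protocol failure: strand propagation not steady after pacing")
  lib <- cyc(n_beats - 1)
  # cyclic closure: one period later the state must have returned
  if (abs(lib[1, "V"] - cyc(n_beats)[1, "V"]) >= 2)
    warn("cycle library is not cyclically closed to within 2 mV")
  iup <- which.max(diff(lib[, "V"]))
  lib <- lib[c(iup:nrow(lib), seq_len(iup - 1)), , drop = FALSE]
  # conduction velocity from activation times at 25 % / 75 % of the strand
  q1 <- round(n * 0.25); q2 <- round(n * 0.75)
  k1 <- sim$activation$count[q1 + 1]; k2 <- sim$activation$count[q2 + 1]
  cv <- (q2 - q1) * dx /
    (sim$activation$times[q2 + 1, k2] - sim$activation$times[q1 + 1, k1])
  structure(
    list(states = lib, dt_lib = dt_lib, period = bcl, cv = cv,
         params = params, dx = dx, dt = dt),
    class = "cycle_library")
}

#' @export
print.cycle_library <- function(x, ...) {
  cat(sprintf(
    "<cycle_library> %d states over %g ms (dt %g ms), CV %.3f mm/ms, V in [%.1f, %.1f] mV\n",
    nrow(x$states), x$period, x$dt_lib, x$cv,
    min(x$states[, "V"]), max(x$states[, "V"])))
  invisible(x)
}

#' Spiral-wave initiation specification
#'
#' Describes where and with which rotation sense a spiral (2D) or scroll
#' (3D) wave is initiated by the phase-distribution method, and the pitch
#' of the Archimedean iso-phase lines.
#'
#' @param centre In-plane centre `c(x, y)` (mm) for flat geometries, or a
#'   3D point on the wall for curved ones.
#' @param chirality `"anticlockwise"` or `"clockwise"` (viewed from the
#'   +z / outward side).
#' @param lambda Pitch of the Archimedean phase lines (mm).  Defaults,
#'   when a library is supplied at application time, to the pulse
#'   wavelength CV x period.
#' @param frame Optional local frame for curved walls: list with
#'   `origin` (3D point) and orthonormal in-plane axes `e1`, `e2`.  The
#'   phase formula is applied in this tangent plane and extended along
#'   the normal (constant phase through the wall, giving an initially
#'   transmural filament).
#' @return A `spiral_spec`.
#' @export
spiral_spec <- function(centre, chirality = c("anticlockwise", "clockwise"),
                        lambda = NULL, frame = NULL) {
  chirality <- match.arg(chirality)
  if (!is.null(lambda) && lambda <= 0) abort("lambda must be > 0")
  structure(list(centre = centre, chirality = chirality, lambda = lambda,
                 frame = frame),
            class = "spiral_spec")
}

#' Archimedean phase map
#'
#' Phase in `[0, 1)` assigned to in-plane points:
#' `phi = frac(s * theta / (2 pi) + r / lambda)` with `theta` the polar
#' angle about the centre, `r` the planar radius, and `s = +1`
#' (anticlockwise) or `-1` (clockwise).  Iso-phase curves are Archimedean
#' spirals with pitch `lambda`; the phase winds exactly once around the
#' centre, which is the phase singularity seeding the rotor.
#'
#' @param x,y In-plane coordinates (mm); vectorised.
#' @param spec A [spiral_spec()] (the `lambda` field must be set).
#' @return Phase values in `[0, 1)`; the centre point maps to 0.
#' @export
archimedean_phase <- function(x, y, spec) {
  if (is.null(spec$lambda)) abort("spec$lambda must be set")
  # sign chosen so the label matches the observed rotation sense of the
  # resulting rotor viewed from the epicardial (+z / outward) side
  s <- if (spec$chirality == "anticlockwise") -1 else 1
  dxp <- x - spec$centre[1]
  dyp <- y - spec$centre[2]
  r <- sqrt(dxp^2 + dyp^2)
  th <- atan2(dyp, dxp)
  phi <- (s * th / (2 * pi) + r / spec$lambda) %% 1
  phi[r == 0] <- 0
  phi
}

#' Initiate a scroll wave by phase distribution
#'
#' Assigns to each tissue voxel the library state at its Archimedean
#' phase: voxel with phase `phi` receives library sample
#' `round(phi * L) mod L`.  For flat walls the phase is computed from the
#' in-plane (x, y) coordinates and is constant through the wall
#' thickness; for curved walls the coordinates are projections onto the
#' tangent plane at the chosen centre.
#'
#' @param geom A [voxel_geometry].
#' @param lib A `cycle_library` from [record_cycle()].
#' @param spec A [spiral_spec()].
#' @return A `field_state` ready for [run_tissue()].
#' @export
apply_phase_distribution <- function(geom, lib, spec) {
  if (is.null(spec$lambda)) spec$lambda <- lib$cv * lib$period
  co <- geom_coords(geom)
  if (!is.null(spec$frame)) {
    f <- spec$frame
    d <- sweep(co, 2, f$origin)
    u <- as.numeric(d %*% f$e1)
    v <- as.numeric(d %*% f$e2)
    spec2 <- spec; spec2$centre <- c(0, 0)
    phi <- archimedean_phase(u, v, spec2)
  } else {
    phi <- archimedean_phase(co[, 1], co[, 2], spec)
  }
  L <- nrow(lib$states)
  ki <- (round(phi * L) %% L) + 1L
  as_field_state(lib$states[ki, , drop = FALSE], geom)
}

#' Tangent frame on a spherical wall
#'
#' Convenience for the hemispherical geometries: builds the local frame
#' (origin on the wall, two tangent axes) at a point given by its radial
#' direction.
#'
#' @param direction 3D direction from the sphere centre (need not be
#'   normalised).
#' @param radius Radius at which to place the frame origin (mm), e.g. the
#'   mid-wall radius.
#' @param centre Sphere centre (mm).
#' @return A frame list suitable for [spiral_spec()].
#' @export
sphere_frame <- function(direction, radius = 13.5, centre = c(0, 0, 0)) {
  n <- direction / sqrt(sum(direction^2))
  origin <- centre + radius * n
  a <- if (abs(n[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- a - sum(a * n) * n
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  list(origin = origin, e1 = e1, e2 = e2, normal = n)
}
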