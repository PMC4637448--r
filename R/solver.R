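#' Solver configuration
#'
#' Collects the monodomain integration parameters.  The explicit scheme
#' requires `dt <= dx^2 / (6 D)`; with the default grid (dx 0.33 mm,
#' D 0.07 mm^2/ms) the bound is about 0.26 ms, far above the default
#' 0.01 ms step.
#'
#' @param duration Simulated time (ms).
#' @param D Diffusion coefficient (mm^2/ms).
#' @param dt Time step (ms).
#' @param record_interval Snapshot interval for the 3D V and oi fields
#'   (ms); `NA` disables snapshots.
#' @param probes Probe locations: matrix/list of mm coordinates, or a
#'   vector of compact voxel indices.
#' @param probe_dt Probe sampling interval (ms).
#' @param stim `NULL` or a list with `sites` (compact voxel indices or a
#'   matrix of mm coordinates), `amplitude` (pA, negative =
#'   depolarising), `start`, `duration`, `period`, `n` (pulse count).
#' @param record_activation Record upward threshold-crossing times per
#'   voxel (needed for conduction velocity and breakthrough analysis).
#' @param act_threshold Activation threshold (mV).
#' @param act_max Maximum crossings stored per voxel.
#' @param state_probe Voxel (compact index or mm coords) at which the full
#'   21-variable state is recorded, or `NULL`.
#' @param state_probe_dt Sampling interval of the state probe (ms).
#' @param nernst_every Steps between refreshes of the cached Nernst
#'   potentials (concentrations move slowly; 10 steps = 0.1 ms).
#' @return A `solver_config` list.
#' @export
solver_config <- function(duration, D = 0.07, dt = 0.01,
                          record_interval = 10, probes = NULL, probe_dt = 1,
                          stim = NULL, record_activation = FALSE,
                          act_threshold = -50, act_max = 64L,
                          state_probe = NULL, state_probe_dt = 1,
                          nernst_every = 10L) {
  if (duration < 0) abort("duration must be >= 0")
  if (dt <= 0) abort("dt must be > 0")
  structure(
    list(duration = duration, D = D, dt = dt,
         record_interval = record_interval, probes = probes,
         probe_dt = probe_dt, stim = stim,
         record_activation = record_activation,
         act_threshold = act_threshold, act_max = as.integer(act_max),
         state_probe = state_probe, state_probe_dt = state_probe_dt,
         nernst_every = as.integer(nernst_every)),
    class = "solver_config")
}

check_stability <- function(cfg, dx) {
  bound <- dx^2 / (6 * cfg$D)
  if (cfg$D > 0 && cfg$dt > bound)
    abort(sprintf(
      "unstable configuration: dt = %g ms exceeds dx^2/(6D) = %.3g ms",
      cfg$dt, bound))
  invisible(TRUE)
}

#' No-flux Laplacian stencil weights
#'
#' Builds the 7-point method-of-weights stencil on a voxel geometry: each
#' tissue neighbour contributes `1/dx^2`, absent neighbours contribute
#' nothing, and the centre weight is minus the sum of its neighbour
#' weights, so every stencil row sums to zero (discrete no-flux
#' conservation).
#'
#' @param geom A [voxel_geometry].
#' @return A `laplacian_weights` list with the neighbour index matrix,
#'   per-voxel neighbour count, and `dx`.
#' @export
build_weights <- function(geom) {
  nbr <- voxel_neighbours(geom)
  structure(
    list(nbr = nbr, n_neighbours = rowSums(nbr >= 0), dx = geom$dx,
         n = nrow(nbr)),
    class = "laplacian_weights")
}

#' @export
print.laplacian_weights <- function(x, ...) {
  cat(sprintf("<laplacian_weights> %d voxels, dx %g mm; neighbour counts: %s\n",
              x$n, x$dx,
              paste(names(table(x$n_neighbours)), collapse = "/")))
  invisible(x)
}

#' Apply the discrete Laplacian
#'
#' @param V Voltage field: compact vector (one value per tissue voxel).
#' @param W A `laplacian_weights` object from [build_weights()].
#' @return Compact vector of the weighted 7-point stencil, mV/mm^2.
#' @export
laplacian <- function(V, W) {
  if (length(V) != W$n) abort("field length does not match geometry")
  acc <- -W$n_neighbours * V
  for (s in 1:6) {
    q <- W$nbr[, s]
    has <- q >= 0
    acc[has] <- acc[has] + V[q[has] + 1]
  }
  acc / W$dx^2
}

#' Uniform field state
#'
#' Replicates one cell state over every tissue voxel of a geometry.
#'
#' @param geom A [voxel_geometry].
#' @param state A `cell_state` (defaults to the control resting state).
#' @return A `field_state` matrix (N x 21) with the geometry attached.
#' @export
uniform_state <- function(geom, state = cell_state_rest()) {
  m <- matrix(as.numeric(state), geom$n_voxels, 21, byrow = TRUE)
  colnames(m) <- CRN_STATE_NAMES
  structure(m, geometry = geom, class = c("field_state", "matrix", "array"))
}

as_field_state <- function(m, geom) {
  colnames(m) <- CRN_STATE_NAMES
  structure(m, geometry = geom, class = c("field_state", "matrix", "array"))
}

#' @export
print.field_state <- function(x, ...) {
  g <- attr(x, "geometry")
  cat(sprintf("<field_state> %d voxels ('%s'), V in [%.1f, %.1f] mV\n",
              nrow(x), g$name, min(x[, "V"]), max(x[, "V"])))
  invisible(x)
}

#' Scatter a compact field into a 3D array
#'
#' @param v Compact per-voxel vector.
#' @param geom A [voxel_geometry].
#' @return 3D array with `NA` outside the tissue.
#' @export
field_array <- function(v, geom) {
  a <- array(NA_real_, dim(geom$mask))
  a[geom$mask] <- v
  a
}

resolve_sites <- function(geom, sites) {
  if (is.null(sites)) return(integer(0))
  if (is.matrix(sites))
    return(vapply(seq_len(nrow(sites)),
                  function(r) nearest_voxel(geom, sites[r, ]), 1L))
  if (is.list(sites))
    return(vapply(sites, function(p) {
      if (length(p) >= 2) nearest_voxel(geom, p) else as.integer(p)
    }, 1L))
  as.integer(sites)
}

#' Advance a tissue state by one time step
#'
#' Single explicit step of the monodomain equation: reaction (Rush-Larsen
#' gates, Euler voltage and concentrations) plus `D` times the no-flux
#' Laplacian of V.  Diffusion acts on the membrane potential only.
#'
#' @param state A `field_state`.
#' @param W Stencil weights from [build_weights()] (must match the
#'   state's geometry).
#' @param cfg A [solver_config()].
#' @param params A [cell_params()] list.
#' @return Updated `field_state`.
#' @export
step_tissue <- function(state, W, cfg, params = cell_params()) {
  geom <- attr(state, "geometry")
  check_stability(cfg, geom$dx)
  r <- sim_run_cpp(unclass(state), W$nbr, geom$dx, cfg$D, cfg$dt, cfg$dt,
                   unclass(params), integer(0), 0, 0, 0, 0, 0L,
                   integer(0), 0, -1L, 0, 0, FALSE, FALSE,
                   cfg$act_threshold, 0L, 1L)
  as_field_state(r$final_state, geom)
}

#' Run a monodomain tissue simulation
#'
#' Integrates the monodomain reaction-diffusion equation on a voxel
#' geometry with no-flux boundaries, recording 3D voltage and oi-gate
#' snapshots at `record_interval`, probe action potentials at
#' `probe_dt`, and (optionally) per-voxel activation times.  The run is
#' deterministic: identical inputs give identical outputs.
#'
#' @param geom A [voxel_geometry].
#' @param init A `field_state` (e.g. from [uniform_state()] or
#'   [apply_phase_distribution()]).
#' @param cfg A [solver_config()].
#' @param params A [cell_params()] list.
#' @return A `sim_result` list: `snap_t`, `snap_V`, `snap_oi` (snapshot
#'   times and N x n matrix stacks), `probes` (tibble `t_ms`, `probe`,
#'   `V_mV`), `activation` (matrix of crossing times), `final_state`,
#'   plus the inputs and wall-clock `elapsed`.
#' @export
run_tissue <- function(geom, init, cfg, params = cell_params()) {
  stopifnot(inherits(geom, "voxel_geometry"), inherits(cfg, "solver_config"))
  if (nrow(init) != geom$n_voxels) abort("initial state does not match geometry")
  check_stability(cfg, geom$dx)
  W <- build_weights(geom)
  probe_idx <- resolve_sites(geom, cfg$probes)
  sprobe_idx <- if (is.null(cfg$state_probe)) -1L else
    resolve_sites(geom, list(cfg$state_probe))[1] - 1L
  stim <- cfg$stim
  stim_idx <- if (is.null(stim)) integer(0) else resolve_sites(geom, stim$sites)
  rec_snap <- !is.na(cfg$record_interval) && cfg$record_interval > 0
  t0 <- proc.time()[3]
  r <- sim_run_cpp(unclass(init), W$nbr, geom$dx, cfg$D, cfg$dt, cfg$duration,
                   unclass(params),
                   stim_idx - 1L,
                   if (is.null(stim)) 0 else stim$amplitude,
                   if (is.null(stim)) 0 else stim$start %||% 0,
                   if (is.null(stim)) 0 else stim$period %||% 0,
                   if (is.null(stim)) 0 else stim$duration %||% 2,
                   if (is.null(stim)) 0L else as.integer(stim$n %||% 1),
                   probe_idx - 1L, cfg$probe_dt,
                   sprobe_idx, cfg$state_probe_dt,
                   if (rec_snap) cfg$record_interval else 0,
                   rec_snap, cfg$record_activation, cfg$act_threshold,
                   cfg$act_max, cfg$nernst_every)
  elapsed <- proc.time()[3] - t0
  probes <- if (length(probe_idx)) {
    np <- length(probe_idx)
    tibble(t_ms = rep(r$probe_t, np),
           probe = rep(seq_len(np), each = length(r$probe_t)),
           V_mV = as.numeric(r$probe_V))
  } else tibble(t_ms = numeric(0), probe = integer(0), V_mV = numeric(0))
  structure(
    list(geom = geom, cfg = cfg, params = params,
         snap_t = if (rec_snap) r$snap_t else numeric(0),
         snap_V = if (rec_snap) r$snap_V else NULL,
         snap_oi = if (rec_snap) r$snap_oi else NULL,
         probes = probes,
         state_probe = if (sprobe_idx >= 0) {
           m <- r$state_probe; colnames(m) <- CRN_STATE_NAMES
           list(t = r$state_probe_t, states = m)
         } else NULL,
         activation = if (cfg$record_activation)
           list(times = r$act_times, count = r$act_count) else NULL,
         final_state = as_field_state(r$final_state, geom),
         elapsed = elapsed),
    class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(
    "<sim_result> '%s', %g ms simulated (dt %g ms), %d snapshots, %d probes [%.1f s]\n",
    x$geom$name, x$cfg$duration, x$cfg$dt, length(x$snap_t),
    length(unique(x$probes$probe)), x$elapsed))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Probe trace of a simulation
#'
#' @param sim A `sim_result`.
#' @param probe Probe number.
#' @return Tibble with `t_ms` and `V_mV`.
#' @export
probe_trace <- function(sim, probe = 1) {
  out <- dplyr::filter(sim$probes, .data$probe == !!probe)
  if (!nrow(out)) abort("no such probe")
  out[, c("t_ms", "V_mV")]
}
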