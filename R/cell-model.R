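#' Ionic model parameters
#'
#' Parameter set for the Courtemanche-Ramirez-Nattel (CRN) human atrial
#' myocyte with optional atrial-fibrillation electrical remodelling and an
#' acetylcholine-activated potassium current (IKACh).  With all scale
#' factors at 1 and `ach = 0` this is the published control model.
#'
#' The remodelled variant ([af_params()]) reduces the L-type calcium
#' conductance to 35 % of control, increases the rapid and slow
#' delayed-rectifier potassium conductances ninefold, and adds IKACh at an
#' acetylcholine concentration of 0.0035 umol/L.
#'
#' @param scale_gCaL L-type Ca2+ conductance scale (dimensionless, > 0).
#' @param scale_gKr Rapid delayed-rectifier K+ conductance scale (> 0).
#' @param scale_gKs Slow delayed-rectifier K+ conductance scale (> 0).
#' @param ach Acetylcholine concentration (umol/L, >= 0); 0 disables IKACh.
#' @param ach_exponent Exponent on `ach` in the IKACh activation term.  The
#'   published constant family uses 0.477; exposed because typeset sources
#'   disagree on the final digit.
#' @param cach_offset,cach_amp Offset and amplitude of the
#'   voltage-dependent IKACh term (dimensionless).
#' @param Cm Cell capacitance (pF).
#' @return A `crn_params` list.
#' @seealso [af_params()], [total_current()], [step_cell()]
#' @export
#' @examples
#' cell_params()          # control CRN
#' af_params()            # AF-remodelled variant with IKACh
cell_params <- function(scale_gCaL = 1, scale_gKr = 1, scale_gKs = 1,
                        ach = 0, ach_exponent = 0.477,
                        cach_offset = 0.052, cach_amp = 0.45, Cm = 100) {
  if (any(c(scale_gCaL, scale_gKr, scale_gKs) <= 0))
    abort("conductance scale factors must be > 0")
  if (ach < 0) abort("ach must be >= 0")
  if (Cm <= 0) abort("Cm must be > 0")
  structure(
    list(scale_gCaL = scale_gCaL, scale_gKr = scale_gKr,
         scale_gKs = scale_gKs, ach = ach, ach_exponent = ach_exponent,
         cach_offset = cach_offset, cach_amp = cach_amp, Cm = Cm),
    class = "crn_params")
}

#' @rdname cell_params
#' @export
af_params <- function(ach = 0.0035) {
  cell_params(scale_gCaL = 0.35, scale_gKr = 9, scale_gKs = 9, ach = ach)
}

#' @export
print.crn_params <- function(x, ...) {
  kind <- if (x$scale_gCaL == 1 && x$scale_gKr == 1 && x$scale_gKs == 1 &&
              x$ach == 0) "control" else "modified"
  cat("<crn_params> (", kind, ")\n", sep = "")
  cat(sprintf("  gCaL x%g, gKr x%g, gKs x%g, [ACh] %g umol/L, Cm %g pF\n",
              x$scale_gCaL, x$scale_gKr, x$scale_gKs, x$ach, x$Cm))
  invisible(x)
}

#' Resting state of the control CRN cell
#'
#' Full 21-variable state (membrane potential, 15 gates, 5 intracellular
#' concentrations) at the published resting steady state.
#'
#' @return Named numeric vector of length 21, class `cell_state`.
#' @export
cell_state_rest <- function() {
  s <- crn_rest_state_cpp()
  class(s) <- "cell_state"
  s
}

#' @export
print.cell_state <- function(x, ...) {
  cat("<cell_state> V =", format(x[["V"]], digits = 4), "mV\n")
  print(unclass(x), ...)
  invisible(x)
}

validate_cell_state <- function(state) {
  if (length(state) != 21L) abort("cell state must have 21 variables")
  g <- state[CRN_GATE_NAMES]
  if (any(g < -1e-12 | g > 1 + 1e-12))
    abort("gate variables must lie in [0, 1]")
  if (any(state[CRN_CONC_NAMES] <= 0))
    abort("ionic concentrations must be positive")
  invisible(TRUE)
}

#' Acetylcholine-dependent activation of IKACh
#'
#' `O_Ach = 10 / (1 + 9.13 / ach^exponent)`, the ligand-gated activation
#' term of the acetylcholine-activated potassium current.  Monotone
#' increasing in `ach`; 0 at `ach = 0` (limit convention) and saturating
#' at 10.
#'
#' @param ach Acetylcholine concentration (umol/L, >= 0); vectorised.
#' @param exponent Exponent on `ach` (default 0.477).
#' @return Dimensionless activation in `[0, 10)`.
#' @export
#' @examples
#' ikach_open(0.0035)   # ~0.073 at the default AF concentration
ikach_open <- function(ach, exponent = 0.477) {
  if (any(ach < 0)) abort("ach must be >= 0")
  ifelse(ach == 0, 0, 10 / (1 + 9.13 / ach^exponent))
}

#' Voltage-dependent term of IKACh
#'
#' `C_Ach = 0.052 + 0.45 / (1 + exp((V + 59.53) / 17.18))`; monotone
#' decreasing in V with range (0.052, 0.502).
#'
#' @param V Membrane potential (mV); vectorised.
#' @param offset,amp Curve offset and amplitude.
#' @return Dimensionless value in `(offset, offset + amp)`.
#' @export
ikach_voltage <- function(V, offset = 0.052, amp = 0.45) {
  if (any(!is.finite(V))) abort("V must be finite")
  offset + amp / (1 + exp((V + 59.53) / 17.18))
}

#' Acetylcholine-activated potassium current
#'
#' `I_KACh = Cm * O_Ach * C_Ach * (V - E_K)` in pA, with `E_K` the Nernst
#' potassium reversal potential computed from the cell's K+ concentrations
#' (extracellular K+ fixed at the CRN value of 5.4 mM).
#'
#' @param state A `cell_state` vector.
#' @param params A `crn_params` list.
#' @return Current in pA (positive = outward).
#' @export
ikach_current <- function(state, params = cell_params()) {
  validate_cell_state(state)
  e_k <- 26.712338 * log(5.4 / state[["K_i"]])
  o <- ikach_open(params$ach, params$ach_exponent)
  c_v <- ikach_voltage(state[["V"]], params$cach_offset, params$cach_amp)
  unname(params$Cm * o * c_v * (state[["V"]] - e_k))
}

#' All CRN membrane currents at one state
#'
#' Evaluates every membrane current of the (possibly remodelled) CRN model
#' at the given state, by direct scalar evaluation of the published rate
#' expressions.  This is the reference path against which the integrator's
#' tabulated path is checked.
#'
#' @inheritParams ikach_current
#' @return A tibble with columns `current` and `pA`.
#' @export
crn_currents <- function(state, params = cell_params()) {
  validate_cell_state(state)
  cur <- crn_currents_cpp(as.numeric(state), unclass(params))
  if (any(!is.finite(cur))) {
    bad <- names(cur)[!is.finite(cur)]
    abort(paste0("numerical failure evaluating current(s): ",
                 paste(bad, collapse = ", ")))
  }
  tibble(current = names(cur), pA = as.numeric(cur))
}

#' Total membrane current
#'
#' Sum of all CRN membrane currents (including IKACh) in pA at the given
#' state; positive values are outward (repolarising).
#'
#' @inheritParams ikach_current
#' @return Total ionic current in pA.
#' @export
total_current <- function(state, params = cell_params()) {
  sum(crn_currents(state, params)$pA)
}

#' Advance a single cell by one or more time steps
#'
#' Rush-Larsen update for gating variables and forward Euler for membrane
#' potential and concentrations, the same scheme the tissue solver uses.
#'
#' @param state A `cell_state` vector.
#' @param params A `crn_params` list.
#' @param dt Time step (ms, default 0.01).
#' @param I_stim Stimulus current (pA; negative = depolarising) applied
#'   throughout.
#' @param n_steps Number of steps to take.
#' @return Updated `cell_state`.
#' @export
step_cell <- function(state, params = cell_params(), dt = 0.01, I_stim = 0,
                      n_steps = 1L) {
  validate_cell_state(state)
  if (dt <= 0) abort("dt must be > 0")
  r <- sim_run_cpp(matrix(as.numeric(state), nrow = 1), matrix(-1L, 1, 6),
                   1.0, 0.0, dt, dt * n_steps, unclass(params),
                   if (I_stim != 0) 0L else integer(0), I_stim, 0,
                   0, dt * n_steps + 1, 1L,
                   integer(0), 0, -1L, 0, 0, FALSE, FALSE, -50, 0L, 1L)
  out <- r$final_state[1, ]
  names(out) <- CRN_STATE_NAMES
  g <- out[CRN_GATE_NAMES]
  if (any(!is.finite(out)) || any(g < -1e-12 | g > 1 + 1e-12))
    abort("integration failure: state invariant violated after step")
  class(out) <- "cell_state"
  out
}

#' Pace a single cell to steady state
#'
#' Applies a periodic stimulus train and returns the final beat once the
#' action-potential duration has converged (APD90 change < `tol_apd` ms
#' between consecutive beats).  The protocol used to obtain the steady
#' oscillation that seeds the phase-distribution initiation.
#'
#' @param params A `crn_params` list.
#' @param bcl Basic cycle length (ms).  Must exceed the expected APD.
#' @param n_beats Number of beats to simulate (>= 2 for the convergence
#'   check; the last beat is returned).
#' @param dt Integration step (ms).
#' @param stim_amp Stimulus amplitude (pA, negative = depolarising).
#' @param stim_dur Stimulus duration (ms).
#' @param dt_sample Sampling interval of the returned traces (ms).
#' @param tol_apd Steadiness tolerance on APD90 (ms).
#' @return A `paced_cell` list: `trace` (tibble `t_ms`, `V_mV` over the
#'   final beat), `states` (matrix of all 21 variables over the final
#'   beat, sampled at `dt_sample`), `final_state`, `apd90`, and
#'   `steady` (logical).
#' @export
pace_to_steady <- function(params = cell_params(), bcl = 1000, n_beats = 20,
                           dt = 0.01, stim_amp = -2000, stim_dur = 2,
                           dt_sample = 0.1, tol_apd = 1) {
  if (n_beats < 1) abort("n_beats must be >= 1")
  if (bcl <= 0) abort("bcl must be > 0")
  rest <- cell_state_rest()
  r <- sim_run_cpp(matrix(as.numeric(rest), nrow = 1), matrix(-1L, 1, 6),
                   1.0, 0.0, dt, bcl * n_beats, unclass(params),
                   0L, stim_amp, 0, bcl, stim_dur, as.integer(n_beats),
                   0L, dt_sample, 0L, dt_sample, 0, FALSE, FALSE, -50, 0L, 1L)
  tt <- r$probe_t
  V <- r$probe_V[, 1]
  beat_apd <- function(b) {
    sel <- tt >= (b - 1) * bcl & tt < b * bcl
    tryCatch(apd90(V[sel], dt_sample), error = function(e) NA_real_)
  }
  sel_last <- tt >= (n_beats - 1) * bcl
  if (max(V[sel_last]) < 0)
    abort("stimulus failure: no action potential elicited on the final beat")
  a_last <- beat_apd(n_beats)
  steady <- if (n_beats >= 2) {
    a_prev <- beat_apd(n_beats - 1)
    is.finite(a_last) && is.finite(a_prev) && abs(a_last - a_prev) < tol_apd
  } else TRUE
  states <- r$state_probe[r$state_probe_t >= (n_beats - 1) * bcl, , drop = FALSE]
  colnames(states) <- CRN_STATE_NAMES
  fin <- r$final_state[1, ]
  names(fin) <- CRN_STATE_NAMES
  class(fin) <- "cell_state"
  structure(
    list(trace = tibble(t_ms = tt[sel_last] - (n_beats - 1) * bcl,
                        V_mV = V[sel_last]),
         states = states, final_state = fin, apd90 = a_last,
         steady = steady, bcl = bcl, params = params,
         dt = dt, dt_sample = dt_sample),
    class = "paced_cell")
}

#' @export
print.paced_cell <- function(x, ...) {
  cat(sprintf("<paced_cell> bcl %g ms, APD90 %.1f ms, %s\n", x$bcl, x$apd90,
              if (x$steady) "steady" else "NOT steady"))
  invisible(x)
}

#' Action-potential duration at 90 % repolarisation
#'
#' Time from the point of maximum upstroke velocity to 90 % repolarisation
#' of the peak-to-baseline amplitude, with linear interpolation at the
#' crossing.  The baseline is the minimum potential before the upstroke.
#'
#' @param V Membrane-potential trace (mV) containing one action potential.
#' @param dt_sample Sampling interval of the trace (ms).
#' @return APD90 in ms.
#' @export
apd90 <- function(V, dt_sample) {
  if (length(V) < 3) abort("trace too short")
  if (diff(range(V)) < 5)
    abort("no upstroke found: trace is essentially flat")
  dv <- diff(V)
  iup <- which.max(dv)
  peak <- max(V[iup:length(V)])
  base <- min(V[seq_len(iup)])
  if (peak - base < 20) abort("no upstroke found")
  v90 <- peak - 0.9 * (peak - base)
  after <- V[(iup + 1):length(V)]
  below <- which(after <= v90)
  # crossing must occur after the peak
  ipk <- which.max(after)
  below <- below[below >= ipk]
  if (!length(below)) abort("trace ends before 90 % repolarisation")
  ir <- below[1] + iup
  frac <- (V[ir - 1] - v90) / (V[ir - 1] - V[ir])
  ((ir - 1 + frac) - iup) * dt_sample
}
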