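#' Power density spectrum of an action-potential trace
#'
#' Single-taper periodogram of the mean-removed trace, zero-padded to the
#' next power of two (at least fourfold) so peak positions are resolved
#' beyond the raw bin width.  The dominant frequency is the global power
#' maximum above 0.5 Hz; secondary peaks are local maxima separated from
#' stronger ones by at least `min_sep` Hz.
#'
#' @param V Voltage trace (mV), uniformly sampled.
#' @param dt_sample Sampling interval (ms).
#' @param min_sep Minimum separation between reported peaks (Hz).
#' @return A `psd_result`: tibble `freq_hz`, `power` with attributes
#'   `dominant_hz`, `peaks` (tibble `freq_hz`, `rel_power`) and
#'   `resolution_hz` (raw, pre-padding).
#' @export
psd <- function(V, dt_sample = 1, min_sep = 0.5) {
  n <- length(V)
  span_s <- n * dt_sample / 1000
  if (span_s < 2)
    warn(sprintf("trace is %.2f s long; frequency resolution %.2f Hz",
                 span_s, 1 / span_s))
  x <- V - mean(V)
  n2 <- 2^ceiling(log2(n * 4))
  P <- Mod(fft(c(x, rep(0, n2 - n))))^2 / n
  nf <- n2 %/% 2 + 1
  fr <- (seq_len(nf) - 1) / (n2 * dt_sample / 1000)   # Hz
  Pp <- P[seq_len(nf)]
  sel <- fr > 0.5
  dom <- fr[sel][which.max(Pp[sel])]
  pmax_ <- max(Pp[sel])
  # local maxima, greedily thinned by separation
  i <- which(sel)[-c(1, sum(sel))]
  loc <- i[Pp[i] > Pp[i - 1] & Pp[i] >= Pp[i + 1]]
  loc <- loc[order(Pp[loc], decreasing = TRUE)]
  keep <- integer(0)
  for (q in loc) {
    if (!length(keep) || all(abs(fr[q] - fr[keep]) >= min_sep))
      keep <- c(keep, q)
  }
  peaks <- tibble(freq_hz = fr[keep], rel_power = Pp[keep] / pmax_)
  out <- tibble(freq_hz = fr, power = Pp)
  attr(out, "dominant_hz") <- dom
  attr(out, "peaks") <- peaks
  attr(out, "resolution_hz") <- 1 / span_s
  class(out) <- c("psd_result", class(out))
  out
}

#' Dominant frequency of a PSD
#'
#' @param p A `psd_result`.
#' @return Frequency (Hz) of the global power maximum above 0.5 Hz.
#' @export
dominant_frequency <- function(p) attr(p, "dominant_hz")

#' Cycle lengths and recurrence map
#'
#' Detects successive upward crossings of `threshold` (with linear
#' interpolation) and returns the consecutive cycle lengths together
#' with the recurrence point set (CL_n, CL_{n+1}) used to judge whether
#' an arrhythmia is monomorphic (a single tight cluster) or polymorphic.
#'
#' @param V Voltage trace (mV), uniformly sampled.
#' @param dt_sample Sampling interval (ms).
#' @param threshold Crossing threshold (mV).
#' @return A `recurrence_map`: tibble `cl_ms`, `cl_next_ms` with
#'   attribute `cycle_lengths` (all CLs, ms).
#' @export
cycle_lengths <- function(V, dt_sample = 1, threshold = -50) {
  n <- length(V)
  up <- which(V[-n] < threshold & V[-1] >= threshold)
  if (length(up) < 3)
    abort("fewer than 3 upstrokes: cannot build a recurrence map")
  frac <- (threshold - V[up]) / (V[up + 1] - V[up])
  t_cross <- (up - 1 + frac) * dt_sample
  cls <- diff(t_cross)
  out <- tibble(cl_ms = cls[-length(cls)], cl_next_ms = cls[-1])
  attr(out, "cycle_lengths") <- cls
  class(out) <- c("recurrence_map", class(out))
  out
}

#' Morphology classification from a PSD
#'
#' Polymorphic iff at least two spectral peaks that are not harmonics of
#' the dominant frequency carry at least `rel_threshold` of the dominant
#' peak's power (the dominant peak itself counts as the first).
#'
#' @param p A `psd_result`.
#' @param rel_threshold Relative-power threshold.
#' @param harmonic_tol Distance (Hz) within which a peak counts as a
#'   harmonic k * f_dom (k >= 2).
#' @return `"monomorphic"` or `"polymorphic"`.
#' @export
classify_morphology <- function(p, rel_threshold = 0.2, harmonic_tol = 0.4) {
  dom <- attr(p, "dominant_hz")
  pk <- attr(p, "peaks")
  pk <- pk[pk$rel_power >= rel_threshold, , drop = FALSE]
  is_harm <- vapply(pk$freq_hz, function(f) {
    k <- round(f / dom)
    k >= 2 && abs(f - k * dom) <= harmonic_tol
  }, TRUE)
  if (sum(!is_harm) >= 2) "polymorphic" else "monomorphic"
}

#' Conduction velocity on a strand
#'
#' Activation time (first upward crossing of the threshold) is read at
#' 25 % and 75 % of the strand length; CV is distance over time
#' difference.
#'
#' @param sim A `sim_result` of a strand run with
#'   `record_activation = TRUE`.
#' @param fractions Measurement positions as fractions of strand length.
#' @return Conduction velocity (mm/ms).
#' @export
measure_cv <- function(sim, fractions = c(0.25, 0.75)) {
  if (is.null(sim$activation)) abort("run with record_activation = TRUE")
  n <- sim$geom$n_voxels
  i1 <- round(n * fractions[1]); i2 <- round(n * fractions[2])
  c1 <- sim$activation$count[i1 + 1]; c2 <- sim$activation$count[i2 + 1]
  if (c1 < 1 || c2 < 1) abort("wave failed to traverse the strand")
  t1 <- sim$activation$times[i1 + 1, 1]
  t2 <- sim$activation$times[i2 + 1, 1]
  if (abs(t2 - t1) < 1e-9) abort("zero activation-time interval")
  (i2 - i1) * sim$geom$dx / (t2 - t1)
}

#' Epicardial activation map for one cycle
#'
#' First upward-crossing time of each epicardial voxel within a time
#' window, from the solver's activation record.
#'
#' @param sim A `sim_result` with `record_activation = TRUE`.
#' @param window `c(t0, t1)` in ms.
#' @return Tibble `voxel`, `x`, `y`, `z`, `t_act` (NA if the voxel did
#'   not activate in the window), epicardial voxels only.
#' @export
activation_map <- function(sim, window) {
  if (is.null(sim$activation)) abort("run with record_activation = TRUE")
  geom <- sim$geom
  vx <- geom_voxels(geom)
  at <- sim$activation$times
  cnt <- sim$activation$count
  t_act <- vapply(seq_len(nrow(at)), function(i) {
    if (cnt[i] == 0) return(NA_real_)
    ts <- at[i, seq_len(cnt[i])]
    ts <- ts[ts >= window[1] & ts < window[2]]
    if (length(ts)) ts[1] else NA_real_
  }, 1)
  out <- tibble(voxel = seq_len(nrow(vx)), x = vx$x, y = vx$y, z = vx$z,
                t_act = t_act, epi = vx$epi)
  out[out$epi, c("voxel", "x", "y", "z", "t_act")]
}

#' Detect epicardial breakthrough events
#'
#' A breakthrough is excitation surfacing as a point source: a local
#' minimum of the epicardial activation-time map whose surrounding ring
#' (radius `ring_radius`) activates at least `ring_delay` ms later, and
#' which is not fed by a front entering from the border of the map
#' (i.e. not connected to the border through voxels activated within
#' `connect_tol` ms of the event).
#'
#' @param act Activation map from [activation_map()].
#' @param geom The [voxel_geometry].
#' @param ring_radius Ring radius (mm).
#' @param ring_delay Minimum ring delay (ms).
#' @param connect_tol Connection tolerance (ms) for the border test.
#' @return Tibble of events: `x`, `y`, `z`, `t_act`,
#'   `junction_distance` (mm to the nearest junction-labelled voxel;
#'   `NA` if the geometry has none).
#' @export
detect_breakthrough <- function(act, geom, ring_radius = 2, ring_delay = 2,
                                connect_tol = 2) {
  a <- act[is.finite(act$t_act), , drop = FALSE]
  if (nrow(a) < 10)
    return(tibble(x = numeric(0), y = numeric(0), z = numeric(0),
                  t_act = numeric(0), junction_distance = numeric(0)))
  co <- cbind(a$x, a$y, a$z)
  dxg <- geom$dx
  # neighbour structure on the epicardial point cloud
  nbr_within <- function(i, rad) {
    d2 <- (co[, 1] - co[i, 1])^2 + (co[, 2] - co[i, 2])^2 +
      (co[, 3] - co[i, 3])^2
    which(d2 > 1e-12 & d2 <= rad^2)
  }
  # border: points with an unusually thin surface neighbourhood
  deg <- vapply(seq_len(nrow(a)), function(i)
    length(nbr_within(i, 1.8 * dxg)), 1L)
  border <- deg <= 5
  cand <- which(vapply(seq_len(nrow(a)), function(i) {
    nb <- nbr_within(i, 3 * dxg)
    length(nb) > 0 && all(a$t_act[i] <= a$t_act[nb] + 1e-9)
  }, TRUE))
  events <- list()
  for (i in cand) {
    ring <- nbr_within(i, ring_radius + dxg)
    ring <- ring[sqrt((co[ring, 1] - co[i, 1])^2 +
                      (co[ring, 2] - co[i, 2])^2 +
                      (co[ring, 3] - co[i, 3])^2) >= ring_radius - dxg]
    if (!length(ring)) next
    if (min(a$t_act[ring]) - a$t_act[i] < ring_delay) next
    # border connectivity through early-activated voxels
    early <- a$t_act <= a$t_act[i] + connect_tol
    if (any(border & early)) {
      reach <- logical(nrow(a))
      reach[i] <- TRUE
      frontier <- i
      while (length(frontier)) {
        nxt <- unique(unlist(lapply(frontier, nbr_within, rad = 1.8 * dxg)))
        nxt <- nxt[early[nxt] & !reach[nxt]]
        reach[nxt] <- TRUE
        frontier <- nxt
      }
      if (any(reach & border)) next
    }
    events[[length(events) + 1]] <- i
  }
  ev <- unlist(events)
  if (is.null(ev))
    return(tibble(x = numeric(0), y = numeric(0), z = numeric(0),
                  t_act = numeric(0), junction_distance = numeric(0)))
  jc <- junction_clusters(geom)
  jd <- if (length(jc)) {
    vapply(ev, function(i) {
      min(vapply(jc, function(p)
        sqrt(sum((co[i, ] - p)^2)), 1)) }, 1)
  } else rep(NA_real_, length(ev))
  tibble(x = co[ev, 1], y = co[ev, 2], z = co[ev, 3],
         t_act = a$t_act[ev], junction_distance = jd)
}
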