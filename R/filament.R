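#' Extract scroll-wave filaments from a pair of fields
#'
#' The filament is the broken-line approximation of the intersection of
#' the isosurfaces `V = v_iso` and `oi = oi_iso`.  Each grid cube is
#' decomposed into six tetrahedra; within a tetrahedron both fields are
#' linear, so each isosurface is a plane and their intersection is a
#' straight segment clipped to the tetrahedron.  Adjacent cubes share
#' face diagonals, so the segments join without cracks and are linked
#' into polylines by shared endpoints.
#'
#' For single-layer (2D sheet) geometries the same construction one
#' dimension down yields isolated phase-singularity points (the spiral
#' tips) rather than polylines.
#'
#' @param V,oi Compact per-voxel fields (one value per tissue voxel).
#' @param geom The [voxel_geometry] the fields live on.
#' @param v_iso Voltage isovalue (mV).
#' @param oi_iso oi-gate isovalue.
#' @return Tibble `filament`, `vertex`, `x`, `y`, `z` (mm); zero rows if
#'   no filament crosses the tissue.  For 2D sheets each point is its own
#'   one-vertex "filament".
#' @export
extract_filament <- function(V, oi, geom, v_iso = -50, oi_iso = 0.5) {
  d <- dim(geom$mask)
  if (d[3] == 1L) {
    Vf <- field_array(V, geom)[, , 1]
    Of <- field_array(oi, geom)[, , 1]
    pts <- tips2d_cpp(Vf, Of, geom$dx, geom$origin, v_iso, oi_iso)
    if (!nrow(pts)) {
      return(tibble(filament = integer(0), vertex = integer(0),
                    x = numeric(0), y = numeric(0), z = numeric(0)))
    }
    return(tibble(filament = seq_len(nrow(pts)), vertex = 1L,
                  x = pts[, 1], y = pts[, 2],
                  z = rep(geom$origin[3] + 0.5 * geom$dx, nrow(pts))))
  }
  # the kernel indexes z layers from 0; shift so reported z matches the
  # voxel-centre convention z = origin + (k - 0.5) dx
  org <- c(geom$origin[1], geom$origin[2], geom$origin[3] + 0.5 * geom$dx)
  segs <- filament_segments_cpp(field_array(V, geom), field_array(oi, geom),
                                dim(geom$mask), geom$dx, org, v_iso, oi_iso)
  link_segments(segs)
}

# Link shared-endpoint segments into ordered polylines.
link_segments <- function(segs, tol = 1e-6) {
  empty <- tibble(filament = integer(0), vertex = integer(0),
                  x = numeric(0), y = numeric(0), z = numeric(0))
  ns <- nrow(segs)
  if (!ns) return(empty)
  p1 <- segs[, 1:3, drop = FALSE]
  p2 <- segs[, 4:6, drop = FALSE]
  key <- function(p) paste(round(p[, 1] / tol), round(p[, 2] / tol),
                           round(p[, 3] / tol))
  k1 <- key(p1); k2 <- key(p2)
  used <- logical(ns)
  ends <- split(seq_len(2 * ns), c(k1, k2))   # endpoint slot -> segments
  seg_of <- function(slot) (slot - 1L) %% ns + 1L
  other_key <- function(slot) if (slot <= ns) k2[slot] else k1[slot - ns]
  other_pt <- function(slot) if (slot <= ns) p2[slot, ] else p1[slot - ns, ]
  this_pt <- function(slot) if (slot <= ns) p1[slot, ] else p2[slot - ns, ]
  out <- list()
  fid <- 0L
  for (s0 in seq_len(ns)) {
    if (used[s0]) next
    fid <- fid + 1L
    # walk forward from segment s0's second endpoint
    used[s0] <- TRUE
    pts <- list(p1[s0, ], p2[s0, ])
    walk <- function(start_key, pts, prepend) {
      kcur <- start_key
      repeat {
        slots <- ends[[kcur]]
        slots <- slots[!used[seg_of(slots)]]
        if (!length(slots)) break
        sl <- slots[1]
        used[seg_of(sl)] <<- TRUE
        nxt <- other_pt(sl)
        if (prepend) pts <- c(list(nxt), pts) else pts <- c(pts, list(nxt))
        kcur <- other_key(sl)
      }
      pts
    }
    pts <- walk(k2[s0], pts, prepend = FALSE)
    pts <- walk(k1[s0], pts, prepend = TRUE)
    m <- do.call(rbind, pts)
    out[[fid]] <- tibble(filament = fid, vertex = seq_len(nrow(m)),
                         x = m[, 1], y = m[, 2], z = m[, 3])
  }
  dplyr::bind_rows(out)
}

#' Epicardial tips of a filament set
#'
#' For each polyline, the endpoint(s) lying within 1.5 voxels of an
#' epicardium-flagged voxel (a filament's broken line stops about half a
#' grid cube short of the surface); closed loops and filaments with no
#' epicardial endpoint contribute nothing.  For 2D sheets every
#' singularity point is itself the tip.
#'
#' @param filaments Tibble from [extract_filament()].
#' @param geom The [voxel_geometry].
#' @return Tibble `filament`, `x`, `y`, `z`.
#' @export
filament_tips <- function(filaments, geom) {
  if (!nrow(filaments))
    return(tibble(filament = integer(0), x = numeric(0), y = numeric(0),
                  z = numeric(0)))
  if (dim(geom$mask)[3] == 1L)
    return(filaments[, c("filament", "x", "y", "z")])
  vx <- geom_voxels(geom)
  ep <- vx[vx$epi, , drop = FALSE]
  # a filament ends about half a grid cube inside the tissue, so an
  # epicardial endpoint sits within ~1.5 voxels of an epi-flagged voxel
  epi_dist <- function(p)
    sqrt(min((ep$x - p[1])^2 + (ep$y - p[2])^2 + (ep$z - p[3])^2))
  tol <- 1.5 * geom$dx
  out <- lapply(split(filaments, filaments$filament), function(f) {
    n <- nrow(f)
    if (n < 2) return(NULL)
    a <- c(f$x[1], f$y[1], f$z[1])
    b <- c(f$x[n], f$y[n], f$z[n])
    if (sqrt(sum((a - b)^2)) < 1e-9) return(NULL)   # closed loop
    picks <- list()
    if (epi_dist(a) <= tol) picks <- c(picks, list(a))
    if (epi_dist(b) <= tol) picks <- c(picks, list(b))
    if (!length(picks)) return(NULL)
    m <- do.call(rbind, picks)
    tibble(filament = f$filament[1], x = m[, 1], y = m[, 2], z = m[, 3])
  })
  dplyr::bind_rows(out)
}

#' Track spiral tips through a simulation
#'
#' Extracts the filament at every recorded snapshot and reduces it to one
#' epicardial tip position per time.  Tip points within `cluster_tol` of
#' each other are merged into clusters; the reported tip is the centroid
#' of the cluster nearest the previous tip, so a transiently created
#' second singularity pair (e.g. a wave break at a boundary) does not
#' yank the trace.
#'
#' @param sim A `sim_result` with snapshots.
#' @param cluster_tol Single-link clustering distance (mm).
#' @return A `tip_trace` tibble: `t_ms`, `x`, `y`, `z`, `n_points`
#'   (points in the chosen cluster), `n_clusters`, `filament_length`
#'   (total polyline arc length at that time, mm).
#' @export
track_tips <- function(sim, cluster_tol = 2) {
  geom <- sim$geom
  prev <- NULL
  rows <- list()
  for (s in seq_along(sim$snap_t)) {
    fil <- extract_filament(sim$snap_V[, s], sim$snap_oi[, s], geom)
    if (!nrow(fil)) next
    len <- sum(unlist(lapply(split(fil, fil$filament), function(f) {
      if (nrow(f) < 2) return(0)
      sum(sqrt(diff(f$x)^2 + diff(f$y)^2 + diff(f$z)^2))
    })))
    tp <- filament_tips(fil, geom)
    if (!nrow(tp)) next
    cl <- cluster_points(cbind(tp$x, tp$y, tp$z), cluster_tol)
    cent <- do.call(rbind, lapply(cl, function(ix)
      c(mean(tp$x[ix]), mean(tp$y[ix]), mean(tp$z[ix]), length(ix))))
    pick <- if (is.null(prev)) which.max(cent[, 4]) else
      which.min((cent[, 1] - prev[1])^2 + (cent[, 2] - prev[2])^2 +
                (cent[, 3] - prev[3])^2)
    prev <- cent[pick, 1:3]
    rows[[length(rows) + 1]] <-
      tibble(t_ms = sim$snap_t[s], x = cent[pick, 1], y = cent[pick, 2],
             z = cent[pick, 3], n_points = as.integer(cent[pick, 4]),
             n_clusters = length(cl), filament_length = len)
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("tip_trace", class(out))
  out
}

# greedy single-link clustering for the handful of tip points per frame
cluster_points <- function(p, tol) {
  n <- nrow(p)
  cl <- rep(0L, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (cl[i] > 0) next
    cur <- cur + 1L
    members <- i
    cl[i] <- cur
    repeat {
      d2 <- vapply(which(cl == 0), function(j)
        min((p[j, 1] - p[members, 1])^2 + (p[j, 2] - p[members, 2])^2 +
            (p[j, 3] - p[members, 3])^2), 1)
      add <- which(cl == 0)[d2 <= tol^2]
      if (!length(add)) break
      cl[add] <- cur
      members <- c(members, add)
    }
  }
  split(seq_len(n), cl)
}

#' Rotation period of a tip trace
#'
#' Dominant period of the oscillation of the tip x coordinate, estimated
#' from the periodogram of the detrended series.
#'
#' @param tips A `tip_trace` (needs >= 2 rotations of data).
#' @return Period in ms.
#' @export
rotation_period <- function(tips) {
  if (nrow(tips) < 8) abort("too little tip data to estimate a period")
  dt <- stats::median(diff(tips$t_ms))
  x <- tips$x - mean(tips$x)
  # remove slow drift so the rotation peak dominates
  x <- stats::residuals(stats::lm(x ~ poly(tips$t_ms, 2)))
  if (sd(x) < 1e-6) abort("tip is stationary: no rotation signal")
  n2 <- 2^ceiling(log2(length(x) * 4))
  P <- Mod(fft(c(x, rep(0, n2 - length(x)))))^2
  fr <- (seq_len(n2 %/% 2) - 1) / (n2 * dt)   # cycles per ms
  Pp <- P[seq_len(n2 %/% 2)]
  sel <- fr > 1 / (tips$t_ms[nrow(tips)] - tips$t_ms[1])  # > 1 full cycle
  if (!any(sel)) abort("too little tip data to estimate a period")
  1 / fr[sel][which.max(Pp[sel])]
}

#' Rotation-averaged tip trace
#'
#' Averages the raw tip positions over consecutive non-overlapping
#' windows of one rotation period, removing the circular core motion so
#' that residual displacement reflects drift.
#'
#' @param tips A `tip_trace`.
#' @param period Rotation period (ms), e.g. from [rotation_period()].
#' @return Tibble `window`, `t_ms` (window midpoint), `x`, `y`, `z`,
#'   `n` (samples averaged).
#' @export
average_tip_trace <- function(tips, period) {
  if (!nrow(tips)) abort("empty tip trace")
  w <- floor((tips$t_ms - tips$t_ms[1]) / period)
  out <- tips %>%
    mutate(window = w) %>%
    group_by(.data$window) %>%
    summarise(t_ms = mean(.data$t_ms), x = mean(.data$x), y = mean(.data$y),
              z = mean(.data$z), n = dplyr::n(), .groups = "drop")
  # an incomplete window does not average the rotation out; drop it
  # unless it is the only one
  expected <- period / stats::median(diff(tips$t_ms))
  full <- out$n >= 0.7 * expected
  if (any(full)) out <- out[full, , drop = FALSE]
  out
}

#' Classify drift of an averaged tip trace
#'
#' The secular velocity of the rotation-averaged trace (after discarding
#' the initial transient) -- the least-squares slope of position against
#' time, which a bounded meander cannot inflate the way a start-to-end
#' difference over a short window can -- is rescaled to a 40 s reference
#' duration and compared with the 10 mm criterion: more than 10 mm per
#' 40 s is drifting.  Large but erratic motion (path length far
#' exceeding net displacement) is excluded as not interpretable as
#' continuous drift.  The raw start-to-end displacement is reported
#' alongside.
#'
#' @param avg Averaged trace from [average_tip_trace()].
#' @param threshold Drift threshold (mm per reference duration).
#' @param ref_duration Reference duration (ms).
#' @param discard Number of initial rotation windows dropped as transient.
#' @param max_path_ratio Path-length / displacement ratio above which
#'   drifting-scale motion is excluded.
#' @return A `drift_class` list: `classification` (stationary / drifting
#'   / excluded), `displacement` (mm over the analysed window),
#'   `rate` (mm/s), `scaled_displacement` (mm per reference duration),
#'   `direction` (unit vector), `path_ratio`.
#' @export
classify_drift <- function(avg, threshold = 10, ref_duration = 40000,
                           discard = 2, max_path_ratio = 6) {
  if (!nrow(avg)) abort("empty averaged trace")
  a <- avg[avg$window >= discard, , drop = FALSE]
  if (nrow(a) < 2) a <- avg[max(1, nrow(avg) - 1):nrow(avg), , drop = FALSE]
  n <- nrow(a)
  dvec <- c(a$x[n] - a$x[1], a$y[n] - a$y[1], a$z[n] - a$z[1])
  disp <- sqrt(sum(dvec^2))
  span <- a$t_ms[n] - a$t_ms[1]
  path <- sum(sqrt(diff(a$x)^2 + diff(a$y)^2 + diff(a$z)^2))
  # secular velocity: least-squares slope of position against time
  vel <- if (span > 0) {
    tc <- a$t_ms - mean(a$t_ms)
    c(sum(tc * a$x), sum(tc * a$y), sum(tc * a$z)) / sum(tc^2) * 1000
  } else c(0, 0, 0)
  rate <- sqrt(sum(vel^2))                      # mm/s
  scaled <- rate / 1000 * ref_duration          # mm per reference window
  ratio <- if (disp > 1e-9) path / disp else Inf
  cls <- if (scaled <= threshold) "stationary"
         else if (ratio > max_path_ratio) "excluded"
         else "drifting"
  structure(
    list(classification = cls, displacement = disp,
         rate = rate, scaled_displacement = scaled,
         direction = if (rate > 1e-9) vel / rate else c(0, 0, 0),
         path_ratio = ratio, window_ms = span),
    class = "drift_class")
}

#' @export
print.drift_class <- function(x, ...) {
  cat(sprintf(
    "<drift_class> %s: %.2f mm over %.0f ms (%.2f mm/s; %.1f mm per 40 s)\n",
    x$classification, x$displacement, x$window_ms, x$rate,
    x$scaled_displacement))
  invisible(x)
}

#' Spiral core diameter
#'
#' Twice the RMS distance of raw tip points from their centroid, over the
#' last `n_rotations` rotations if a period is supplied (otherwise the
#' whole trace).
#'
#' @param tips A `tip_trace`.
#' @param period Optional rotation period (ms).
#' @param n_rotations Number of final rotations used.
#' @return Core diameter (mm).
#' @export
core_diameter <- function(tips, period = NULL, n_rotations = 5) {
  if (!nrow(tips)) abort("insufficient tip data")
  t_end <- tips$t_ms[nrow(tips)]
  sel <- if (!is.null(period)) tips$t_ms > t_end - n_rotations * period
         else rep(TRUE, nrow(tips))
  tp <- tips[sel, , drop = FALSE]
  2 * sqrt(mean((tp$x - mean(tp$x))^2 + (tp$y - mean(tp$y))^2 +
                (tp$z - mean(tp$z))^2))
}
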