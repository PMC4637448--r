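#' Voxel geometries
#'
#' A `voxel_geometry` is a labelled occupancy mask on a regular Cartesian
#' grid: a 3D logical `mask`, a per-voxel region `label` (wall, ridge,
#' bridge, junction), a logical `epi` flag marking the designated
#' epicardial surface, the grid spacing `dx` (mm) and the grid `origin`
#' (mm).  In-plane voxel coordinates are the grid nodes
#' `origin + (i - 1) * dx`; through-wall (z) layers are voxel-centred at
#' `(k - 0.5) * dx` so that an `n`-mm wall maps to `round(n/dx - 0.5) + 1`
#' layers.  A voxel belongs to the tissue iff its centre lies inside the
#' continuous solid being voxelised.
#'
#' @name voxel_geometry
NULL

GEOM_LABELS <- c(none = 0L, wall = 1L, ridge = 2L, bridge = 3L, junction = 4L)

new_voxel_geometry <- function(mask, label, epi, dx, origin, name,
                               check_connected = TRUE) {
  stopifnot(is.array(mask), length(dim(mask)) == 3, dx > 0)
  storage.mode(label) <- "integer"
  n <- sum(mask)
  if (n == 0) abort("geometry has no tissue voxels")
  g <- structure(
    list(mask = mask, label = label, epi = epi & mask, dx = dx,
         origin = origin, name = name, n_voxels = n),
    class = "voxel_geometry")
  if (check_connected && !geom_is_connected(g))
    abort(paste0("construction error: '", name,
                 "' tissue is not a single 6-connected component"))
  g
}

#' @export
print.voxel_geometry <- function(x, ...) {
  d <- dim(x$mask)
  lab <- table(factor(x$label[x$mask],
                      levels = GEOM_LABELS, labels = names(GEOM_LABELS)))
  cat(sprintf("<voxel_geometry> '%s': %d x %d x %d grid, dx %g mm, %d voxels\n",
              x$name, d[1], d[2], d[3], x$dx, x$n_voxels))
  cat("  labels:", paste(sprintf("%s %d", names(lab)[lab > 0], lab[lab > 0]),
                         collapse = ", "), "\n")
  cat("  epicardial voxels:", sum(x$epi), "\n")
  invisible(x)
}

#' @export
dim.voxel_geometry <- function(x) dim(x$mask)

#' Tabulate the voxels of a geometry
#'
#' @param geom A [voxel_geometry].
#' @return A tibble with grid indices, mm coordinates, region label and
#'   epicardial flag, one row per tissue voxel (compact-index order).
#' @export
geom_voxels <- function(geom) {
  d <- dim(geom$mask)
  w <- which(geom$mask)
  ijk <- arrayInd(w, d)
  tibble(
    i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
    x = geom$origin[1] + (ijk[, 1] - 1) * geom$dx,
    y = geom$origin[2] + (ijk[, 2] - 1) * geom$dx,
    z = geom$origin[3] + (ijk[, 3] - 0.5) * geom$dx,
    label = names(GEOM_LABELS)[geom$label[w] + 1L],
    epi = geom$epi[w])
}

# compact index array: 0 outside tissue, 1..N inside (column-major order)
geom_index <- function(geom) {
  idx <- array(0L, dim(geom$mask))
  idx[geom$mask] <- seq_len(geom$n_voxels)
  idx
}

# N x 6 matrix of 0-based compact neighbour indices (x-,x+,y-,y+,z-,z+),
# -1 where the neighbour is absent (tissue boundary): the no-flux stencil.
voxel_neighbours <- function(geom) {
  idx <- geom_index(geom)
  d <- dim(idx)
  w <- which(geom$mask)
  ijk <- arrayInd(w, d)
  out <- matrix(-1L, length(w), 6)
  shifts <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
                  c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  for (s in seq_len(6)) {
    ni <- ijk[, 1] + shifts[s, 1]
    nj <- ijk[, 2] + shifts[s, 2]
    nk <- ijk[, 3] + shifts[s, 3]
    ok <- ni >= 1 & ni <= d[1] & nj >= 1 & nj <= d[2] & nk >= 1 & nk <= d[3]
    lin <- ni[ok] + d[1] * (nj[ok] - 1) + d[1] * d[2] * (nk[ok] - 1)
    val <- idx[lin]
    out[which(ok)[val > 0], s] <- val[val > 0] - 1L
  }
  out
}

geom_is_connected <- function(geom) {
  nbr <- voxel_neighbours(geom)
  n <- nrow(nbr)
  visited <- logical(n)
  frontier <- 1L
  visited[1] <- TRUE
  while (length(frontier)) {
    nxt <- nbr[frontier, , drop = FALSE]
    nxt <- unique(nxt[nxt >= 0]) + 1L
    frontier <- nxt[!visited[nxt]]
    visited[frontier] <- TRUE
  }
  all(visited)
}

# label bridge/wall contact voxels as junctions (both sides)
label_junctions <- function(mask, label) {
  idx <- array(seq_along(mask), dim(mask))
  d <- dim(mask)
  near <- function(code_a, code_b) {
    # voxels with label code_a having a 6-neighbour with label code_b
    hit <- array(FALSE, d)
    for (s in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))) {
      shifted <- array(GEOM_LABELS[["none"]], d)
      src <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
      dst <- src
      for (a in 1:3) {
        if (s[a] == 1) { dst[[a]] <- 2:d[a]; src[[a]] <- 1:(d[a] - 1) }
        if (s[a] == -1) { dst[[a]] <- 1:(d[a] - 1); src[[a]] <- 2:d[a] }
      }
      shifted[dst[[1]], dst[[2]], dst[[3]]] <- label[src[[1]], src[[2]], src[[3]]]
      hit <- hit | (label == code_a & shifted == code_b)
    }
    hit
  }
  j1 <- near(GEOM_LABELS[["bridge"]], GEOM_LABELS[["wall"]])
  j2 <- near(GEOM_LABELS[["wall"]], GEOM_LABELS[["bridge"]])
  label[j1 | j2] <- GEOM_LABELS[["junction"]]
  label
}

node_count <- function(L, dx) as.integer(round(L / dx) + 1)
layer_count <- function(thickness, dx) sum((seq_len(1000) - 0.5) * dx < thickness)

#' Build a 2D homogeneous tissue sheet
#'
#' Single-voxel-thick square sheet; node count per side is
#' `round(L/dx) + 1`.  All voxels are wall and all are flagged
#' epicardial.
#'
#' @param Lx,Ly Side lengths (mm).
#' @param dx Grid spacing (mm).
#' @return A [voxel_geometry].
#' @export
geom_sheet <- function(Lx = 25, Ly = 25, dx = 0.33) {
  if (Lx <= 0 || Ly <= 0) abort("sheet dimensions must be positive")
  nx <- node_count(Lx, dx); ny <- node_count(Ly, dx)
  mask <- array(TRUE, c(nx, ny, 1))
  label <- array(GEOM_LABELS[["wall"]], c(nx, ny, 1))
  new_voxel_geometry(mask, label, mask, dx, c(0, 0, -dx / 2), "sheet2d")
}

#' Build a 1D strand
#'
#' A single line of voxels used to record steady propagating pulses for
#' the phase-distribution initiation and to measure conduction velocity.
#'
#' @param length Strand length (mm); < 20 mm draws a warning since a
#'   steady mid-strand pulse needs room to develop.
#' @param dx Grid spacing (mm).
#' @return A [voxel_geometry].
#' @export
geom_strand <- function(length = 33, dx = 0.33) {
  if (length <= 0) abort("strand length must be positive")
  if (length < 20) warn("strand shorter than 20 mm; propagation may not reach steady state")
  n <- node_count(length, dx)
  mask <- array(TRUE, c(n, 1, 1))
  label <- array(GEOM_LABELS[["wall"]], c(n, 1, 1))
  new_voxel_geometry(mask, label, mask, dx, c(0, 0, -dx / 2), "strand1d")
}

#' Build a wedge with linearly tapering wall thickness
#'
#' Thickness decreases linearly from `max_thickness` at `x = 0` to zero at
#' `x = Lx`; the flat face (`k = 1`) is the epicardium.  At least one
#' voxel layer is kept wherever the local thickness reaches half a voxel.
#'
#' @param Lx,Ly In-plane dimensions (mm).
#' @param max_thickness Wall thickness at the thick end (mm).
#' @param dx Grid spacing (mm).
#' @return A [voxel_geometry].
#' @export
geom_wedge <- function(Lx = 25, Ly = 25, max_thickness = 3, dx = 0.33) {
  if (max_thickness < 2 * dx) abort("max_thickness must be at least 2*dx")
  nx <- node_count(Lx, dx); ny <- node_count(Ly, dx)
  nz <- layer_count(max_thickness, dx)
  xs <- (seq_len(nx) - 1) * dx
  th <- max_thickness * pmax(0, 1 - xs / Lx)
  mask <- array(FALSE, c(nx, ny, nz))
  for (k in seq_len(nz)) mask[(k - 0.5) * dx < th, , k] <- TRUE
  label <- array(GEOM_LABELS[["none"]], c(nx, ny, nz))
  label[mask] <- GEOM_LABELS[["wall"]]
  epi <- array(FALSE, c(nx, ny, nz)); epi[, , 1] <- TRUE
  new_voxel_geometry(mask, label, epi, dx, c(0, 0, 0), "wedge")
}

#' Build a flat wall carrying a ridge
#'
#' A constant-thickness wall with a thicker central strip (the ridge) on
#' its endocardial face, spanning the full y extent and centred in x.
#'
#' @param Lx,Ly In-plane dimensions (mm).
#' @param wall_thickness Wall thickness (mm).
#' @param ridge_width Ridge width in x (mm).
#' @param ridge_height Extra thickness under the ridge (mm); 0 gives a
#'   plain slab.
#' @param dx Grid spacing (mm).
#' @return A [voxel_geometry].
#' @export
geom_ridge <- function(Lx = 25, Ly = 25, wall_thickness = 3, ridge_width = 2,
                       ridge_height = 2, dx = 0.33) {
  if (ridge_width > Lx) abort("ridge wider than the wall")
  nx <- node_count(Lx, dx); ny <- node_count(Ly, dx)
  nzw <- layer_count(wall_thickness, dx)
  nz <- layer_count(wall_thickness + ridge_height, dx)
  xs <- (seq_len(nx) - 1) * dx
  on_strip <- abs(xs - Lx / 2) < ridge_width / 2
  mask <- array(FALSE, c(nx, ny, nz))
  mask[, , seq_len(nzw)] <- TRUE
  label <- array(GEOM_LABELS[["none"]], c(nx, ny, nz))
  label[mask] <- GEOM_LABELS[["wall"]]
  if (nz > nzw) {
    for (k in (nzw + 1):nz) {
      mask[on_strip, , k] <- TRUE
      label[on_strip, , k] <- GEOM_LABELS[["ridge"]]
    }
  }
  epi <- array(FALSE, c(nx, ny, nz)); epi[, , 1] <- TRUE
  new_voxel_geometry(mask, label, epi, dx, c(0, 0, 0), "ridge")
}

# distance from points to a circular arc (tube centreline helper)
dist_to_arc <- function(px, pz, py, cx, cz, cy, radius) {
  dxp <- px - cx; dzp <- pz - cz
  rr <- sqrt(dxp^2 + dzp^2)
  ang <- atan2(dzp, dxp)
  on_arc <- ang >= 0 & ang <= pi
  d_rad <- sqrt((rr - radius)^2 + (py - cy)^2)
  # distance to endpoints for points outside the arc's angular range
  e1 <- sqrt((px - (cx + radius))^2 + (pz - cz)^2 + (py - cy)^2)
  e2 <- sqrt((px - (cx - radius))^2 + (pz - cz)^2 + (py - cy)^2)
  ifelse(on_arc, d_rad, pmin(e1, e2))
}

#' Build the flat-wall curved-bridge geometry (PM1)
#'
#' A plain 25 x 25 x 3 mm wall plus a semicircular pectinate-muscle bridge
#' of tube diameter 2 mm and arc length 14 mm, lying in a plane
#' perpendicular to the wall and joining it at two junctions (J1, J2).
#' The along-wall distance between the junctions (the chord, about 8.9 mm)
#' is shorter than the path along the bridge -- the property that renders
#' the bridge electrophysiologically inert.
#'
#' @param dx Grid spacing (mm).
#' @param Lx,Ly,wall_thickness Wall dimensions (mm).
#' @param arc_length Bridge centreline length (mm).
#' @param bridge_diameter Bridge tube diameter (mm).
#' @return A [voxel_geometry].
#' @export
geom_pm1 <- function(dx = 0.33, Lx = 25, Ly = 25, wall_thickness = 3,
                     arc_length = 14, bridge_diameter = 2) {
  nx <- node_count(Lx, dx); ny <- node_count(Ly, dx)
  nzw <- layer_count(wall_thickness, dx)
  ra <- arc_length / pi           # semicircle radius
  zc <- wall_thickness            # arc centre on the endocardial surface
  nz <- layer_count(wall_thickness + ra + bridge_diameter / 2 + dx, dx)
  xs <- (seq_len(nx) - 1) * dx
  ys <- (seq_len(ny) - 1) * dx
  zs <- (seq_len(nz) - 0.5) * dx
  xc <- Lx / 2; yc <- Ly / 2
  mask <- array(FALSE, c(nx, ny, nz))
  mask[, , seq_len(nzw)] <- TRUE
  label <- array(GEOM_LABELS[["none"]], c(nx, ny, nz))
  label[mask] <- GEOM_LABELS[["wall"]]
  # bridge tube around the semicircular arc (in the x-z plane at y = yc)
  co <- expand.grid(x = xs, y = ys, z = zs)
  d <- dist_to_arc(co$x, co$z, co$y, xc, zc, yc, ra)
  tube <- array(d <= bridge_diameter / 2, c(nx, ny, nz))
  newb <- tube & !mask
  mask[newb] <- TRUE
  label[newb] <- GEOM_LABELS[["bridge"]]
  label <- label_junctions(mask, label)
  epi <- array(FALSE, c(nx, ny, nz)); epi[, , 1] <- TRUE
  g <- new_voxel_geometry(mask, label, epi, dx, c(0, 0, 0), "pm1")
  if (length(junction_clusters(g)) != 2)
    abort("construction error: bridge arc failed to form exactly 2 junctions")
  g
}

hemisphere_shell <- function(dx, R_out = 15, thickness = 3, margin = 1) {
  nh <- round((R_out + margin) / dx)
  nxy <- 2L * nh + 1L
  nz <- as.integer(ceiling(R_out / dx))
  org <- c(-nh * dx, -nh * dx, 0)
  xs <- org[1] + (seq_len(nxy) - 1) * dx
  zs <- (seq_len(nz) - 0.5) * dx
  co <- expand.grid(x = xs, y = xs, z = zs)
  r <- sqrt(co$x^2 + co$y^2 + co$z^2)
  mask <- array(r >= R_out - thickness & r <= R_out, c(nxy, nxy, nz))
  list(mask = mask, origin = org, dims = c(nxy, nxy, nz),
       coords = co, r = r)
}

#' Build the curved-wall bridge geometries (PM2, PM3)
#'
#' `geom_pm2()`: a hemispherical atrial wall (outer diameter 30 mm,
#' thickness 3 mm, convex epicardial face) with a straight
#' pectinate-muscle bridge of length 8 mm and diameter 2 mm spanning the
#' concave endocardial side near the apex, touching the wall only at its
#' two junctions.  Because an 8 mm chord of the 12 mm-radius endocardial
#' surface dips at most 0.69 mm below it, a 2 mm-thick tube laid exactly
#' on the chord would graze the wall along its whole length; the bridge
#' axis is therefore stood off the wall by `offset` and joined to it by
#' short radial stubs at the ends, like a free-standing pectinate
#' muscle.  The along-wall geodesic between the junctions (about
#' 8.2 mm) remains longer than the 8 mm straight bridge.  `geom_pm3()`
#' extends PM2 with a 2 mm ridge running from junction to junction along
#' the endocardial surface.
#'
#' @param dx Grid spacing (mm).
#' @param R_out Outer hemisphere radius (mm).
#' @param thickness Wall thickness (mm).
#' @param bridge_length Bridge straight-segment length (mm).
#' @param bridge_diameter Bridge (and ridge) tube diameter (mm).
#' @param offset Radial stand-off of the bridge axis from the junction
#'   chord (mm).
#' @return A [voxel_geometry].
#' @export
geom_pm2 <- function(dx = 0.33, R_out = 15, thickness = 3,
                     bridge_length = 8, bridge_diameter = 2, offset = 1) {
  sh <- hemisphere_shell(dx, R_out, thickness)
  mask <- sh$mask
  label <- array(GEOM_LABELS[["none"]], sh$dims)
  label[mask] <- GEOM_LABELS[["wall"]]
  R_in <- R_out - thickness
  hx <- bridge_length / 2
  z0 <- sqrt(R_in^2 - hx^2)   # junction height on the inner surface
  zb <- z0 - offset           # bridge axis height
  rad <- bridge_diameter / 2
  # straight tube: distance to the segment (-hx,0,zb)-(hx,0,zb)
  px <- pmin(pmax(sh$coords$x, -hx), hx)
  d <- sqrt((sh$coords$x - px)^2 + sh$coords$y^2 + (sh$coords$z - zb)^2)
  tube <- d <= rad
  # radial junction stubs from the axis ends up into the wall
  for (sx in c(-hx, hx)) {
    pz <- pmin(pmax(sh$coords$z, zb), z0 + rad)
    ds <- sqrt((sh$coords$x - sx)^2 + sh$coords$y^2 + (sh$coords$z - pz)^2)
    tube <- tube | ds <= rad
  }
  tube <- array(tube, sh$dims)
  newb <- tube & !mask
  mask[newb] <- TRUE
  label[newb] <- GEOM_LABELS[["bridge"]]
  label <- label_junctions(mask, label)
  epi <- array(sh$r > R_out - dx, sh$dims) & mask
  g <- new_voxel_geometry(mask, label, epi, dx, sh$origin, "pm2")
  if (length(junction_clusters(g)) != 2)
    abort("construction error: bridge failed to form exactly 2 junctions")
  g
}

#' @rdname geom_pm2
#' @export
geom_pm3 <- function(dx = 0.33, R_out = 15, thickness = 3,
                     bridge_length = 8, bridge_diameter = 2) {
  base <- geom_pm2(dx, R_out, thickness, bridge_length, bridge_diameter)
  sh <- hemisphere_shell(dx, R_out, thickness)
  R_in <- R_out - thickness
  # great-circle arc on the inner surface from J1 to J2 (x-z plane,
  # through the apex): points with |y| small, r ~ R_in, between junctions
  rr <- sh$r
  # distance from each voxel centre to the arc: radial offset from R_in
  # plus out-of-plane offset, restricted to the angular sector of the arc
  hx <- bridge_length / 2
  z0 <- sqrt(R_in^2 - hx^2)
  ang_end <- atan2(hx, z0)          # polar angle of the junctions
  pol <- atan2(abs(sh$coords$x), sh$coords$z)
  in_sector <- pol <= ang_end
  rho <- sqrt(sh$coords$x^2 + sh$coords$z^2)
  d_arc <- sqrt((rho - R_in)^2 + sh$coords$y^2)
  d_end <- pmin(
    sqrt((sh$coords$x - hx)^2 + sh$coords$y^2 + (sh$coords$z - z0)^2),
    sqrt((sh$coords$x + hx)^2 + sh$coords$y^2 + (sh$coords$z - z0)^2))
  d <- ifelse(in_sector, d_arc, d_end)
  tube <- array(d <= bridge_diameter / 2, sh$dims)
  mask <- base$mask
  label <- base$label
  newr <- tube & !mask
  mask[newr] <- TRUE
  label[newr] <- GEOM_LABELS[["ridge"]]
  new_voxel_geometry(mask, label, base$epi, dx, base$origin, "pm3")
}

#' Junction clusters of a bridge geometry
#'
#' Groups junction-labelled voxels into 26-connected clusters and returns
#' their centroids (mm).
#'
#' @param geom A [voxel_geometry].
#' @return A list of cluster centroid vectors `c(x, y, z)`.
#' @export
junction_clusters <- function(geom) {
  w <- which(geom$label == GEOM_LABELS[["junction"]] & geom$mask)
  if (!length(w)) return(list())
  ijk <- arrayInd(w, dim(geom$mask))
  n <- nrow(ijk)
  cl <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (cl[s] > 0) next
    cur <- cur + 1L
    frontier <- s
    cl[s] <- cur
    while (length(frontier)) {
      nxt <- integer(0)
      for (f in frontier) {
        adj <- which(cl == 0 &
                     abs(ijk[, 1] - ijk[f, 1]) <= 1 &
                     abs(ijk[, 2] - ijk[f, 2]) <= 1 &
                     abs(ijk[, 3] - ijk[f, 3]) <= 1)
        cl[adj] <- cur
        nxt <- c(nxt, adj)
      }
      frontier <- nxt
    }
  }
  lapply(seq_len(cur), function(c0) {
    sel <- cl == c0
    c(x = geom$origin[1] + mean(ijk[sel, 1] - 1) * geom$dx,
      y = geom$origin[2] + mean(ijk[sel, 2] - 1) * geom$dx,
      z = geom$origin[3] + mean(ijk[sel, 3] - 0.5) * geom$dx)
  })
}

#' Map a point in mm to its nearest tissue voxel
#'
#' @param geom A [voxel_geometry].
#' @param p Numeric vector `c(x, y)` or `c(x, y, z)` in mm.
#' @return Compact (1-based) voxel index.
#' @export
nearest_voxel <- function(geom, p) {
  vx <- geom_voxels(geom)
  if (length(p) == 2) p <- c(p, vx$z[1])
  d2 <- (vx$x - p[1])^2 + (vx$y - p[2])^2 + (vx$z - p[3])^2
  which.min(d2)
}

#' Voxel coordinates in mm
#'
#' @param geom A [voxel_geometry].
#' @return Matrix (N x 3) of tissue-voxel centre coordinates in
#'   compact-index order.
#' @export
geom_coords <- function(geom) {
  vx <- geom_voxels(geom)
  cbind(x = vx$x, y = vx$y, z = vx$z)
}
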