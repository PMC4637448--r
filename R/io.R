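#' Write a field as a legacy-VTK structured-points file
#'
#' ASCII legacy VTK, openable by standard viewers; one or more point
#' scalar arrays on the full rectangular grid (non-tissue points carry
#' `fill`).
#'
#' @param path Output file.
#' @param arrays Named list of 3D arrays (equal dims).
#' @param dx Grid spacing (mm).
#' @param origin Grid origin (mm).
#' @param fill Value written outside the tissue (where the array is NA).
#' @export
write_vtk <- function(path, arrays, dx, origin = c(0, 0, 0), fill = -1e30) {
  stopifnot(length(arrays) >= 1, !is.null(names(arrays)))
  d <- dim(arrays[[1]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "atriadrift field", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
               sprintf("ORIGIN %.9g %.9g %.9g", origin[1], origin[2], origin[3]),
               sprintf("SPACING %.9g %.9g %.9g", dx, dx, dx),
               sprintf("POINT_DATA %d", prod(d))), con)
  for (nm in names(arrays)) {
    a <- arrays[[nm]]
    if (!identical(dim(a), d)) abort("arrays must share dimensions")
    v <- as.numeric(a)
    v[!is.finite(v)] <- fill
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    writeLines(formatC(v, format = "g", digits = 9), con)
  }
  invisible(path)
}

#' Read a legacy-VTK structured-points file
#'
#' @param path File written by [write_vtk()] (ASCII legacy VTK with
#'   point scalars).
#' @return List with `arrays` (named list of 3D arrays), `dx`, `origin`.
#' @export
read_vtk <- function(path) {
  ln <- readLines(path)
  if (length(ln) < 8 || !grepl("^# vtk", ln[1]))
    abort(paste0("parse error: not a legacy VTK file: ", path))
  grab <- function(tag) {
    i <- grep(paste0("^", tag, " "), ln)[1]
    if (is.na(i)) abort(paste0("parse error: missing ", tag, " in ", path))
    as.numeric(strsplit(trimws(ln[i]), "\\s+")[[1]][-1])
  }
  d <- as.integer(grab("DIMENSIONS"))
  origin <- grab("ORIGIN")
  sp <- grab("SPACING")
  if (length(unique(round(sp, 12))) != 1)
    abort("parse error: anisotropic spacing not supported")
  npt <- prod(d)
  si <- grep("^SCALARS ", ln)
  arrays <- list()
  for (i in si) {
    nm <- strsplit(ln[i], "\\s+")[[1]][2]
    j <- i + 2   # skip LOOKUP_TABLE
    vals <- numeric(0)
    while (length(vals) < npt) {
      if (j > length(ln))
        abort(sprintf("parse error: truncated scalar '%s' at line %d", nm, j))
      vals <- c(vals, as.numeric(strsplit(trimws(ln[j]), "\\s+")[[1]]))
      j <- j + 1
    }
    arrays[[nm]] <- array(vals[seq_len(npt)], d)
  }
  list(arrays = arrays, dx = sp[1], origin = origin)
}

#' Save / load a voxel geometry
#'
#' The geometry travels as a legacy-VTK structured-points file with three
#' point scalars (`tissue`, `label`, `epi`) plus a JSON sidecar carrying
#' the name and conventions.
#'
#' @param geom A [voxel_geometry].
#' @param path Output `.vtk` path (the sidecar gets `.json` appended).
#' @export
write_geometry <- function(geom, path) {
  write_vtk(path,
            list(tissue = array(as.numeric(geom$mask), dim(geom$mask)),
                 label = array(as.numeric(geom$label), dim(geom$mask)),
                 epi = array(as.numeric(geom$epi), dim(geom$mask))),
            geom$dx, geom$origin, fill = 0)
  jsonlite::write_json(
    list(name = geom$name, dx = geom$dx, origin = geom$origin,
         format_version = 1L),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_geometry
#' @return `read_geometry()`: the reconstructed [voxel_geometry].
#' @export
read_geometry <- function(path) {
  v <- read_vtk(path)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path)
          else list(name = "imported")
  mask <- v$arrays$tissue > 0.5
  if (is.null(mask)) abort("parse error: geometry file lacks 'tissue' scalar")
  label <- array(as.integer(round(
    if (is.null(v$arrays$label)) as.numeric(mask) else v$arrays$label)),
    dim(mask))
  epi <- if (is.null(v$arrays$epi)) mask else v$arrays$epi > 0.5
  new_voxel_geometry(mask, label, epi, v$dx, unlist(v$origin),
                     meta$name %||% "imported", check_connected = FALSE)
}

#' Write simulation snapshots as numbered VTK files with a manifest
#'
#' @param sim A `sim_result` with snapshots.
#' @param dir Output directory (created if needed).
#' @param stride Write every `stride`-th snapshot.
#' @return Paths written (invisibly).
#' @export
write_snapshots <- function(sim, dir, stride = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  geom <- sim$geom
  idx <- seq(1, length(sim$snap_t), by = stride)
  paths <- character(0)
  for (q in idx) {
    p <- file.path(dir, sprintf("snap_%05d.vtk", q))
    write_vtk(p, list(V = field_array(sim$snap_V[, q], geom),
                      oi = field_array(sim$snap_oi[, q], geom)),
              geom$dx, geom$origin)
    paths <- c(paths, p)
  }
  jsonlite::write_json(
    list(t_ms = sim$snap_t[idx], files = basename(paths),
         dx = geom$dx, geometry = geom$name),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Full run configuration with the model's standard defaults
#'
#' One flat, serialisable record of every tunable constant: integration
#' steps, grid spacing, diffusion, ionic remodelling scales, the
#' acetylcholine concentration, isovalues used for filament extraction,
#' and the drift criterion.  Round-trips losslessly through JSON;
#' unknown keys are rejected on read.
#'
#' @param ... Overrides of the default fields.
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  defaults <- list(
    schema_version = 1L, tag = "",
    dt_ms = 0.01, dx_mm = 0.33, D_mm2_ms = 0.07,
    record_interval_ms = 10, probe_dt_ms = 1,
    scale_gCaL = 0.35, scale_gKr = 9, scale_gKs = 9,
    ach_umol_l = 0.0035, ach_exponent = 0.477,
    cach_offset = 0.052, cach_amp = 0.45, Cm_pF = 100,
    stim_amp_pA = -2000, stim_dur_ms = 2,
    bcl_ms = 300, v_iso_mV = -50, oi_iso = 0.5,
    drift_threshold_mm = 10, drift_ref_duration_ms = 40000,
    morphology_rel_threshold = 0.2)
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad))
    abort(paste0("unknown config key(s): ", paste(bad, collapse = ", ")))
  defaults[names(over)] <- over
  structure(defaults, class = "run_config")
}

#' @rdname run_config
#' @param cfg A `run_config`.
#' @param path JSON file path.
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x[setdiff(names(x), c())])
}

#' Write a trace as two-column CSV
#'
#' @param trace Tibble with `t_ms` and `V_mV` (or any two columns).
#' @param path Output CSV.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}

write_scenario <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$tips, file.path(dir, "tips.csv"),
                   row.names = FALSE)
  utils::write.csv(result$avg_trace, file.path(dir, "tips_averaged.csv"),
                   row.names = FALSE)
  write_trace_csv(result$probe, file.path(dir, "probe.csv"))
  spec <- result$spec
  jsonlite::write_json(
    c(list(spec = unclass(spec)),
      as.list(result$summary),
      list(thresholds = list(drift_threshold_mm = 10,
                             drift_ref_duration_ms = 40000,
                             v_iso_mV = -50, oi_iso = 0.5,
                             morphology_rel_threshold = 0.2))),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
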