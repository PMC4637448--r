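#' @importFrom ggplot2 ggplot aes geom_line geom_path geom_point geom_tile
#'   autoplot labs coord_equal scale_fill_viridis_c theme_minimal
NULL

#' Plot a tip trace
#'
#' Raw tip positions coloured by time, in the epicardial plane.
#'
#' @param object A `tip_trace` from [track_tips()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.tip_trace <- function(object, ...) {
  ggplot(object, aes(x = .data$x, y = .data$y, colour = .data$t_ms)) +
    geom_path() + geom_point(size = 0.6) +
    coord_equal() +
    labs(x = "x (mm)", y = "y (mm)", colour = "t (ms)",
         title = "Spiral tip trajectory") +
    theme_minimal()
}

#' Plot a power spectrum
#'
#' @param object A `psd_result`.
#' @param f_max Upper frequency limit of the plot (Hz).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.psd_result <- function(object, f_max = 25, ...) {
  df <- tibble(freq_hz = object$freq_hz, power = object$power)
  df <- df[df$freq_hz <= f_max, ]
  ggplot(df, aes(x = .data$freq_hz, y = .data$power)) +
    geom_line() +
    labs(x = "frequency (Hz)", y = "power density",
         title = sprintf("Dominant frequency %.2f Hz",
                         attr(object, "dominant_hz"))) +
    theme_minimal()
}

#' Plot a recurrence map
#'
#' Consecutive cycle lengths (CL_n vs CL_{n+1}); a single tight cluster
#' indicates a monomorphic rhythm.
#'
#' @param object A `recurrence_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.recurrence_map <- function(object, ...) {
  ggplot(object, aes(x = .data$cl_ms, y = .data$cl_next_ms)) +
    geom_point(alpha = 0.6) +
    coord_equal() +
    labs(x = expression(CL[n] ~ "(ms)"), y = expression(CL[n + 1] ~ "(ms)"),
         title = "Recurrence map") +
    theme_minimal()
}

#' Plot a voltage snapshot
#'
#' Epicardial-plane view of one recorded voltage field (maximum over z
#' for 3D geometries).
#'
#' @param sim A `sim_result` with snapshots.
#' @param snapshot Snapshot number.
#' @return A ggplot.
#' @export
plot_snapshot <- function(sim, snapshot = length(sim$snap_t)) {
  geom <- sim$geom
  a <- field_array(sim$snap_V[, snapshot], geom)
  v2 <- apply(a, c(1, 2), function(z) if (all(is.na(z))) NA_real_
              else max(z, na.rm = TRUE))
  d <- dim(v2)
  df <- tibble(
    x = geom$origin[1] + (rep(seq_len(d[1]), d[2]) - 1) * geom$dx,
    y = geom$origin[2] + (rep(seq_len(d[2]), each = d[1]) - 1) * geom$dx,
    V = as.numeric(v2))
  df <- df[is.finite(df$V), ]
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$V)) +
    geom_tile() +
    scale_fill_viridis_c(option = "inferno") +
    coord_equal() +
    labs(x = "x (mm)", y = "y (mm)", fill = "V (mV)",
         title = sprintf("t = %g ms", sim$snap_t[snapshot])) +
    theme_minimal()
}

#' Plot a geometry cross-section
#'
#' Thickness map (number of tissue layers) in the epicardial plane with
#' region labels overlaid.
#'
#' @param geom A [voxel_geometry].
#' @return A ggplot.
#' @export
plot_geometry <- function(geom) {
  vx <- geom_voxels(geom)
  thick <- vx %>%
    group_by(.data$i, .data$j) %>%
    summarise(x = .data$x[1], y = .data$y[1],
              layers = dplyr::n(),
              label = .data$label[which.max(.data$label != "wall")],
              .groups = "drop")
  ggplot(thick, aes(x = .data$x, y = .data$y)) +
    geom_tile(aes(fill = .data$layers)) +
    geom_point(data = thick[thick$label != "wall", ],
               aes(colour = .data$label), size = 0.3) +
    coord_equal() +
    labs(x = "x (mm)", y = "y (mm)", fill = "layers", colour = "region",
         title = geom$name) +
    theme_minimal()
}
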