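#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a paced-cell result
#'
#' @param x A `paced_cell` from [pace_to_steady()].
#' @param ... Unused.
#' @return The final-beat trace as a tibble (`t_ms`, `V_mV`).
#' @exportS3Method generics::tidy
tidy.paced_cell <- function(x, ...) x$trace

#' @rdname tidy.paced_cell
#' @return `glance()`: one-row tibble with `apd90`, `bcl`, `steady`,
#'   `peak_mV`, `rest_mV`.
#' @exportS3Method generics::glance
glance.paced_cell <- function(x, ...) {
  tibble(apd90_ms = x$apd90, bcl_ms = x$bcl, steady = x$steady,
         peak_mV = max(x$trace$V_mV), rest_mV = min(x$trace$V_mV))
}

#' Tidy a simulation result
#'
#' @param x A `sim_result`.
#' @param ... Unused.
#' @return The probe traces tibble.
#' @exportS3Method generics::tidy
tidy.sim_result <- function(x, ...) x$probes

#' @rdname tidy.sim_result
#' @exportS3Method generics::glance
glance.sim_result <- function(x, ...) {
  tibble(geometry = x$geom$name, n_voxels = x$geom$n_voxels,
         duration_ms = x$cfg$duration, dt_ms = x$cfg$dt,
         D_mm2_ms = x$cfg$D, n_snapshots = length(x$snap_t),
         elapsed_s = unname(x$elapsed))
}

#' Tidy a PSD
#'
#' @param x A `psd_result`.
#' @param ... Unused.
#' @return Tibble `freq_hz`, `power`.
#' @exportS3Method generics::tidy
tidy.psd_result <- function(x, ...) tibble(freq_hz = x$freq_hz, power = x$power)

#' @rdname tidy.psd_result
#' @exportS3Method generics::glance
glance.psd_result <- function(x, ...) {
  pk <- attr(x, "peaks")
  tibble(dominant_hz = attr(x, "dominant_hz"),
         resolution_hz = attr(x, "resolution_hz"),
         n_peaks_20pct = sum(pk$rel_power >= 0.2))
}

#' Tidy a recurrence map
#'
#' @param x A `recurrence_map`.
#' @param ... Unused.
#' @return Tibble `cl_ms`, `cl_next_ms`.
#' @exportS3Method generics::tidy
tidy.recurrence_map <- function(x, ...)
  tibble(cl_ms = x$cl_ms, cl_next_ms = x$cl_next_ms)

#' @rdname tidy.recurrence_map
#' @exportS3Method generics::glance
glance.recurrence_map <- function(x, ...) {
  cls <- attr(x, "cycle_lengths")
  tibble(mean_cl_ms = mean(cls), sd_cl_ms = sd(cls), n_cycles = length(cls),
         lag1_correlation = if (length(cls) > 2)
           stats::cor(cls[-length(cls)], cls[-1]) else NA_real_)
}

#' Tidy a drift classification
#'
#' @param x A `drift_class`.
#' @param ... Unused.
#' @return One-row tibble of the drift metrics.
#' @exportS3Method generics::tidy
tidy.drift_class <- function(x, ...) {
  tibble(classification = x$classification, displacement_mm = x$displacement,
         rate_mm_s = x$rate, scaled_displacement_mm = x$scaled_displacement,
         dir_x = x$direction[1], dir_y = x$direction[2],
         dir_z = x$direction[3], path_ratio = x$path_ratio)
}

#' Tidy a scenario result
#'
#' @param x A `scenario_result`.
#' @param ... Unused.
#' @return The tip trace tibble.
#' @exportS3Method generics::tidy
tidy.scenario_result <- function(x, ...) x$tips

#' @rdname tidy.scenario_result
#' @exportS3Method generics::glance
glance.scenario_result <- function(x, ...) x$summary
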