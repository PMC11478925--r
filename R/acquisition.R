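#' Acquisition parameters for a single-voxel PRESS measurement
#'
#' Describes a 1.5 T short-echo PRESS acquisition: echo/repetition time,
#' number of complex points, filter bandwidth and voxel geometry. The
#' transmitter frequency is derived from the field strength
#' (about 63.87 MHz for protons at 1.5 T) and the spectral resolution in
#' Hz per point from `bandwidth_hz / n_points` (1.024 Hz at the defaults).
#'
#' @param field_strength_t Static field in tesla.
#' @param te_ms Echo time in milliseconds.
#' @param tr_ms Repetition time in milliseconds.
#' @param n_points Number of complex points acquired (1024 or 2048 typical).
#' @param bandwidth_hz Filter bandwidth in Hz; defaults to `1.024 * n_points`
#'   so that the per-point resolution is 1.024 Hz.
#' @param voxel_edge_cm Cubic voxel edge length in cm (1.5 or 2.0).
#' @param n_averages Number of water-suppressed repetitions (128 or 256).
#' @param n_water_averages Number of unsuppressed water-reference repetitions.
#' @return An object of class `mrs_acq_params` (a named list) with the
#'   derived fields `transmitter_mhz`, `hz_per_point` and `dwell_s`.
#' @examples
#' p <- acq_params()
#' p$hz_per_point
#' @export
acq_params <- function(field_strength_t = 1.5,
                       te_ms = 30,
                       tr_ms = 1500,
                       n_points = 2048,
                       bandwidth_hz = 1.024 * n_points,
                       voxel_edge_cm = 2.0,
                       n_averages = 128,
                       n_water_averages = 8) {
  stopifnot(n_points > 0, te_ms > 0, tr_ms > 0, bandwidth_hz > 0)
  hz_per_point <- bandwidth_hz / n_points
  p <- structure(list(
    field_strength_t = field_strength_t,
    transmitter_mhz = GAMMA_1H_MHZ_PER_T * field_strength_t,
    te_ms = te_ms,
    tr_ms = tr_ms,
    n_points = as.integer(n_points),
    bandwidth_hz = bandwidth_hz,
    hz_per_point = hz_per_point,
    dwell_s = 1 / bandwidth_hz,
    voxel_edge_cm = voxel_edge_cm,
    n_averages = n_averages,
    n_water_averages = n_water_averages
  ), class = "mrs_acq_params")
  if (abs(p$hz_per_point - bandwidth_hz / n_points) > 0.01 * p$hz_per_point) {
    abort("inconsistent hz_per_point")
  }
  p
}

#' @export
print.mrs_acq_params <- function(x, ...) {
  cat(sprintf(
    "<mrs_acq_params> %.1f T (%.3f MHz), TE %g ms, TR %g ms, %d pts @ %.3f Hz/pt, voxel %g cm\n",
    x$field_strength_t, x$transmitter_mhz, x$te_ms, x$tr_ms,
    x$n_points, x$hz_per_point, x$voxel_edge_cm
  ))
  invisible(x)
}

# time axis in seconds for an acquisition
acq_time_axis <- function(params) {
  (seq_len(params$n_points) - 1) * params$dwell_s
}
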