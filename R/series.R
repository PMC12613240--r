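#' Saturation scheme
#'
#' Pulsed presaturation parameters of a CEST series. The default matches the
#' low-power whole-Z-spectrum protocol: 148 Gaussian-shaped pulses of 20 ms
#' at 80% duty cycle (total saturation time 3.7 s). The conventional APTw
#' scheme uses 4 rectangular pulses of 200 ms at 95% duty cycle and 2 uT.
#'
#' @param pulse_shape `"gaussian"` or `"rectangular"`.
#' @param n_pulses number of RF pulses.
#' @param pulse_duration_s single-pulse duration in seconds.
#' @param duty_cycle duty cycle in (0, 1].
#' @param nominal_B1_uT nominal mean saturation amplitude in microtesla.
#' @param total_sat_time_s total saturation time; must agree with
#'   `n_pulses * pulse_duration_s / duty_cycle` within 5%.
#' @return An object of class `cest_scheme`.
#' @export
saturation_scheme <- function(pulse_shape = c("gaussian", "rectangular"),
                              n_pulses = 148L, pulse_duration_s = 0.020,
                              duty_cycle = 0.80, nominal_B1_uT = 0.6,
                              total_sat_time_s = n_pulses * pulse_duration_s / duty_cycle) {
  pulse_shape <- match.arg(pulse_shape)
  stopifnot(n_pulses >= 1, pulse_duration_s > 0,
            duty_cycle > 0, duty_cycle <= 1, nominal_B1_uT > 0)
  implied <- n_pulses * pulse_duration_s / duty_cycle
  if (abs(total_sat_time_s - implied) / implied > 0.05)
    stop(sprintf("total_sat_time_s (%.3f) inconsistent with n_pulses*t_p/DC (%.3f)",
                 total_sat_time_s, implied))
  structure(list(pulse_shape = pulse_shape, n_pulses = as.integer(n_pulses),
                 pulse_duration_s = pulse_duration_s, duty_cycle = duty_cycle,
                 nominal_B1_uT = nominal_B1_uT,
                 total_sat_time_s = total_sat_time_s),
            class = "cest_scheme")
}

#' Saturation frequency-offset grid
#'
#' Offsets are stored in acquisition order so normalization frames can be
#' interpolated by acquisition index; a sorted view is derived on demand.
#' Entries at the normalization offset (-300 ppm) are flagged as M0 frames.
#'
#' @param offsets_ppm numeric vector in acquisition order.
#' @param m0_flags logical vector; defaults to `offsets_ppm == -300`.
#' @param repetition_index integer per entry (1 for first occurrence of an
#'   offset, 2 for its repeat, ...); derived when omitted.
#' @param max_abs_ppm non-M0 offsets must lie within this range (default 250).
#' @return An object of class `cest_offsets`.
#' @export
offset_grid <- function(offsets_ppm, m0_flags = offsets_ppm == -300,
                        repetition_index = NULL, max_abs_ppm = 250) {
  stopifnot(length(m0_flags) == length(offsets_ppm))
  if (!any(m0_flags)) stop("offset grid must contain at least one M0 frame")
  if (any(abs(offsets_ppm[!m0_flags]) > max_abs_ppm + 1e-9))
    stop("non-M0 offsets must lie within +/-", max_abs_ppm, " ppm")
  if (is.null(repetition_index)) {
    repetition_index <- integer(length(offsets_ppm))
    for (i in seq_along(offsets_ppm))
      repetition_index[i] <- sum(offsets_ppm[seq_len(i)] == offsets_ppm[i])
  }
  structure(list(offsets_ppm = as.numeric(offsets_ppm),
                 m0_flags = as.logical(m0_flags),
                 repetition_index = as.integer(repetition_index)),
            class = "cest_offsets")
}

#' @export
length.cest_offsets <- function(x) length(x$offsets_ppm)

# sorted unique non-M0 offsets
sorted_offsets <- function(grid) sort(unique(grid$offsets_ppm[!grid$m0_flags]))

#' CEST saturation series
#'
#' The raw object all processing stages consume: a 4D signal volume indexed
#' by acquisition frame, together with its geometry, offset grid, saturation
#' scheme and brain mask.
#'
#' @param signal 4D numeric array (x, y, z, frame), values >= 0.
#' @param geometry `cest_geometry`.
#' @param grid `cest_offsets`; its length must equal `dim(signal)[4]`.
#' @param scheme `cest_scheme`.
#' @param mask 3D logical array (defaults to all `TRUE`).
#' @param recovery_times_s optional numeric vector (saturation-recovery
#'   series only): per-frame recovery delay in seconds.
#' @return An object of class `cest_series`.
#' @export
cest_series <- function(signal, geometry, grid, scheme, mask = NULL,
                        recovery_times_s = NULL) {
  stopifnot(inherits(geometry, "cest_geometry"), inherits(grid, "cest_offsets"),
            inherits(scheme, "cest_scheme"))
  dims <- dim(signal)
  if (length(dims) != 4L)
    stop("signal must be a 4D array (x, y, z, acquisition frame)")
  if (!identical(dims[1:3], as.integer(geometry$matrix_dims)))
    stop("signal spatial dimensions do not match geometry")
  if (dims[4] != length(grid))
    stop(sprintf("signal has %d frames but the offset grid lists %d entries",
                 dims[4], length(grid)))
  if (is.null(mask)) mask <- array(TRUE, dims[1:3])
  stopifnot(identical(dim(mask), dims[1:3]))
  msk <- as.logical(mask)
  if (any(!is.finite(signal[rep(msk, dims[4])])))
    stop("masked voxels must have finite signal in every frame")
  if (!is.null(recovery_times_s))
    stopifnot(length(recovery_times_s) == dims[4])
  structure(list(signal = signal, geometry = geometry, grid = grid,
                 scheme = scheme, mask = array(msk, dims[1:3]),
                 recovery_times_s = recovery_times_s),
            class = "cest_series")
}

#' @export
print.cest_series <- function(x, ...) {
  cat(sprintf("<cest_series> %d frames (%d M0), B1 = %.2g uT, %s pulses, %d masked voxels\n",
              length(x$grid), sum(x$grid$m0_flags), x$scheme$nominal_B1_uT,
              x$scheme$pulse_shape, sum(x$mask)))
  invisible(x)
}

#' Field maps (B0, relative B1, T1)
#'
#' @param b0_ppm 3D numeric array: water-shift offset in ppm.
#' @param rel_b1 3D numeric array: actual/nominal B1 (1 = nominal).
#' @param t1_s 3D numeric array: longitudinal relaxation time in seconds.
#' @param mask 3D logical array over which the invariants are enforced.
#' @return An object of class `cest_fieldmaps`; unknown maps may be `NULL`.
#' @export
field_maps <- function(b0_ppm = NULL, rel_b1 = NULL, t1_s = NULL, mask = NULL) {
  if (!is.null(mask) && !is.null(rel_b1)) {
    v <- rel_b1[mask]
    if (any(!is.finite(v) | v <= 0))
      stop("rel_b1 must be finite and positive inside the mask")
  }
  if (!is.null(mask) && !is.null(t1_s)) {
    v <- t1_s[mask]
    if (any(!is.finite(v) | v <= 0.05 | v >= 10))
      stop("t1_s must lie in (0.05, 10) s inside the mask")
  }
  structure(list(b0_ppm = b0_ppm, rel_b1 = rel_b1, t1_s = t1_s, mask = mask),
            class = "cest_fieldmaps")
}
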