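# CEST contrast computation: MTR_Rex, LD, AREX, APTw asymmetry with fluid
# suppression, and the two-point B1 correction.

CONTRAST_NAMES <- c("APTw", "APTw_fs",
                    "MTRRex_amide", "MTRRex_rNOE", "MTRRex_ssMT",
                    "LD_amide", "LD_rNOE", "LD_ssMT",
                    "AREX_amide", "AREX_rNOE", "AREX_ssMT")

#' Contrast volume container
#'
#' @param name one of the canonical contrast names (`APTw`, `APTw_fs`,
#'   `MTRRex_*`, `LD_*`, `AREX_*`).
#' @param values 3D numeric array (`NA` where undefined).
#' @param mask 3D logical.
#' @param b1_reference_uT the B1 the contrast refers to (0.7 for corrected
#'   MTR_Rex-family maps, 2 for APTw).
#' @param geometry `cest_geometry`.
#' @return object of class `cest_contrast`. Units: % for the APTw family,
#'   dimensionless for MTR_Rex and LD, 1/s for AREX.
#' @export
contrast_volume <- function(name, values, mask, b1_reference_uT, geometry) {
  name <- match.arg(name, CONTRAST_NAMES)
  stopifnot(identical(dim(values), dim(mask)))
  structure(list(name = name, values = values, mask = mask,
                 b1_reference_uT = b1_reference_uT, geometry = geometry),
            class = "cest_contrast")
}

#' Relaxation-compensated MTR_Rex contrast
#'
#' `1/z_lab - 1/z_ref`. Non-positive inputs yield `NA` (undefined).
#' @param z_lab,z_ref labeled / reference Z values (vectorized).
#' @return numeric, same shape as the inputs.
#' @export
mtr_rex <- function(z_lab, z_ref) {
  out <- 1 / z_lab - 1 / z_ref
  out[!is.na(z_lab) & (z_lab <= 0 | z_ref <= 0)] <- NA_real_
  out
}

#' Lorentzian-difference contrast
#'
#' `z_ref - z_lab` (not relaxation-compensated).
#' @inheritParams mtr_rex
#' @export
ld <- function(z_lab, z_ref) z_ref - z_lab

#' Apparent exchange-dependent relaxation
#'
#' `MTR_Rex / T1`, in 1/s. Non-positive T1 yields `NA`.
#' @param mtrrex MTR_Rex value(s).
#' @param t1_s T1 in seconds.
#' @export
arex <- function(mtrrex, t1_s) {
  out <- mtrrex / t1_s
  out[!is.na(t1_s) & t1_s <= 0] <- NA_real_
  out
}

#' APTw asymmetry contrast from a high-power Z-stack
#'
#' Replicate offsets are averaged (at normalization); per side, Z is fitted
#' with a quadratic in offset over that side's cluster and evaluated at
#' `sign * 3.5 + b0` (B0-corrected evaluation). The contrast is
#' `[Z(-3.5) - Z(+3.5)] * 100` in percent. Voxels missing one side or with
#' an invalid B0 entry are `NA`.
#'
#' @param zs `cest_zstack` of the APTw series (normalized).
#' @param b0_ppm 3D numeric array (water shift, ppm).
#' @return `cest_contrast` named `"APTw"`; the Z(-3.5 ppm) evaluation is
#'   attached as attribute `"z_minus35"` for fluid suppression.
#' @export
aptw_contrast <- function(zs, b0_ppm) {
  stopifnot(inherits(zs, "cest_zstack"))
  w <- zs$offsets_ppm
  neg <- which(w < 0); pos <- which(w > 0)
  if (length(neg) < 3 || length(pos) < 3)
    stop("APTw evaluation needs at least 3 offsets per side")
  dims <- dim(zs$z)
  zmat <- matrix(zs$z, nrow = prod(dims[1:3]))
  vox <- which(zs$mask)
  # per-side quadratic fits share their design matrix across voxels
  side_eval <- function(cols, at) {
    X <- cbind(1, w[cols], w[cols]^2)
    P <- solve(crossprod(X), t(X))          # 3 x n_side projector
    coef <- zmat[vox, cols, drop = FALSE] %*% t(P)
    coef[, 1] + coef[, 2] * at + coef[, 3] * at^2
  }
  shift <- b0_ppm[vox]
  zneg <- side_eval(neg, -3.5 + shift)
  zpos <- side_eval(pos, 3.5 + shift)
  bad <- !is.finite(shift)
  zneg[bad] <- NA_real_; zpos[bad] <- NA_real_
  vals <- array(NA_real_, dims[1:3])
  vals[vox] <- (zneg - zpos) * 100
  zm <- array(NA_real_, dims[1:3])
  zm[vox] <- zneg
  out <- contrast_volume("APTw", vals, zs$mask, 2, zs$geometry)
  attr(out, "z_minus35") <- zm
  out
}

#' Fluid-suppressed APTw contrast
#'
#' `APTw * (0.35 / Z(-3.5 ppm))^2`: voxels with fluid-like (high) Z at
#' -3.5 ppm are down-weighted; Z(-3.5) = 0.35 leaves the contrast unchanged.
#' Non-positive Z(-3.5) yields `NA`.
#'
#' @param aptw_vol `cest_contrast` `"APTw"` (or numeric array).
#' @param z_minus35 3D array of Z(-3.5 ppm); defaults to the attribute
#'   attached by [aptw_contrast()].
#' @param z_ref_const the reference constant (default 0.35).
#' @return `cest_contrast` named `"APTw_fs"`.
#' @export
fluid_suppress <- function(aptw_vol, z_minus35 = attr(aptw_vol, "z_minus35"),
                           z_ref_const = 0.35) {
  vals <- if (inherits(aptw_vol, "cest_contrast")) aptw_vol$values else aptw_vol
  if (is.null(z_minus35)) stop("z_minus35 is required")
  fac <- (z_ref_const / z_minus35)^2
  fac[!is.na(z_minus35) & z_minus35 <= 0] <- NA_real_
  out_vals <- vals * fac
  if (inherits(aptw_vol, "cest_contrast"))
    contrast_volume("APTw_fs", out_vals, aptw_vol$mask, aptw_vol$b1_reference_uT,
                    aptw_vol$geometry)
  else out_vals
}

#' Two-point B1 correction of a contrast map
#'
#' Per voxel, the contrast measured at the two actual saturation amplitudes
#' `rel_b1 * (nominal_low, nominal_high)` defines a line that is evaluated
#' at the target B1 (interpolating or extrapolating as the voxel's relative
#' B1 dictates). Degenerate pairs (equal actual B1) yield `NA`.
#'
#' @param c_low,c_high `cest_contrast` maps of the same contrast acquired at
#'   the low / high nominal B1.
#' @param rel_b1 3D numeric array.
#' @param nominal_low_uT,nominal_high_uT nominal amplitudes (default 0.6 and
#'   0.9 uT).
#' @param target_uT reconstruction B1 (default 0.7 uT).
#' @return `cest_contrast` tagged with `b1_reference_uT = target_uT`.
#' @export
b1_correct_two_point <- function(c_low, c_high, rel_b1,
                                 nominal_low_uT = 0.6, nominal_high_uT = 0.9,
                                 target_uT = 0.7) {
  stopifnot(inherits(c_low, "cest_contrast"), inherits(c_high, "cest_contrast"))
  if (!identical(c_low$name, c_high$name))
    stop("contrast names differ: ", c_low$name, " vs ", c_high$name)
  if (!geometry_equal(c_low$geometry, c_high$geometry))
    stop("contrast geometries differ")
  b1_lo <- rel_b1 * nominal_low_uT
  b1_hi <- rel_b1 * nominal_high_uT
  slope <- (c_high$values - c_low$values) / (b1_hi - b1_lo)
  vals <- c_low$values + slope * (target_uT - b1_lo)
  vals[abs(b1_hi - b1_lo) < 1e-12] <- NA_real_
  contrast_volume(c_low$name, vals, c_low$mask & c_high$mask, target_uT,
                  c_low$geometry)
}
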