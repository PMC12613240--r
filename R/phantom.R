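# Synthetic multi-subject brain-slab phantom.
#
# The generator forward-models every acquisition the pipeline consumes (two
# low-power whole-Z-spectrum series, a high-power APTw series, WASABI, and a
# saturation-recovery T1 series) on an ellipsoidal GM/WM slab whose regional
# contrast ground truth is parameterized from published 3-T group reference
# values. Pool amplitudes are inverted per voxel so that the analytic
# MTR_Rex at the voxel's actual B1 matches the (linearly B1-scaled) regional
# truth, which makes the two-point B1 correction exact by construction.

REGIONS <- c("FL", "ParTem", "OC", "Ccs")
TISSUES <- c("GM", "WM")

#' ROI label table
#'
#' Label codes 1-8 for the eight (tissue, region) ROIs; 0 is background.
#' @return data.frame with `code`, `tissue`, `region`.
#' @export
roi_table <- function() {
  data.frame(code = 1:8,
             tissue = rep(TISSUES, each = 4),
             region = rep(REGIONS, 2),
             stringsAsFactors = FALSE)
}

#' Regional ground-truth presets
#'
#' Group reference values (mean of per-subject ROI medians over 10 healthy
#' volunteers at 3 T) for APTw (%), the B1-corrected MTR_Rex amide, rNOE and
#' ssMT contrasts (at 0.7 uT), and T1 (s), per tissue and region, with the
#' reported between-subject SDs used as inter-subject jitter.
#'
#' @return data.frame with one row per (tissue, region), columns `aptw_pct`,
#'   `mtrrex_amide`, `mtrrex_rnoe`, `mtrrex_ssmt`, `t1_s` and their `sd_*`
#'   counterparts.
#' @export
regional_truth_presets <- function() {
  tab <- rbind(
    # tissue region aptw  amide  rnoe  ssmt  t1    sd_aptw sd_am sd_rn sd_mt sd_t1
    c(0.16, 0.19,  0.29, 0.34, 1.49, 0.34, 0.01, 0.02, 0.01, 0.05),
    c(0.44, 0.205, 0.31, 0.38, 1.46, 0.53, 0.01, 0.01, 0.01, 0.03),
    c(0.14, 0.21,  0.31, 0.38, 1.44, 0.59, 0.01, 0.01, 0.01, 0.04),
    c(0.98, 0.23,  0.31, 0.40, 1.42, 0.68, 0.01, 0.02, 0.02, 0.06),
    c(-0.51, 0.17, 0.30, 0.41, 1.14, 0.35, 0.01, 0.02, 0.02, 0.06),
    c(0.13, 0.19,  0.31, 0.42, 1.21, 0.41, 0.01, 0.01, 0.01, 0.03),
    c(0.01, 0.19,  0.31, 0.43, 1.20, 0.56, 0.01, 0.01, 0.01, 0.04),
    c(0.64, 0.20,  0.31, 0.42, 1.20, 0.57, 0.01, 0.01, 0.03, 0.05))
  out <- cbind(roi_table(), as.data.frame(tab))
  names(out)[4:13] <- c("aptw_pct", "mtrrex_amide", "mtrrex_rnoe",
                        "mtrrex_ssmt", "t1_s", "sd_aptw_pct",
                        "sd_mtrrex_amide", "sd_mtrrex_rnoe",
                        "sd_mtrrex_ssmt", "sd_t1_s")
  out
}

#' Phantom configuration
#'
#' @param geometry slab geometry (default 48 x 40 x 8 voxels of
#'   1.7 x 1.7 x 3 mm).
#' @param n_subjects cohort size.
#' @param seed master seed; per-subject streams are derived from it.
#' @param noise_sd_frac Gaussian noise SD as a fraction of M0.
#' @param m0_drift_frac linear signal drift between the first and last frame
#'   of each saturation series.
#' @param b0_amplitude_ppm amplitude of the smooth B0 field.
#' @param relb1_range range of the relative-B1 field (lowest values
#'   anterior, in the frontal lobe).
#' @param jitter_frac scales the inter-subject truth jitter (0 disables).
#' @param pool_fwhm FWHM (ppm) of the DS, amide, rNOE and ssMT pools.
#' @param ds_amplitude,plateau_gm,plateau_wm,z0 fixed line-shape parameters.
#' @param b1_ref_uT reference B1 at which the truth contrasts are stated.
#' @param aptw_anchor_gm,aptw_anchor_wm Z(-3.5 ppm) operating points.
#' @param aptw_slope,aptw_curv per-side slope (1/ppm) and curvature
#'   (1/ppm^2) of the APTw-series Z profile.
#' @param m0_au equilibrium signal level (arbitrary units).
#' @return list of class `cest_phantom_config`.
#' @export
phantom_config <- function(geometry = volume_geometry(c(48L, 40L, 8L), c(1.7, 1.7, 3)),
                           n_subjects = 10L, seed = 42L,
                           noise_sd_frac = 0.007, m0_drift_frac = 0.02,
                           b0_amplitude_ppm = 0.05,
                           relb1_range = c(0.74, 1.05), jitter_frac = 1,
                           pool_fwhm = c(DS = 1.4, amide = 1.0, rNOE = 3.5, ssMT = 25),
                           ds_amplitude = 0.85, plateau_gm = 0.07,
                           plateau_wm = 0.10, z0 = 1,
                           b1_ref_uT = 0.7,
                           aptw_anchor_gm = 0.55, aptw_anchor_wm = 0.50,
                           aptw_slope = 0.05, aptw_curv = 0.02,
                           m0_au = 1000) {
  stopifnot(inherits(geometry, "cest_geometry"), n_subjects >= 1,
            noise_sd_frac >= 0, length(relb1_range) == 2,
            relb1_range[1] > 0, diff(relb1_range) >= 0)
  structure(as.list(environment()), class = "cest_phantom_config")
}

# low-power whole-Z-spectrum offsets: 57 unequally spaced within +/-250 ppm,
# dense around the exchange resonances, framed by two M0 frames at -300
lowpower_offsets <- function() {
  wings <- c(250, 175, 100, 50, 30, 20, 12, 8)
  core <- seq(5, 0.25, by = -0.25)          # dense around the resonances
  half <- sort(c(wings, core))
  offs <- sort(c(-half, 0, half))
  stopifnot(length(offs) == 57L)
  c(-300, offs, -300)
}

# APTw offsets: one leading M0, then pairs around +/-3.5 ppm with the
# leading sign alternating between pairs so that a linear signal drift
# cancels (to first order) in the asymmetry
aptw_offsets <- function() {
  mags <- c(4, 3.75, 3.75, 3.5, 3.5, 3.25, 3.25, 3)
  pairs <- lapply(seq_along(mags), function(i) {
    if (i %% 2) c(-mags[i], mags[i]) else c(mags[i], -mags[i])
  })
  c(-300, unlist(pairs))
}

wasabi_offsets <- function() c(-300, seq(-2, 2, length.out = 31))

DEFAULT_T1REC_TIMES <- c(0.3, 0.8, 1.5, 2.5, 4.0)

#' Build the phantom ROI label volume
#'
#' Ellipsoidal brain slab with a WM core and GM shell, partitioned anterior
#' to posterior into frontal (FL), parietotemporal (ParTem) and occipital
#' (OC) thirds, with a small posterior-medial calcarine (Ccs) wedge carved
#' out of the occipital band. Every ROI must reach `min_voxels`.
#'
#' @param config `cest_phantom_config`.
#' @param min_voxels per-ROI voxel floor (default 100).
#' @return 3D integer label array (codes of [roi_table()], 0 = background).
#' @export
make_labels <- function(config = phantom_config(), min_voxels = 100L) {
  d <- config$geometry$matrix_dims
  cx <- (d + 1) / 2
  r <- c(0.48, 0.475, 0.475) * d            # ellipsoid semi-axes in voxels
  ix <- slot_grid(d)
  dx <- (ix$x - cx[1]) / r[1]
  dy <- (ix$y - cx[2]) / r[2]
  dz <- (ix$z - cx[3]) / r[3]
  rho2 <- dx^2 + dy^2 + dz^2
  brain <- rho2 <= 1
  wm <- rho2 <= 0.85^2
  region <- ifelse(dy < -1 / 3, 1L, ifelse(dy < 0.18, 2L, 3L))
  ccs <- dy >= 0.48 & abs(dx) <= 0.32
  region[ccs] <- 4L
  labels <- integer(prod(d))
  labels[brain & !wm] <- region[brain & !wm]          # GM codes 1..4
  labels[wm] <- region[wm] + 4L                       # WM codes 5..8
  labels <- array(labels, d)
  counts <- tabulate(labels, nbins = 8L)
  if (any(counts < min_voxels)) {
    tab <- roi_table()
    bad <- which(counts < min_voxels)[1]
    stop(sprintf("geometry too small: ROI %s-%s has %d voxels (< %d)",
                 tab$tissue[bad], tab$region[bad], counts[bad], min_voxels))
  }
  labels
}

slot_grid <- function(d) {
  list(x = array(rep(seq_len(d[1]), times = d[2] * d[3]), d),
       y = array(rep(rep(seq_len(d[2]), each = d[1]), times = d[3]), d),
       z = array(rep(seq_len(d[3]), each = d[1] * d[2]), d))
}

# smooth true field maps: B0 as a low-order polynomial bounded by the
# configured amplitude; relative B1 lowest anteriorly (frontal lobe), rising
# towards the posterior with some lateral/through-plane modulation
make_true_fields <- function(config, labels) {
  d <- config$geometry$matrix_dims
  cx <- (d + 1) / 2
  r <- c(0.48, 0.475, 0.475) * d
  ix <- slot_grid(d)
  dx <- (ix$x - cx[1]) / r[1]
  dy <- (ix$y - cx[2]) / r[2]
  dz <- (ix$z - cx[3]) / r[3]
  amp <- config$b0_amplitude_ppm
  b0 <- amp * (0.6 * dx * dy + 0.4 * (dz^2 - 0.5))
  b0 <- pmin(pmax(b0, -amp), amp)
  rb <- config$relb1_range
  ty <- pmin(pmax((dy + 1) / 2, 0), 1)       # 0 anterior -> 1 posterior
  mod <- 0.6 + 0.4 * pmin(dx^2 + dz^2, 1)
  rel_b1 <- rb[1] + diff(rb) * ty^2 * mod
  rel_b1 <- pmin(pmax(rel_b1, rb[1]), rb[2])
  list(b0_ppm = array(b0, d), rel_b1 = array(rel_b1, d))
}

# unit-amplitude Lorentzian
lorentz1 <- function(dw, center, fwhm) {
  g <- fwhm / 2
  g^2 / (g^2 + (dw - center)^2)
}

#' Invert pool amplitudes from target MTR_Rex contrasts
#'
#' Given target MTR_Rex values at the amide, rNOE and ssMT centres, solve
#' for the three pool amplitudes such that the analytic four-pool model
#' reproduces every target simultaneously. Each fixed-point sweep updates
#' one amplitude in closed form (the pool's own Lorentzian is 1 at its
#' centre, so `A = Z_ref - 1 / (target + 1/Z_ref)`), holding the others;
#' sweeps repeat until the forward MTR_Rex matches all targets within
#' `tol`. Vectorized over target rows.
#'
#' @param targets numeric matrix (n x 3) or length-3 vector of target
#'   MTR_Rex values, columns amide, rNOE, ssMT.
#' @param pool_fwhm named FWHMs as in [phantom_config()].
#' @param ds_amplitude,plateau,z0 fixed DS/plateau parameters.
#' @param tol convergence tolerance on the forward contrasts.
#' @return matrix (n x 3) of amplitudes in [0, 1).
#' @export
invert_pool_amplitudes <- function(targets,
                                   pool_fwhm = c(DS = 1.4, amide = 1.0,
                                                 rNOE = 3.5, ssMT = 25),
                                   ds_amplitude = 0.85, plateau = 0.10,
                                   z0 = 1, tol = 1e-9) {
  if (is.null(dim(targets))) targets <- matrix(targets, nrow = 1)
  stopifnot(ncol(targets) == 3, all(is.finite(targets)), all(targets >= 0))
  cen <- POOL_CENTERS[c("amide", "rNOE", "ssMT")]
  # cross-talk of pool j (unit amplitude) at the centre of pool i
  xt <- outer(seq_along(cen), seq_along(cen), function(i, j)
    lorentz1(cen[i], cen[j], pool_fwhm[c("amide", "rNOE", "ssMT")][j]))
  ds_at <- ds_amplitude * lorentz1(cen, 0, pool_fwhm[["DS"]])
  base <- z0 - plateau - ds_at                 # length 3, recycled by column
  n <- nrow(targets)
  A <- matrix(0, n, 3)
  for (sweep in 1:200) {
    for (i in 1:3) {
      others <- setdiff(1:3, i)
      zref <- base[i] - A[, others, drop = FALSE] %*% xt[i, others]
      zlab <- 1 / (targets[, i] + 1 / zref)
      A[, i] <- zref - zlab
    }
    # forward check
    err <- 0
    for (i in 1:3) {
      others <- setdiff(1:3, i)
      zref <- base[i] - A[, others, drop = FALSE] %*% xt[i, others]
      zlab <- zref - A[, i]
      err <- max(err, max(abs(1 / zlab - 1 / zref - targets[, i])))
    }
    if (err < tol) break
  }
  if (err >= tol)
    stop("pool-amplitude inversion did not converge (targets unreachable?)")
  A[A < 0 & A > -1e-9] <- 0                    # clamp roundoff at zero targets
  zlab_min <- rep(Inf, n)
  for (i in 1:3) {
    others <- setdiff(1:3, i)
    zref <- base[i] - A[, others, drop = FALSE] %*% xt[i, others]
    zlab_min <- pmin(zlab_min, zref - A[, i])
  }
  if (any(A < 0) || any(A >= 1) || any(zlab_min <= 0))
    stop("no amplitude solution in [0, 1): target contrast unreachable for given widths")
  colnames(A) <- c("amide", "rNOE", "ssMT")
  A
}

# jitter the regional presets for one subject
jitter_truth <- function(presets, jitter_frac) {
  truth <- presets
  for (f in c("aptw_pct", "mtrrex_amide", "mtrrex_rnoe", "mtrrex_ssmt", "t1_s")) {
    sd <- presets[[paste0("sd_", f)]] * jitter_frac
    truth[[f]] <- presets[[f]] + stats::rnorm(nrow(presets), 0, sd)
  }
  truth$mtrrex_amide <- pmax(truth$mtrrex_amide, 0)
  truth$mtrrex_rnoe <- pmax(truth$mtrrex_rnoe, 0)
  truth$mtrrex_ssmt <- pmax(truth$mtrrex_ssmt, 0)
  truth$t1_s <- pmax(truth$t1_s, 0.2)
  truth
}

# per-frame linear drift factors for a series of n frames
drift_factors <- function(n, drift_frac) {
  if (n == 1L) return(1)
  1 - drift_frac * (seq_len(n) - 1) / (n - 1)
}

# evaluate the low-power forward model for all masked voxels of one series
simulate_lowpower <- function(config, labels, truth, fields, nominal_b1) {
  d <- config$geometry$matrix_dims
  offs_all <- lowpower_offsets()
  grid <- offset_grid(offs_all)
  sat <- !grid$m0_flags
  w <- grid$offsets_ppm[sat]
  nfrm <- length(offs_all)
  vox <- which(labels > 0)
  z <- matrix(NA_real_, length(vox), length(w))
  scale_fac <- fields$rel_b1[vox] * nominal_b1 / config$b1_ref_uT
  for (code in 1:8) {
    rows <- which(labels[vox] == code)
    if (!length(rows)) next
    tr <- truth[truth$code == code, ]
    plateau <- if (tr$tissue == "GM") config$plateau_gm else config$plateau_wm
    tg <- cbind(tr$mtrrex_amide, tr$mtrrex_rnoe, tr$mtrrex_ssmt)[rep(1, length(rows)), , drop = FALSE] *
      scale_fac[rows]
    A <- invert_pool_amplitudes(tg, config$pool_fwhm, config$ds_amplitude,
                                plateau, config$z0)
    dw0 <- fields$b0_ppm[vox][rows]
    for (j in seq_along(w)) {
      x <- w[j] - dw0                       # B0-shifted evaluation offset
      zj <- config$z0 - plateau -
        config$ds_amplitude * lorentz1(x, 0, config$pool_fwhm[["DS"]]) -
        A[, 1] * lorentz1(x, 3.5, config$pool_fwhm[["amide"]]) -
        A[, 2] * lorentz1(x, -3.5, config$pool_fwhm[["rNOE"]]) -
        A[, 3] * lorentz1(x, -2.5, config$pool_fwhm[["ssMT"]])
      z[rows, j] <- zj
    }
  }
  dfac <- drift_factors(nfrm, config$m0_drift_frac)
  sig <- matrix(0, prod(d), nfrm)
  sig[vox, which(sat)] <- z
  sig[vox, which(!sat)] <- 1
  sig <- sweep(sig, 2, config$m0_au * dfac, `*`)
  scheme <- saturation_scheme("gaussian", 148L, 0.020, 0.80, nominal_b1)
  cest_series(array(sig, c(d, nfrm)), config$geometry, grid, scheme,
              mask = array(labels > 0, d))
}

simulate_aptw <- function(config, labels, truth, fields) {
  d <- config$geometry$matrix_dims
  offs_all <- aptw_offsets()
  grid <- offset_grid(offs_all)
  sat <- !grid$m0_flags
  w <- grid$offsets_ppm[sat]
  vox <- which(labels > 0)
  anchor <- ifelse(truth$tissue[labels[vox]] == "GM",
                   config$aptw_anchor_gm, config$aptw_anchor_wm)
  aptw <- truth$aptw_pct[labels[vox]] / 100
  dw0 <- fields$b0_ppm[vox]
  z <- matrix(NA_real_, length(vox), length(w))
  for (j in seq_along(w)) {
    x <- w[j] - dw0
    xi <- abs(x) - 3.5                      # distance from the pool centre
    zneg <- anchor + config$aptw_slope * xi + config$aptw_curv * xi^2
    zpos <- (anchor - aptw) + config$aptw_slope * xi + config$aptw_curv * xi^2
    z[, j] <- ifelse(x < 0, zneg, zpos)
  }
  nfrm <- length(offs_all)
  dfac <- drift_factors(nfrm, config$m0_drift_frac)
  sig <- matrix(0, prod(d), nfrm)
  sig[vox, which(sat)] <- z
  sig[vox, which(!sat)] <- 1
  sig <- sweep(sig, 2, config$m0_au * dfac, `*`)
  scheme <- saturation_scheme("rectangular", 4L, 0.200, 0.95, 2)
  cest_series(array(sig, c(d, nfrm)), config$geometry, grid, scheme,
              mask = array(labels > 0, d))
}

simulate_wasabi <- function(config, labels, fields, t_p = 0.005,
                            nominal_b1 = 3.7) {
  d <- config$geometry$matrix_dims
  offs_all <- wasabi_offsets()
  grid <- offset_grid(offs_all, max_abs_ppm = 250)
  sat <- !grid$m0_flags
  w <- grid$offsets_ppm[sat]
  vox <- which(labels > 0)
  z <- matrix(NA_real_, length(vox), length(w))
  b1 <- fields$rel_b1[vox] * nominal_b1
  dw0 <- fields$b0_ppm[vox]
  for (i in seq_along(vox))
    z[i, ] <- wasabi_signal(w, b1[i], dw0[i], c_par = 1, d_par = 0.9, t_p = t_p)
  nfrm <- length(offs_all)
  sig <- matrix(0, prod(d), nfrm)
  sig[vox, which(sat)] <- z
  sig[vox, which(!sat)] <- 1
  sig <- sig * config$m0_au
  scheme <- saturation_scheme("rectangular", 1L, t_p, 1, nominal_b1,
                              total_sat_time_s = t_p)
  cest_series(array(sig, c(d, nfrm)), config$geometry, grid, scheme,
              mask = array(labels > 0, d))
}

simulate_t1rec <- function(config, labels, t1_vol,
                           times = DEFAULT_T1REC_TIMES) {
  d <- config$geometry$matrix_dims
  vox <- which(labels > 0)
  nfrm <- length(times)
  sig <- matrix(0, prod(d), nfrm)
  for (j in seq_len(nfrm))
    sig[vox, j] <- config$m0_au * (1 - exp(-times[j] / t1_vol[vox]))
  grid <- offset_grid(rep(-300, nfrm))
  scheme <- saturation_scheme("rectangular", 1L, 0.005, 1, 2,
                              total_sat_time_s = 0.005)
  cest_series(array(sig, c(d, nfrm)), config$geometry, grid, scheme,
              mask = array(labels > 0, d), recovery_times_s = times)
}

add_noise <- function(series, sd_au) {
  if (sd_au <= 0) return(series)
  series$signal <- series$signal +
    array(stats::rnorm(length(series$signal), 0, sd_au), dim(series$signal))
  series
}

#' Generate one phantom subject
#'
#' Draws the subject's regional truth (preset mean plus Gaussian
#' inter-subject jitter), builds the smooth true B0/relative-B1 fields and
#' the regional T1 volume, forward-models all five acquisition series, and
#' adds per-frame Gaussian noise. Reproducible: the subject's RNG stream is
#' derived deterministically from the master seed.
#'
#' @param config `cest_phantom_config`.
#' @param presets regional truth table (default [regional_truth_presets()]).
#' @param subject_index 1-based subject number.
#' @return list of class `cest_phantom_subject`: `labels`, `truth`,
#'   `field_maps_true`, `series` (lowpower_06, lowpower_09, aptw, wasabi,
#'   t1rec), `subject_index`, `config`.
#' @export
make_subject <- function(config = phantom_config(),
                         presets = regional_truth_presets(),
                         subject_index = 1L) {
  seeds <- subject_seeds(config$seed, config$n_subjects)
  if (subject_index > length(seeds))
    seeds <- subject_seeds(config$seed, subject_index)
  set.seed(seeds[subject_index])
  labels <- make_labels(config)
  truth <- jitter_truth(presets, config$jitter_frac)
  fields <- make_true_fields(config, labels)
  t1_vol <- array(0, config$geometry$matrix_dims)
  vox <- which(labels > 0)
  t1_vol[vox] <- truth$t1_s[labels[vox]]
  series <- list(
    lowpower_06 = simulate_lowpower(config, labels, truth, fields, 0.6),
    lowpower_09 = simulate_lowpower(config, labels, truth, fields, 0.9),
    aptw = simulate_aptw(config, labels, truth, fields),
    wasabi = simulate_wasabi(config, labels, fields),
    t1rec = simulate_t1rec(config, labels, t1_vol))
  sd_au <- config$noise_sd_frac * config$m0_au
  series <- lapply(series, add_noise, sd_au = sd_au)
  fm <- field_maps(b0_ppm = fields$b0_ppm, rel_b1 = fields$rel_b1,
                   t1_s = t1_vol)
  structure(list(labels = labels, truth = truth, field_maps_true = fm,
                 series = series, subject_index = subject_index,
                 config = config),
            class = "cest_phantom_subject")
}

# deterministic per-subject seeds below 2^31
subject_seeds <- function(master_seed, n) {
  set.seed(master_seed %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Generate the full phantom cohort
#'
#' @inheritParams make_subject
#' @return list of `cest_phantom_subject` objects.
#' @export
simulate_cohort <- function(config = phantom_config(),
                            presets = regional_truth_presets()) {
  lapply(seq_len(config$n_subjects), function(k)
    make_subject(config, presets, k))
}

#' Write a phantom subject to disk
#'
#' Writes all five series (NIfTI + sidecars), the label volume, the true
#' field maps and a `truth.json` into `dir`.
#'
#' @param subject `cest_phantom_subject`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_phantom_subject <- function(subject, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  geom <- subject$config$geometry
  for (nm in names(subject$series))
    write_series(subject$series[[nm]], file.path(dir, paste0(nm, ".nii.gz")))
  write_nifti(subject$labels, geom, file.path(dir, "labels.nii.gz"))
  write_field_maps(subject$field_maps_true, geom, file.path(dir, "true_maps"))
  jsonlite::write_json(subject$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
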