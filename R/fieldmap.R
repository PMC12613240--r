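# B0 / relative-B1 mapping from a WASABI series and T1 mapping from a
# saturation-recovery series.

GAMMA_HZ_PER_UT <- 42.576          # 1H gyromagnetic ratio, Hz per uT
DEFAULT_FIELD_T <- 3

#' WASABI signal model
#'
#' `Z(dw) = |c - d * sin^2(atan(gB1 / (dw - dw0))) *
#' sin^2(0.5 * t_p * sqrt(gB1^2 + (dw - dw0)^2))|` with all frequencies
#' angular (rad/s); offsets are converted from ppm at the given field
#' strength.
#'
#' @param offsets_ppm saturation offsets in ppm.
#' @param b1_uT absolute B1 amplitude in microtesla.
#' @param d_omega_ppm water-shift offset (B0) in ppm.
#' @param c_par,d_par offset level and modulation depth.
#' @param t_p pulse duration in seconds (default 5 ms).
#' @param field_T static field strength in tesla.
#' @return numeric vector of model Z values.
#' @export
wasabi_signal <- function(offsets_ppm, b1_uT, d_omega_ppm, c_par = 1,
                          d_par = 0.9, t_p = 0.005, field_T = DEFAULT_FIELD_T) {
  g_b1 <- 2 * pi * GAMMA_HZ_PER_UT * b1_uT
  dw <- 2 * pi * GAMMA_HZ_PER_UT * field_T * (offsets_ppm - d_omega_ppm)
  theta <- atan2(g_b1, dw)
  term <- sin(theta)^2 * sin(0.5 * t_p * sqrt(g_b1^2 + dw^2))^2
  abs(c_par - d_par * term)
}

#' Fit WASABI B0 and relative-B1 maps
#'
#' Per-voxel least squares of the WASABI model over a multi-start grid in
#' (water shift, relative B1) -- the oscillatory landscape has many local
#' minima -- followed by Nelder-Mead refinement of all four parameters with
#' the linear pair (c, d) profiled at the grid stage. Grid ties are broken
#' towards the smallest water shift.
#'
#' @param series `cest_series` whose offsets densely span roughly +/-2 ppm,
#'   with one M0 frame.
#' @param t_p WASABI pulse duration (s).
#' @param field_T static field (T).
#' @param grid_dw,grid_relb1 multi-start grids (ppm / relative units).
#' @param max_rel_rms per-voxel relative residual above which the voxel is
#'   flagged as non-converged in the quality mask.
#' @return `cest_fieldmaps` with `b0_ppm` and `rel_b1` filled, plus a
#'   `quality` logical array (TRUE = trustworthy).
#' @export
fit_wasabi <- function(series, t_p = 0.005, field_T = DEFAULT_FIELD_T,
                       grid_dw = seq(-0.6, 0.6, by = 0.2),
                       grid_relb1 = seq(0.5, 1.5, by = 0.25),
                       max_rel_rms = 0.2) {
  stopifnot(inherits(series, "cest_series"))
  nominal <- series$scheme$nominal_B1_uT
  zs <- normalize_series(series)
  w <- zs$offsets_ppm
  if (diff(range(w)) < 2) stop("WASABI offsets must densely span about +/-2 ppm")
  dims <- dim(zs$z)
  vox <- which(zs$mask)
  zmat <- matrix(zs$z, nrow = prod(dims[1:3]))[vox, , drop = FALSE]
  # grid stage: shared model curves, profiled (c, d) per voxel
  starts <- expand.grid(dw = grid_dw, rb1 = grid_relb1)
  ord <- order(abs(starts$dw))          # tie-break: smallest |dw| first
  starts <- starts[ord, ]
  nst <- nrow(starts)
  nv <- length(vox)
  best_sse <- rep(Inf, nv); best_idx <- rep(1L, nv)
  best_c <- rep(1, nv); best_d <- rep(0.9, nv)
  for (s in seq_len(nst)) {
    term <- 1 - wasabi_signal(w, starts$rb1[s] * nominal, starts$dw[s],
                              c_par = 1, d_par = 1, t_p = t_p,
                              field_T = field_T)   # the oscillation itself
    X <- cbind(1, -term)
    XtX <- crossprod(X)
    coef <- zmat %*% X %*% solve(XtX)              # profiled (c, d)
    fitted <- coef %*% t(X)
    sse <- rowSums((zmat - fitted)^2)
    upd <- sse < best_sse * (1 - 1e-9)
    best_sse[upd] <- sse[upd]; best_idx[upd] <- s
    best_c[upd] <- coef[upd, 1]; best_d[upd] <- coef[upd, 2]
  }
  b0 <- array(NA_real_, dims[1:3])
  rb1 <- array(NA_real_, dims[1:3])
  quality <- array(FALSE, dims[1:3])
  for (i in seq_len(nv)) {
    y <- zmat[i, ]
    obj <- function(p) {
      if (p[2] <= 0) return(1e6)
      sum((wasabi_signal(w, p[2], p[1], p[3], p[4], t_p, field_T) - y)^2)
    }
    p0 <- c(starts$dw[best_idx[i]], starts$rb1[best_idx[i]] * nominal,
            best_c[i], best_d[i])
    opt <- stats::optim(p0, obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 2000))
    b0[vox[i]] <- opt$par[1]
    rb1[vox[i]] <- opt$par[2] / nominal
    rel_rms <- sqrt(opt$value / length(y)) / max(mean(abs(y)), 1e-12)
    quality[vox[i]] <- opt$convergence == 0 && rel_rms < max_rel_rms &&
      abs(opt$par[1]) < 2
  }
  maps <- field_maps(b0_ppm = b0, rel_b1 = rb1, mask = zs$mask)
  maps$quality <- quality
  maps
}

#' Fit a saturation-recovery T1 map
#'
#' Per-voxel fit of `S(t) = A * (1 - exp(-t / T1))` with `A` profiled in
#' closed form and T1 found by 1D minimization on (0.05, 10) s. The
#' estimator is invariant to overall signal scale. Voxels whose estimate
#' hits the search boundary (e.g. a constant signal, which is consistent
#' with any `t >> T1`) or with non-positive mean signal are flagged
#' unreliable.
#'
#' @param series `cest_series` of recovery images.
#' @param recovery_times_s strictly increasing recovery delays (>= 3);
#'   defaults to the times stored in the series.
#' @return `cest_fieldmaps` with `t1_s` filled plus a `quality` array.
#' @export
fit_t1_satrec <- function(series, recovery_times_s = series$recovery_times_s) {
  stopifnot(inherits(series, "cest_series"))
  t <- recovery_times_s
  if (is.null(t) || length(t) < 3L) stop("need at least 3 recovery times")
  if (is.unsorted(t, strictly = TRUE)) stop("recovery times must be strictly increasing")
  if (length(t) != dim(series$signal)[4])
    stop("number of recovery times must match the number of frames")
  dims <- dim(series$signal)
  vox <- which(series$mask)
  smat <- matrix(series$signal, nrow = prod(dims[1:3]))[vox, , drop = FALSE]
  t1 <- array(NA_real_, dims[1:3])
  quality <- array(FALSE, dims[1:3])
  lo <- 0.05; hi <- 10
  for (i in seq_along(vox)) {
    y <- smat[i, ]
    if (mean(y) <= 0) next
    sse <- function(T1) {
      f <- 1 - exp(-t / T1)
      a <- sum(y * f) / sum(f * f)
      sum((y - a * f)^2)
    }
    opt <- stats::optimize(sse, c(lo, hi), tol = 1e-9)
    t1[vox[i]] <- opt$minimum
    quality[vox[i]] <- opt$minimum > lo * 1.05 && opt$minimum < hi * 0.95
  }
  maps <- field_maps(t1_s = t1)
  maps$quality <- quality
  maps$mask <- series$mask
  maps
}
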