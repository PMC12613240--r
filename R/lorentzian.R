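# Voxel-wise four-pool Lorentzian decomposition of low-power Z-spectra.
#
# The model is Z(dw) = z0 - plateau - sum_i A_i (G_i/2)^2 / ((G_i/2)^2 +
# (dw - d_i)^2) over pools DS (centre fitted within +/-0.3 ppm of 0),
# amide (+3.5 ppm), rNOE (-3.5 ppm) and ssMT (-2.5 ppm); the constant
# plateau accounts for the pulsed presaturation background.

POOLS <- c("DS", "amide", "rNOE", "ssMT")
POOL_CENTERS <- c(DS = 0, amide = 3.5, rNOE = -3.5, ssMT = -2.5)

#' Default four-pool fit configuration
#'
#' Start values and box bounds for the 11 free parameters. Width bounds are
#' disjoint between rNOE and ssMT so the two overlapping negative-offset
#' pools cannot swap roles.
#'
#' @param maxit maximum L-BFGS-B iterations.
#' @param factr L-BFGS-B relative-cost convergence factor (times machine
#'   epsilon); the default corresponds to a relative cost change ~2e-9.
#' @return list with `start`, `lower`, `upper`, `maxit`, `factr`.
#' @export
fit_config <- function(maxit = 400L, factr = 1e7) {
  nm <- c("A_DS", "A_amide", "A_rNOE", "A_ssMT",
          "G_DS", "G_amide", "G_rNOE", "G_ssMT", "d_DS", "plateau", "z0")
  start <- c(0.05, 0.05, 0.05, 0.05, 1.4, 1.0, 3.5, 25, 0, 0.05, 1.0)
  lower <- c(0, 0, 0, 0, 0.3, 0.3, 1.0, 10, -0.3, 0, 0.8)
  upper <- c(rep(1 - 1e-6, 4), 5, 3, 8, 100, 0.3, 0.5, 1.1)
  names(start) <- names(lower) <- names(upper) <- nm
  list(start = start, lower = lower, upper = upper,
       maxit = as.integer(maxit), factr = factr)
}

#' Evaluate the four-pool Z-spectrum model
#'
#' @param fit a `cest_fourpool` fit object or a named parameter vector of the
#'   layout produced by [fit_config()].
#' @param offsets_ppm frequency offsets at which to evaluate.
#' @return numeric vector of model Z values.
#' @export
model_z <- function(fit, offsets_ppm) {
  par <- if (inherits(fit, "cest_fourpool")) fit$par else fit
  stopifnot(length(par) == 11)
  .fp_model(as.numeric(par), as.numeric(offsets_ppm))
}

#' Fit the four-pool model to one Z-spectrum
#'
#' Bounded nonlinear least squares (L-BFGS-B with analytic gradients).
#' Replicate offsets are averaged and the spectrum is sorted before fitting,
#' so the result is invariant to acquisition order. Non-finite Z entries are
#' dropped.
#'
#' @param offsets_ppm frequency offsets (ppm).
#' @param z Z values, same length.
#' @param config see [fit_config()].
#' @return object of class `cest_fourpool`: `par`, `pools` (per-pool centre,
#'   amplitude, FWHM), `plateau`, `z0`, `residual_rms`, `converged`.
#' @export
fit_four_pool_voxel <- function(offsets_ppm, z, config = fit_config()) {
  keep <- is.finite(z) & is.finite(offsets_ppm)
  offsets_ppm <- offsets_ppm[keep]; z <- z[keep]
  if (anyDuplicated(offsets_ppm)) {
    z <- tapply(z, offsets_ppm, mean)
    offsets_ppm <- as.numeric(names(z))
    z <- as.numeric(z)
  }
  ord <- order(offsets_ppm)
  offsets_ppm <- offsets_ppm[ord]; z <- z[ord]
  if (length(z) < 12L)
    stop("need at least 12 distinct finite offsets to fit 11 parameters")
  w <- as.numeric(offsets_ppm)
  run <- function(start) {
    stats::optim(start, fn = .fp_sse, gr = .fp_grad, w = w, y = z,
                 method = "L-BFGS-B", lower = config$lower,
                 upper = config$upper,
                 control = list(maxit = config$maxit, factr = config$factr))
  }
  opt <- run(config$start)
  if (opt$convergence != 0) {               # one deterministic restart
    alt <- pmin(pmax(config$start * 1.2 + 0.01, config$lower), config$upper)
    opt2 <- run(alt)
    if (opt2$value < opt$value) opt <- opt2
  }
  par <- opt$par
  names(par) <- names(fit_config()$start)
  pools <- data.frame(name = POOLS,
                      center_ppm = c(par[["d_DS"]], POOL_CENTERS[-1]),
                      amplitude = unname(par[1:4]),
                      fwhm_ppm = unname(par[5:8]))
  structure(list(par = par, pools = pools, plateau = par[["plateau"]],
                 z0 = par[["z0"]],
                 residual_rms = sqrt(opt$value / length(z)),
                 converged = opt$convergence == 0),
            class = "cest_fourpool")
}

#' Voxel-wise four-pool fit of a Z-stack
#'
#' @param zstack a `cest_zstack` (normalized, B0-corrected spectra).
#' @param config see [fit_config()].
#' @param progress print a coarse progress line.
#' @return object of class `cest_fourpool_maps`: a list of 3D parameter maps
#'   (one per parameter) plus `residual_rms`, `converged`, `mask`.
#' @export
fit_four_pool <- function(zstack, config = fit_config(), progress = FALSE) {
  stopifnot(inherits(zstack, "cest_zstack"))
  dims <- dim(zstack$z)[1:3]
  vox <- which(zstack$mask)
  nvol <- prod(dims)
  zmat <- matrix(zstack$z, nrow = nvol)[vox, , drop = FALSE]
  w <- zstack$offsets_ppm
  if (length(w) < 12L) stop("fewer offsets than free parameters")
  npar <- length(config$start)
  pars <- matrix(NA_real_, length(vox), npar)
  rrms <- rep(NA_real_, length(vox))
  conv <- rep(FALSE, length(vox))
  for (i in seq_along(vox)) {
    f <- fit_four_pool_voxel(w, zmat[i, ], config)
    pars[i, ] <- f$par
    rrms[i] <- f$residual_rms
    conv[i] <- f$converged
    if (progress && i %% 2000 == 0)
      message(sprintf("  fitted %d / %d voxels", i, length(vox)))
  }
  maps <- list()
  for (j in seq_len(npar)) {
    m <- array(NA_real_, dims)
    m[vox] <- pars[, j]
    maps[[names(config$start)[j]]] <- m
  }
  res <- array(NA_real_, dims); res[vox] <- rrms
  cv <- array(FALSE, dims); cv[vox] <- conv
  structure(list(maps = maps, residual_rms = res, converged = cv,
                 mask = zstack$mask, geometry = zstack$geometry),
            class = "cest_fourpool_maps")
}

# parameter vector of one voxel from a fitted map set
voxel_par <- function(fitmaps, i) {
  vapply(fitmaps$maps, function(m) m[i], numeric(1))
}

#' Labeled and reference Z values for one pool
#'
#' Both are evaluated at the pool's centre; the reference spectrum is the
#' fitted model with the pool of interest removed (amplitude set to zero,
#' plateau retained).
#'
#' @param fit `cest_fourpool` object or 11-parameter vector.
#' @param pool `"amide"`, `"rNOE"` or `"ssMT"` (or `"DS"`).
#' @return named numeric vector `c(z_lab, z_ref)`.
#' @export
zlab_zref <- function(fit, pool = c("amide", "rNOE", "ssMT", "DS")) {
  pool <- match.arg(pool)
  par <- if (inherits(fit, "cest_fourpool")) fit$par else fit
  k <- match(pool, POOLS)
  center <- if (pool == "DS") par[[9]] else POOL_CENTERS[[pool]]
  z_lab <- .fp_model(as.numeric(par), center)
  par_ref <- as.numeric(par)
  par_ref[k] <- 0
  z_ref <- .fp_model(par_ref, center)
  c(z_lab = z_lab, z_ref = z_ref)
}
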