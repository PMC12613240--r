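# Z-stack preprocessing: M0-interpolated normalization, B0 correction by
# spectral resampling, and PCA-based denoising.

#' Normalized Z-spectrum stack
#'
#' @param z 4D numeric array (x, y, z, offset), dimensionless.
#' @param offsets_ppm sorted unique offsets matching the 4th dimension.
#' @param geometry `cest_geometry`.
#' @param mask 3D logical.
#' @param provenance named logical flags (`normalized`, `b0_corrected`,
#'   `denoised`).
#' @return object of class `cest_zstack`.
#' @export
zstack <- function(z, offsets_ppm, geometry, mask,
                   provenance = c(normalized = TRUE, b0_corrected = FALSE,
                                  denoised = FALSE)) {
  stopifnot(length(dim(z)) == 4L, dim(z)[4] == length(offsets_ppm),
            !is.unsorted(offsets_ppm), !anyDuplicated(offsets_ppm))
  structure(list(z = z, offsets_ppm = as.numeric(offsets_ppm),
                 geometry = geometry, mask = mask, provenance = provenance),
            class = "cest_zstack")
}

#' Normalize a saturation series into a Z-stack
#'
#' Z = M_sat / M0 per voxel and frame, where M0 at each acquisition index is
#' linearly interpolated (by index) between the two M0 frames; series with a
#' single M0 frame (the APTw case) use it throughout. Voxels with
#' non-positive M0 are removed from the mask. Replicate offsets are averaged,
#' and the output stack is on the sorted unique offset grid.
#'
#' @param series `cest_series` with at least one M0-flagged frame.
#' @return `cest_zstack`.
#' @export
normalize_series <- function(series) {
  stopifnot(inherits(series, "cest_series"))
  grid <- series$grid
  m0_idx <- which(grid$m0_flags)
  if (length(m0_idx) < 1L) stop("series has no M0 frame")
  dims <- dim(series$signal)
  nvol <- prod(dims[1:3])
  sig <- matrix(series$signal, nrow = nvol)
  nfrm <- dims[4]
  if (length(m0_idx) == 1L) {
    m0 <- matrix(sig[, m0_idx], nvol, nfrm)
  } else {
    i0 <- m0_idx[1]; i1 <- m0_idx[length(m0_idx)]
    frac <- (seq_len(nfrm) - i0) / (i1 - i0)
    m0 <- outer(sig[, i0], rep(1, nfrm)) +
      outer(sig[, i1] - sig[, i0], frac)
  }
  mask <- series$mask
  bad_m0 <- matrixStats_rowMin(m0) <= 0
  mask[bad_m0 & mask] <- FALSE
  zfull <- sig / m0
  sat <- !grid$m0_flags
  offs <- grid$offsets_ppm[sat]
  zsat <- zfull[, sat, drop = FALSE]
  uo <- sort(unique(offs))
  if (length(uo) < length(offs)) {       # average replicate offsets
    zu <- matrix(0, nvol, length(uo))
    for (j in seq_along(uo)) {
      cols <- which(offs == uo[j])
      zu[, j] <- if (length(cols) > 1L) rowMeans(zsat[, cols, drop = FALSE])
                 else zsat[, cols]
    }
    zsat <- zu
  } else {
    zsat <- zsat[, order(offs), drop = FALSE]
  }
  z4 <- array(zsat, c(dims[1:3], length(uo)))
  zstack(z4, uo, series$geometry, mask)
}

matrixStats_rowMin <- function(m) do.call(pmin, as.data.frame(m))

#' B0-correct a Z-stack by spectral resampling
#'
#' Per voxel the spectrum is resampled at `offsets + b0` using
#' shape-preserving piecewise-cubic (monotone Hermite) interpolation over the
#' sorted offset grid. Entries that would require extrapolation beyond the
#' measured range become `NA` (flagged invalid, never extrapolated); voxels
#' with an implausible shift (|b0| > `max_shift_ppm`) are invalidated
#' entirely.
#'
#' @param zs `cest_zstack`.
#' @param b0_ppm 3D numeric array of water-shift offsets (ppm).
#' @param max_shift_ppm plausibility bound for |b0| (default 1 ppm).
#' @return `cest_zstack` with `b0_corrected = TRUE`.
#' @export
correct_b0 <- function(zs, b0_ppm, max_shift_ppm = 1) {
  stopifnot(inherits(zs, "cest_zstack"))
  dims <- dim(zs$z)
  stopifnot(identical(dim(b0_ppm), dims[1:3]))
  w <- zs$offsets_ppm
  nvol <- prod(dims[1:3])
  zmat <- matrix(zs$z, nrow = nvol)
  vox <- which(zs$mask)
  out <- zmat
  rng <- range(w)
  for (i in vox) {
    shift <- b0_ppm[i]
    if (!is.finite(shift) || abs(shift) > max_shift_ppm) {
      out[i, ] <- NA_real_
      next
    }
    if (shift == 0) next
    target <- w + shift
    fin <- is.finite(zmat[i, ])
    if (sum(fin) < 4L) {
      out[i, ] <- NA_real_
      next
    }
    f <- stats::splinefun(w[fin], zmat[i, fin], method = "monoH.FC")
    zi <- f(target)
    zi[target < min(w[fin]) | target > max(w[fin])] <- NA_real_
    out[i, ] <- zi
  }
  prov <- zs$provenance
  prov["b0_corrected"] <- TRUE
  zstack(array(out, dims), w, zs$geometry, zs$mask, prov)
}

# Malinowski indicator function over singular values; returns the component
# count at the indicator minimum.
malinowski_k <- function(d, n) {
  p <- length(d)
  ev <- d^2
  ind <- rep(NA_real_, p - 1)
  for (k in seq_len(p - 1)) {
    re <- sqrt(sum(ev[(k + 1):p]) / (n * (p - k)))
    ind[k] <- re / (p - k)^2
  }
  which.min(ind)
}

# Marchenko-Pastur-style noise edge: keep components whose singular value
# exceeds the largest value expected from an i.i.d. noise matrix whose
# variance is estimated from the lower half of the eigenvalue spectrum.
noise_edge_k <- function(d, n) {
  p <- length(d)
  ev <- d^2
  noise_var <- stats::median(ev[ceiling(p / 2):p]) / n
  max(1L, sum(d > sqrt(noise_var) * (sqrt(n) + sqrt(p))))
}

#' PCA-based Z-spectrum denoising
#'
#' Masked voxel spectra are cast into a voxels x offsets matrix,
#' mean-centered along offsets (the mean spectrum is subtracted), truncated
#' to the leading principal components and reconstructed. The component
#' count defaults to a Marchenko-Pastur noise-edge criterion (all components
#' above the eigenvalue level expected from pure noise are retained); the
#' Malinowski indicator-function minimum is available as an alternative but
#' tends to truncate more aggressively, which can bias spatially smooth
#' contrast gradients. Offsets with any non-finite value among the masked
#' voxels (e.g. wing entries flagged by B0 correction) are passed through
#' unchanged, as are voxels outside the mask.
#'
#' @param zs `cest_zstack` with >= 10 masked voxels and >= 5 offsets.
#' @param k number of components; `NULL` (default) applies `criterion`.
#' @param criterion `"noise_edge"` (default) or `"malinowski"`.
#' @return `cest_zstack` with `denoised = TRUE`; the chosen component count
#'   is attached as attribute `"k"`.
#' @export
denoise_pca <- function(zs, k = NULL,
                        criterion = c("noise_edge", "malinowski")) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(zs, "cest_zstack"))
  dims <- dim(zs$z)
  vox <- which(zs$mask)
  if (length(vox) < 10L) stop("denoising needs at least 10 masked voxels")
  if (dims[4] < 5L) stop("denoising needs at least 5 offsets")
  zmat <- matrix(zs$z, nrow = prod(dims[1:3]))
  x <- zmat[vox, , drop = FALSE]
  usable <- colSums(!is.finite(x)) == 0L
  xs <- x[, usable, drop = FALSE]
  mu <- colMeans(xs)
  xc <- sweep(xs, 2, mu)
  sv <- svd(xc)
  if (sum(sv$d > sv$d[1] * 1e-12) <= 1L) {
    warning("denoise_pca: input is (numerically) rank-1; returned unchanged")
    out <- zs
    attr(out, "k") <- NA_integer_
    return(out)
  }
  if (is.null(k))
    k <- switch(criterion,
                noise_edge = noise_edge_k(sv$d, nrow(xs)),
                malinowski = malinowski_k(sv$d, nrow(xs)))
  k <- min(k, length(sv$d))
  recon <- sv$u[, 1:k, drop = FALSE] %*%
    (sv$d[1:k] * t(sv$v[, 1:k, drop = FALSE]))
  xs_new <- sweep(recon, 2, mu, `+`)
  x[, usable] <- xs_new
  zmat[vox, ] <- x
  prov <- zs$provenance
  prov["denoised"] <- TRUE
  out <- zstack(array(zmat, dims), zs$offsets_ppm, zs$geometry, zs$mask, prov)
  attr(out, "k") <- as.integer(k)
  out
}
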