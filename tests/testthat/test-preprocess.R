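test_that("normalization interpolates M0 by acquisition index", {
  # M0 1000 at the start, 900 at the end, one frame midway: M0_interp = 950
  sat <- array(475, c(1, 1, 1, 1))
  s <- toy_series(sat, m0_first = 1000, m0_last = 900, offsets = 0)
  zs <- normalize_series(s)
  expect_equal(zs$z[1, 1, 1, 1], 0.5)
})

test_that("drift-free normalization equals plain division and is scale-free", {
  set.seed(2)
  sat <- array(runif(2 * 2 * 1 * 7, 300, 900), c(2, 2, 1, 7))
  s <- toy_series(sat, 1000, 1000)
  zs <- normalize_series(s)
  expect_equal(as.numeric(zs$z), as.numeric(sat / 1000))
  s2 <- s; s2$signal <- s$signal * 3.7          # degree-0 homogeneity
  expect_equal(normalize_series(s2)$z, zs$z, tolerance = 1e-12)
})

test_that("normalization removes the phantom's linear M0 drift", {
  cfg <- phantom_config(noise_sd_frac = 0, b0_amplitude_ppm = 0,
                        relb1_range = c(1, 1), jitter_frac = 0,
                        m0_drift_frac = 0.02)
  s <- make_subject(cfg, subject_index = 1L)
  nz <- norm_zmat(s$series$lowpower_06)
  vox <- which(s$labels == 1)[1]
  tr <- s$truth[1, ]
  A <- invert_pool_amplitudes(
    c(tr$mtrrex_amide, tr$mtrrex_rnoe, tr$mtrrex_ssmt) * 0.6 / 0.7,
    plateau = 0.07)
  par <- c(0.85, A[1, ], c(1.4, 1.0, 3.5, 25), 0, 0.07, 1)
  expect_lt(max(abs(nz$zmat[vox, ] - model_z(par, nz$offsets))), 1e-9)
})

test_that("voxels with non-positive M0 are dropped from the mask", {
  sat <- array(500, c(2, 1, 1, 3))
  s <- toy_series(sat)
  s$signal[1, 1, 1, c(1, 5)] <- 0
  zs <- normalize_series(s)
  expect_false(zs$mask[1, 1, 1])
  expect_true(zs$mask[2, 1, 1])
})

test_that("B0 correction: identity, constants, implausible shifts", {
  set.seed(4)
  w <- sort(c(seq(-5, 5, 0.5), -20, 20))
  nvox <- 6
  zm <- t(vapply(seq_len(nvox), function(i)
    1 - 0.8 * (0.7^2) / (0.7^2 + w^2) - runif(1, 0, 0.1), numeric(length(w))))
  z4 <- array(zm, c(nvox, 1, 1, length(w)))
  zs <- zstack(z4, w, volume_geometry(c(nvox, 1, 1), c(1.7, 1.7, 3)),
               array(TRUE, c(nvox, 1, 1)))
  out0 <- correct_b0(zs, array(0, c(nvox, 1, 1)))
  expect_identical(out0$z, zs$z)
  expect_true(out0$provenance[["b0_corrected"]])

  # constant spectra are invariant under any shift
  zc <- zs; zc$z <- array(0.5, dim(zs$z))
  outc <- correct_b0(zc, array(0.3, c(nvox, 1, 1)))
  inner <- !is.na(outc$z)
  expect_true(all(abs(outc$z[inner] - 0.5) < 1e-12))

  big <- correct_b0(zs, array(1.5, c(nvox, 1, 1)))
  expect_true(all(is.na(big$z[1, 1, 1, ])))
})

test_that("B0 correction recovers a shifted model spectrum", {
  w <- sort(unique(c(seq(-6, 6, 0.125), seq(-20, 20, 2.5))))
  par <- c(0.85, 0.1, 0.12, 0.16, 1.4, 1.0, 3.5, 25, 0, 0.07, 1)
  shift <- 0.1
  meas <- model_z(par, w - shift)              # water off-centre by +0.1 ppm
  z4 <- array(rep(meas, each = 1), c(1, 1, 1, length(w)))
  zs <- zstack(z4, w, volume_geometry(c(1, 1, 1), c(1.7, 1.7, 3)),
               array(TRUE, c(1, 1, 1)))
  out <- correct_b0(zs, array(shift, c(1, 1, 1)))
  model <- model_z(par, w)
  ok <- !is.na(out$z[1, 1, 1, ])
  expect_true(all(abs(w[ok]) <= 20))
  expect_lt(max(abs(out$z[1, 1, 1, ok] - model[ok])), 1e-3)

  # roundtrip: shifting back with the negated map stays within 2x tolerance
  back <- correct_b0(out, array(-shift, c(1, 1, 1)))
  ok2 <- !is.na(back$z[1, 1, 1, ])
  expect_lt(max(abs(back$z[1, 1, 1, ok2] - meas[ok2])), 2e-3)
})

test_that("PCA denoising is lossless at the true rank", {
  set.seed(5)
  nvox <- 40; noff <- 20
  base <- outer(runif(nvox), sin(seq_len(noff)))
  base <- base + outer(runif(nvox), cos(seq_len(noff) / 3)) +
    outer(rnorm(nvox), seq_len(noff) / noff)
  z4 <- array(base + 1, c(nvox, 1, 1, noff))
  zs <- zstack(z4, seq_len(noff), volume_geometry(c(nvox, 1, 1), c(1, 1, 1)),
               array(TRUE, c(nvox, 1, 1)),
               provenance = c(normalized = TRUE, b0_corrected = TRUE,
                              denoised = FALSE))
  out <- denoise_pca(zs, k = 3)
  expect_lt(max(abs(out$z - zs$z)), 1e-10)
})

test_that("PCA denoising reduces noise and preserves the mean spectrum", {
  set.seed(6)
  nvox <- 200; noff <- 30
  clean <- outer(runif(nvox, 0.5, 1), rep(1, noff)) -
    outer(runif(nvox, 0, 0.3), exp(-seq_len(noff) / 5)) +
    outer(runif(nvox, 0, 0.1), sin(seq_len(noff)))
  noisy <- clean + rnorm(nvox * noff, 0, 0.01)
  mk <- function(m) zstack(array(m, c(nvox, 1, 1, noff)), seq_len(noff),
                           volume_geometry(c(nvox, 1, 1), c(1, 1, 1)),
                           array(TRUE, c(nvox, 1, 1)))
  out <- denoise_pca(mk(noisy))
  den <- matrix(out$z, nvox)
  expect_lt(sqrt(mean((den - clean)^2)), sqrt(mean((noisy - clean)^2)))
  expect_lt(max(abs(colMeans(den) - colMeans(noisy))), 1e-8)
  expect_true(out$provenance[["denoised"]])

  # identical spectra + noise: cross-voxel variance shrinks
  flat <- outer(rep(1, nvox), clean[1, ]) + rnorm(nvox * noff, 0, 0.01)
  outf <- denoise_pca(mk(flat))
  vf <- matrix(outf$z, nvox)
  expect_lt(mean(apply(vf, 2, stats::var)),
            mean(apply(flat, 2, stats::var)))
})

test_that("rank-1 input is returned unchanged with a warning", {
  nvox <- 15; noff <- 8
  m <- outer(rep(1, nvox), seq_len(noff) / 4)
  zs <- zstack(array(m, c(nvox, 1, 1, noff)), seq_len(noff),
               volume_geometry(c(nvox, 1, 1), c(1, 1, 1)),
               array(TRUE, c(nvox, 1, 1)))
  expect_warning(out <- denoise_pca(zs), "rank-1")
  expect_identical(out$z, zs$z)
})
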