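test_that("model_z basic properties", {
  w <- seq(-10, 10, 0.5)
  empty <- c(0, 0, 0, 0, 1.4, 1, 3.5, 25, 0, 0, 1)
  expect_equal(model_z(empty, w), rep(1, length(w)))

  # single amide pool: full depth at the centre, half depth at +/- FWHM/2
  one <- c(0, 0.2, 0, 0, 1.4, 1.2, 3.5, 25, 0, 0, 1)
  expect_equal(model_z(one, 3.5), 0.8)
  expect_equal(model_z(one, 3.5 + 0.6), 1 - 0.1)
  expect_equal(model_z(one, 3.5 - 0.6), 1 - 0.1)
})

test_that("fit recovers known parameters from perturbed starts", {
  w <- sorted_offsets_for_tests()
  truth <- c(0.85, 0.10, 0.13, 0.17, 1.4, 1.0, 3.5, 25, 0.05, 0.10, 1)
  z <- model_z(truth, w)
  cfg <- fit_config(factr = 1, maxit = 3000)   # deep polish for precision test
  cfg$start <- pmin(pmax(truth * c(rep(1.2, 8), 1, 1.2, 1), cfg$lower), cfg$upper)
  cfg$start[9] <- 0.1                      # perturbed DS-centre start
  fit <- fit_four_pool_voxel(w, z, cfg)
  expect_true(fit$converged)
  # z0 and plateau are exchangeable (only their difference enters the model)
  est <- fit$par; tr <- truth
  est[11] <- est[11] - est[10]; tr[11] <- tr[11] - tr[10]
  expect_lt(max(abs(est[-10] - tr[-10])), 1e-4)
  expect_lt(fit$residual_rms, 1e-6)
})

test_that("flat spectrum drives amplitudes and plateau to zero", {
  w <- sorted_offsets_for_tests()
  fit <- fit_four_pool_voxel(w, rep(1, length(w)),
                             fit_config(factr = 1, maxit = 3000))
  expect_lt(max(fit$par[1:4]), 1e-4)
  # z0 and plateau only enter through their difference; the flat spectrum
  # pins that difference at 1 (amplitudes and the net baseline at zero depth)
  expect_lt(abs(fit$par[["z0"]] - fit$par[["plateau"]] - 1), 1e-6)
})

test_that("fit is invariant to offset ordering and averages duplicates", {
  w <- sorted_offsets_for_tests()
  truth <- c(0.85, 0.08, 0.12, 0.2, 1.4, 1.0, 3.5, 25, 0, 0.07, 1)
  z <- model_z(truth, w)
  f1 <- fit_four_pool_voxel(w, z)
  perm <- sample(length(w))
  f2 <- fit_four_pool_voxel(w[perm], z[perm])
  expect_equal(f1$par, f2$par, tolerance = 1e-10)
  # duplicates whose mean equals the model value leave the fit unchanged
  wd <- c(w, 3.5, 3.5)
  zd <- c(z, z[w == 3.5] + 0.01, z[w == 3.5] - 0.01)
  f3 <- fit_four_pool_voxel(wd, zd)
  expect_equal(f1$par, f3$par, tolerance = 1e-8)
})

test_that("fit agrees with a brute-force grid oracle on a 1-pool problem", {
  w <- seq(-8, 8, 0.4)
  z <- 1 - 0.23 * (0.9^2) / (0.9^2 + w^2)       # single DS-like pool
  # oracle: exhaustive (amplitude, width) grid at fixed z0 = 1
  amps <- seq(0.1, 0.4, 0.005); fws <- seq(1, 3, 0.02)
  sse <- outer(amps, fws, function(a, f) {
    vapply(seq_along(a), function(i) {
      g <- f[i] / 2
      sum((1 - a[i] * g^2 / (g^2 + w^2) - z)^2)
    }, numeric(1))
  })
  best <- arrayInd(which.min(sse), dim(sse))
  cfg <- fit_config()
  cfg$lower[c(2:4, 10)] <- 0; cfg$upper[c(2:4, 10)] <- 1e-12   # DS pool only
  cfg$lower[11] <- 1 - 1e-12; cfg$upper[11] <- 1
  cfg$start <- pmin(pmax(cfg$start, cfg$lower), cfg$upper)
  fit <- fit_four_pool_voxel(w, z, cfg)
  expect_equal(fit$par[["A_DS"]], amps[best[1]], tolerance = 0.005)
  expect_equal(fit$par[["G_DS"]], fws[best[2]], tolerance = 0.02)
})

test_that("zlab_zref separates the pool of interest", {
  par <- c(0, 0.1, 0, 0, 1.4, 1, 3.5, 25, 0, 0, 1)
  zz <- zlab_zref(par, "amide")
  expect_equal(unname(zz), c(0.9, 1.0))
  par0 <- par; par0[2] <- 0
  zz0 <- zlab_zref(par0, "amide")
  expect_equal(zz0[["z_lab"]], zz0[["z_ref"]])
  # z_ref >= z_lab for all pools under nonnegative amplitudes
  set.seed(8)
  for (i in 1:10) {
    p <- c(runif(4, 0, 0.3), 1.4, 1, 3.5, 25, runif(1, -0.3, 0.3),
           runif(1, 0, 0.2), 1)
    for (pool in c("amide", "rNOE", "ssMT")) {
      zz <- zlab_zref(p, pool)
      expect_gte(zz[["z_ref"]], zz[["z_lab"]])
    }
  }
})

test_that("noise-free phantom voxels are recovered within 1e-3", {
  s <- clean_subject()
  nz <- norm_zmat(s$series$lowpower_09)
  set.seed(9)
  for (code in c(2, 7)) {
    vox <- sample(which(s$labels == code), 2)
    tr <- s$truth[s$truth$code == code, ]
    plateau <- if (tr$tissue == "GM") 0.07 else 0.10
    A <- invert_pool_amplitudes(
      c(tr$mtrrex_amide, tr$mtrrex_rnoe, tr$mtrrex_ssmt) * 0.9 / 0.7,
      plateau = plateau)
    for (v in vox) {
      fit <- fit_four_pool_voxel(nz$offsets, nz$zmat[v, ])
      expect_lt(max(abs(fit$par[2:4] - A[1, ])), 1e-3)
    }
  }
})
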