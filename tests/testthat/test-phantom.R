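test_that("default label volume has 8 ROIs of at least 100 voxels", {
  lab <- make_labels(phantom_config())
  counts <- tabulate(lab, 8)
  expect_length(counts, 8L)
  expect_true(all(counts >= 100))
  expect_identical(sort(unique(as.integer(lab))), 0:8)
})

test_that("too-small geometry errors naming the deficient ROI", {
  cfg <- phantom_config(geometry = volume_geometry(c(8L, 8L, 2L), c(1.7, 1.7, 3)))
  expect_error(make_labels(cfg), "GM|WM")
})

test_that("doubling matrix dims at least quadruples every ROI count", {
  c1 <- tabulate(make_labels(small_config()), 8)
  cfg2 <- phantom_config(geometry = volume_geometry(c(72L, 60L, 12L),
                                                    c(1.7, 1.7, 3)))
  c2 <- tabulate(make_labels(cfg2), 8)
  expect_true(all(c2 >= 4 * c1))
})

test_that("pool-amplitude inversion: zero targets give zero amplitudes", {
  A <- invert_pool_amplitudes(c(0, 0, 0))
  expect_equal(unname(A[1, ]), c(0, 0, 0))
})

test_that("inversion reproduces the GM-Ccs amide target, cross-checked by bisection", {
  fwhm <- c(DS = 1.4, amide = 1.0, rNOE = 3.5, ssMT = 25)
  targets <- c(amide = 0.23, rNOE = 0.31, ssMT = 0.40)   # GM-Ccs preset at 0.7 uT
  A <- invert_pool_amplitudes(targets, fwhm, ds_amplitude = 0.85,
                              plateau = 0.07, z0 = 1)
  # forward model through model_z: MTR_Rex at each pool centre hits its target
  par <- c(0.85, A[1, ], fwhm, 0, 0.07, 1)
  for (i in seq_along(targets)) {
    pool <- names(targets)[i]
    zz <- zlab_zref(par, pool)
    expect_equal(unname(1 / zz["z_lab"] - 1 / zz["z_ref"]), targets[[i]],
                 tolerance = 1e-6)
  }
  # independent oracle: bisection on the amide amplitude with the other two fixed
  f <- function(a) {
    p <- par; p[2] <- a
    zz <- zlab_zref(p, "amide")
    (1 / zz[["z_lab"]] - 1 / zz[["z_ref"]]) - 0.23
  }
  lo <- 0; hi <- 0.9
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  expect_equal(unname(A[1, "amide"]), (lo + hi) / 2, tolerance = 1e-7)
})

test_that("inversion solves random target batches simultaneously (property)", {
  set.seed(11)
  tg <- cbind(runif(25, 0, 0.35), runif(25, 0, 0.45), runif(25, 0, 0.55))
  A <- invert_pool_amplitudes(tg, plateau = 0.10)
  expect_true(all(A >= 0 & A < 1))
  for (r in sample(nrow(tg), 5)) {
    par <- c(0.85, A[r, ], c(1.4, 1.0, 3.5, 25), 0, 0.10, 1)
    got <- vapply(c("amide", "rNOE", "ssMT"), function(p) {
      zz <- zlab_zref(par, p)
      1 / zz[["z_lab"]] - 1 / zz[["z_ref"]]
    }, numeric(1))
    expect_equal(unname(got), unname(tg[r, ]), tolerance = 1e-6)
  }
  expect_error(invert_pool_amplitudes(c(0.2, 0.3, 0.4), plateau = 0.98),
               "unreachable|converge")
})

test_that("analytic contrast is linear in B1 through the reference point", {
  # amplitudes re-inverted at 0.54 and 0.81 uT interpolate exactly to the
  # 0.7 uT truth under the two-point linear model
  truth <- c(0.205, 0.31, 0.38)
  fwd <- function(b1) {
    A <- invert_pool_amplitudes(truth * b1 / 0.7, plateau = 0.07)
    par <- c(0.85, A[1, ], c(1.4, 1.0, 3.5, 25), 0, 0.07, 1)
    zz <- zlab_zref(par, "amide")
    1 / zz[["z_lab"]] - 1 / zz[["z_ref"]]
  }
  c_lo <- fwd(0.54); c_hi <- fwd(0.81)
  at_ref <- c_lo + (c_hi - c_lo) * (0.7 - 0.54) / (0.81 - 0.54)
  expect_equal(at_ref, truth[1], tolerance = 1e-7)
})

test_that("noise-free phantom Z equals the analytic forward model", {
  s <- clean_subject()
  nz <- norm_zmat(s$series$lowpower_06)
  vox <- which(s$labels == 4)[1]                      # a GM-Ccs voxel
  tr <- s$truth[s$truth$code == 4, ]
  A <- invert_pool_amplitudes(
    c(tr$mtrrex_amide, tr$mtrrex_rnoe, tr$mtrrex_ssmt) * 0.6 / 0.7,
    plateau = 0.07)
  par <- c(0.85, A[1, ], c(1.4, 1.0, 3.5, 25), 0, 0.07, 1)
  expect_equal(nz$zmat[vox, ], model_z(par, nz$offsets), tolerance = 1e-9)
  # Z at the amide centre equals the analytic Z_lab
  zz <- zlab_zref(par, "amide")
  expect_equal(nz$zmat[vox, nz$offsets == 3.5], zz[["z_lab"]],
               tolerance = 1e-9)
})

test_that("same seed regenerates a bit-identical dataset", {
  cfg <- small_config(n_subjects = 1L)
  s1 <- make_subject(cfg, subject_index = 1L)
  s2 <- make_subject(cfg, subject_index = 1L)
  expect_identical(s1$truth, s2$truth)
  for (nm in names(s1$series))
    expect_identical(s1$series[[nm]]$signal, s2$series[[nm]]$signal)
  expect_identical(s1$field_maps_true$b0_ppm, s2$field_maps_true$b0_ppm)
})

test_that("frontal-lobe WM mean relative B1 is about 0.74", {
  s <- cached("default_subject1", make_subject(phantom_config(), subject_index = 1L))
  rb <- s$field_maps_true$rel_b1[s$labels == 5]
  expect_equal(mean(rb), 0.74, tolerance = 0.03)
  expect_true(min(s$field_maps_true$rel_b1[s$labels > 0]) >= 0.74 - 1e-9)
  expect_true(max(s$field_maps_true$rel_b1[s$labels > 0]) <= 1.05 + 1e-9)
})
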