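# Shared fixtures, built in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# small slab geometry that still satisfies the 100-voxel ROI floor
small_config <- function(n_subjects = 3L, ...) {
  phantom_config(geometry = volume_geometry(c(36L, 30L, 6L), c(1.7, 1.7, 3)),
                 n_subjects = n_subjects, seed = 7L, ...)
}

# unequally spaced whole-spectrum offset grid used by the fit tests
sorted_offsets_for_tests <- function() {
  sort(unique(c(seq(-5, 5, 0.25), -8, 8, -12, 12, -20, 20, -50, 50,
                -100, 100, -250, 250)))
}

# noise-free, homogeneous-field, unjittered default-geometry subject
clean_subject <- function() {
  cached("clean_subject", {
    cfg <- phantom_config(noise_sd_frac = 0, m0_drift_frac = 0,
                          b0_amplitude_ppm = 0, relb1_range = c(1, 1),
                          jitter_frac = 0)
    make_subject(cfg, subject_index = 1L)
  })
}

# z matrix (voxels x offsets) of a normalized series
norm_zmat <- function(series) {
  zs <- normalize_series(series)
  list(zs = zs,
       zmat = matrix(zs$z, nrow = prod(dim(zs$z)[1:3])),
       offsets = zs$offsets_ppm)
}

# tiny hand-built series: one M0 frame, n saturation frames, one M0 frame
toy_series <- function(sat_signal, m0_first = 1000, m0_last = 1000,
                       offsets = seq(-2, 2, length.out = dim(sat_signal)[4])) {
  d <- dim(sat_signal)[1:3]
  nfrm <- dim(sat_signal)[4] + 2L
  sig <- array(0, c(d, nfrm))
  sig[, , , 1] <- m0_first
  sig[, , , nfrm] <- m0_last
  sig[, , , 2:(nfrm - 1)] <- sat_signal
  grid <- offset_grid(c(-300, offsets, -300))
  cest_series(sig, volume_geometry(d, c(1.7, 1.7, 3)), grid,
              saturation_scheme(nominal_B1_uT = 0.6))
}
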