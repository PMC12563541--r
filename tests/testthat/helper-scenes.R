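# Shared small scenes and helpers, built fresh in code (no stored data).
# Frames are 64 px with a 128-sample pupil grid unless a test needs more:
# big enough for sub-0.01 rad metric optima, small enough to keep the suite
# fast.

test_config <- function(...) {
  optical_config(pupil_grid_size = 128, ...)
}

test_bead_phantom <- function(n = 8, fov = c(64, 64, 1), seed = 2) {
  make_bead_phantom(n, fov = fov, min_separation = 1200, seed = seed)
}

test_scope <- function(sample_aberration = zernike_vector(), noise = NULL,
                       seed = 2, ...) {
  virtual_scope(test_bead_phantom(seed = seed), test_config(),
                sample_aberration = sample_aberration, noise = noise,
                pupil_grid = 128, ...)
}

# largest per-mode deviation between a recovered correction and the
# negated injected aberration, over the scanned mode set
recovery_error <- function(correction, injected, modes) {
  max(abs(zv_amplitude(correction, modes) + zv_amplitude(injected, modes)))
}

expect_zv_equal <- function(a, b, tol = 1e-12) {
  j <- union(zv_modes(a), zv_modes(b))
  expect_equal(zv_amplitude(a, j), zv_amplitude(b, j), tolerance = tol)
}
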