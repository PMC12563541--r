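# Specimen phantoms, the depth-aberration model, the DM model and noise.

test_that("bead phantoms are deterministic, non-negative and respect placement", {
  a <- make_bead_phantom(10, fov = c(64, 64, 3), min_separation = 800,
                         seed = 5)
  b <- make_bead_phantom(10, fov = c(64, 64, 3), min_separation = 800,
                         seed = 5)
  expect_identical(a$intensity, b$intensity)
  expect_true(all(a$intensity >= 0))
  expect_equal(nrow(a$primitives$centers), 10)
  d <- as.matrix(stats::dist(a$primitives$centers))
  expect_gte(min(d[upper.tri(d)]), 800)
  expect_equal(a$params$diameter_nm, 100)
  # a single bead lands at the centre
  s <- make_bead_phantom(1, fov = c(64, 64, 1), seed = 1)
  expect_equal(unname(s$primitives$centers[1, 1:2]), c(64 * 80 / 2, 64 * 80 / 2))
  expect_error(make_bead_phantom(200, fov = c(32, 32, 1),
                                 min_separation = 2000, seed = 1),
               "separation")
})

test_that("filament phantoms are straight at zero curvature and seeded", {
  f <- make_filament_phantom(3, curvature_scale = 0, fov = c(64, 64, 1),
                             seed = 9)
  for (p in f$primitives$paths) {
    if (nrow(p) >= 3) {
      segs <- diff(p)
      angles <- atan2(segs[, 2], segs[, 1])
      expect_lt(max(abs(diff(angles))), 1e-12)
    }
  }
  f2 <- make_filament_phantom(3, curvature_scale = 0, fov = c(64, 64, 1),
                              seed = 9)
  expect_identical(f$intensity, f2$intensity)
})

test_that("mosaic phantom draws non-negative cell outlines", {
  m <- make_mosaic_phantom(12, fov = c(64, 64, 1), seed = 3)
  expect_true(all(m$intensity >= 0))
  expect_gt(sum(m$intensity > 0), 200)  # outlines cover many pixels
})

test_that("depth model is affine and its perturbation is seeded", {
  m <- depth_aberration_model(slopes = zernike_vector(11, 0.05),
                              offsets = zernike_vector(6, 0.2))
  expect_zv_equal(aberration_at_depth(m, 0), zernike_vector(6, 0.2))
  expect_equal(zv_amplitude(aberration_at_depth(m, 10), 11), 0.5)
  # affine: value at midpoint is the mean of the endpoints
  mid <- zv_amplitude(aberration_at_depth(m, 5), c(6, 11))
  ends <- (zv_amplitude(aberration_at_depth(m, 0), c(6, 11)) +
           zv_amplitude(aberration_at_depth(m, 10), c(6, 11))) / 2
  expect_equal(mid, ends)
  p1 <- depth_aberration_model(perturb_modes = c(12, 13), perturb_sd = 0.02,
                               seed = 4)
  p2 <- depth_aberration_model(perturb_modes = c(12, 13), perturb_sd = 0.02,
                               seed = 4)
  expect_zv_equal(aberration_at_depth(p1, 7), aberration_at_depth(p2, 7))
  expect_equal(zv_rms(aberration_at_depth(p1, 0)), 0)  # offsets exact at 0
})

test_that("DM model applies fidelity, clipping, mode set, and creep", {
  req <- zernike_vector(c(5, 11), c(0.4, -0.8))
  ideal <- dm_apply(dm_model(), req)
  expect_zv_equal(ideal$achieved, req)
  expect_equal(zv_rms(ideal$residual), 0)
  # uncorrectable mode reported, contributes zero
  out <- dm_apply(dm_model(correctable = 2:22), zernike_vector(37, 1))
  expect_equal(zv_amplitude(out$achieved, 37), 0)
  expect_equal(out$uncorrectable, 37L)
  expect_equal(zv_amplitude(out$residual, 37), 1)
  # fidelity and clip
  part <- dm_apply(dm_model(fidelity = 0.9, clip_rad = 0.5), req)
  expect_equal(zv_amplitude(part$achieved, c(5, 11)), c(0.36, -0.45))
  # creep: closed-form exponential drift between t = 0 and t = Inf
  dm <- dm_model(creep_amplitude = 0.05, creep_tau_s = 10)
  a0 <- zv_amplitude(dm_apply(dm, req, t_s = 0)$achieved, 5)
  ainf <- zv_amplitude(dm_apply(dm, req, t_s = 1e9)$achieved, 5)
  at <- zv_amplitude(dm_apply(dm, req, t_s = 10)$achieved, 5)
  expect_equal(ainf / a0 - 1, 0.05)
  expect_equal(at / a0 - 1, 0.05 * (1 - exp(-1)))
  # bypass arm: nothing correctable
  expect_equal(zv_rms(dm_apply(bypass_dm(), req)$achieved), 0)
})

test_that("noise is seeded and scales with the photon budget", {
  img <- matrix(100, 32, 32)
  n1 <- apply_noise(img, noise_model(seed = 7), 3L)
  n2 <- apply_noise(img, noise_model(seed = 7), 3L)
  expect_identical(n1, n2)
  n3 <- apply_noise(img, noise_model(seed = 7), 4L)
  expect_false(identical(n1, n3))
  expect_identical(apply_noise(img, NULL), img)
})
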