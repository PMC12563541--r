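# Resolution estimation: PWF, bead detection, FWHM fits, spectral cutoffs
# and modulation contrast.

test_that("pseudo-widefield matches the widefield render and keeps extents", {
  cfg <- test_config()
  ph <- make_bead_phantom(4, fov = c(32, 32, 5), min_separation = 700,
                          seed = 4)
  stk <- render_sim_stack(ph, zernike_vector(), cfg,
                          z_positions = c(-125, 0, 125), n_channels = 2)
  pwf <- pseudo_widefield(stk)
  expect_equal(dim(pwf), c(32, 32, 3, 2))
  wf <- render_widefield(ph, zernike_vector(), cfg)
  expect_equal(pwf[, , 2, 1], wf[, , 3], tolerance = 1e-6)
  # zero modulation: the PWF equals any single frame
  stk0 <- render_sim_stack(ph, zernike_vector(), cfg, z_positions = 0,
                           modulation_depth = 0)
  expect_equal(pseudo_widefield(stk0)[, , 1, 1], stk0$frames[, , 1, 1, 1, 1],
               tolerance = 1e-9)
})

test_that("bead detection finds isolated beads without false positives", {
  cfg <- test_config()
  ph <- make_bead_phantom(1, fov = c(48, 48, 9), seed = 1)
  vol <- render_widefield(ph, zernike_vector(), cfg)
  det <- detect_beads(vol, 80, 125, min_separation = 800)
  expect_equal(nrow(det), 1)
  truth_vox <- ph$primitives$centers[1, ] / c(80, 80, 125) + 0.5
  expect_lt(max(abs(det[1, 1:3] - truth_vox)), 1.01)
  # a seeded 50-bead field at default noise: nearly all found, none spurious
  ph50 <- make_bead_phantom(50, fov = c(256, 256, 1), min_separation = 1200,
                            seed = 11)
  img <- render_widefield(ph50, zernike_vector(), cfg,
                          noise = noise_model(seed = 3))
  det50 <- detect_beads(img, 80, 125, min_separation = 1000,
                        intensity_floor = 0.3 * max(img))
  expect_gte(nrow(det50), 45)
  centers <- ph50$primitives$centers
  for (i in seq_len(nrow(det50))) {
    d <- sqrt(((det50[i, 1] - 0.5) * 80 - centers[, 1])^2 +
              ((det50[i, 2] - 0.5) * 80 - centers[, 2])^2)
    expect_lt(min(d), 3 * 80)
  }
})

test_that("FWHM equals 2 sqrt(2 ln 2) sigma on synthetic Gaussian spots", {
  # sigma = 141.6 nm -> FWHM = 333.4 nm
  sig <- 141.6
  n <- 64
  x <- (seq_len(n) - 33) * 40
  g <- exp(-x^2 / (2 * sig^2))
  vol <- array(outer(g, g), c(n, n, 1))
  rep <- bead_fwhm(vol, cbind(x = 33, y = 33, z = 1, intensity = 1),
                   voxel_xy = 40, voxel_z = 125, window_xy = 16)
  expect_equal(rep$lateral_mean_nm, 2 * sqrt(2 * log(2)) * sig,
               tolerance = 0.5 / 333)
  # unbiased across sigma in [100, 400] nm (error < 0.5%)
  for (sig in c(100, 200, 400)) {
    g <- exp(-x^2 / (2 * sig^2))
    vol <- array(outer(g, g), c(n, n, 1))
    rep <- bead_fwhm(vol, cbind(x = 33, y = 33, z = 1, intensity = 1),
                     voxel_xy = 40, voxel_z = 125, window_xy = 24)
    expect_equal(rep$lateral_mean_nm / (2 * sqrt(2 * log(2)) * sig), 1,
                 tolerance = 0.005)
  }
})

test_that("simulated bead FWHM matches the diffraction reference and degrades", {
  cfg <- test_config()
  ph <- make_bead_phantom(1, fov = c(64, 64, 25), seed = 1)
  vol <- render_widefield(ph, zernike_vector(), cfg)
  det <- detect_beads(vol, 80, 125, min_separation = 800)
  rep0 <- bead_fwhm(vol, det, 80, 125)
  # reference: quadrature PSF convolved with the 100 nm sphere profile
  oracle <- debye_psf(cfg, n_pix = 48, z_planes = 0)
  ph1 <- make_bead_phantom(1, fov = c(48, 48, 1), seed = 1)
  ref <- aosim:::conv_fft(ph1$intensity,
                          fft_shift(oracle$intensity, inverse = TRUE))
  repr <- bead_fwhm(ref, detect_beads(ref, 80, 125, min_separation = 800),
                    80, 125)
  expect_equal(rep0$lateral_mean_nm, repr$lateral_mean_nm, tolerance = 0.05)
  # spherical aberration strictly increases the axial FWHM
  vola <- render_widefield(ph, zernike_vector(11, 1), cfg)
  repa <- bead_fwhm(vola, detect_beads(vola, 80, 125, min_separation = 800),
                    80, 125)
  expect_gt(repa$axial_mean_nm, rep0$axial_mean_nm)
})

test_that("spectral cutoffs hit the analytic support and constructed band limits", {
  cfg <- test_config()
  psf <- pupil_to_psf(build_pupil(cfg, n_pix = 256),
                      z_planes = seq(-1500, 1500, 125), out_size = 128)
  sr <- spectral_resolution(psf$intensity, cfg$voxel_xy, cfg$voxel_z)
  cutoff <- 2 * cfg$na / (cfg$lambda_em / 1000)
  bin <- 1 / (128 * cfg$voxel_xy / 1000)
  expect_lt(abs(sr$lateral_cutoff_um - cutoff), bin)
  expect_equal(sr$lateral_resolution_nm, 1000 / sr$lateral_cutoff_um)
  # hard band limit at 2 um^-1 reads back as 500 nm resolution
  n <- 64
  mask <- sqrt(outer(fft_freq(n, 0.08)^2, fft_freq(n, 0.08)^2, "+")) <= 2
  vol <- with_seed(1, {
    f <- stats::fft(array(stats::rnorm(n * n * 8), c(n, n, 8)))
    mask3 <- array(rep(mask, 8), c(n, n, 8))
    Re(stats::fft(f * mask3, inverse = TRUE)) / (n * n * 8)
  })
  sr2 <- spectral_resolution(vol, 80, 125, window = FALSE)
  bin2 <- 1 / (n * 0.08)
  expect_lt(abs(sr2$lateral_cutoff_um - 2), bin2)
  # invariance to intensity scaling and DC offset
  sr3 <- spectral_resolution(5 * vol + 100, 80, 125, window = FALSE)
  expect_equal(sr3$lateral_cutoff_um, sr2$lateral_cutoff_um)
})

test_that("doubled-support rendering about doubles the spectral cutoff", {
  # 40 nm sampling so the doubled support (~8.4/um) stays under Nyquist
  cfg <- optical_config(voxel_xy = 40, pupil_grid_size = 256)
  ph <- make_filament_phantom(8, width_nm = 100, curvature_scale = 0.08,
                              fov = c(128, 128, 1), seed = 5,
                              voxel_xy = 40)
  wf <- render_widefield(ph, zernike_vector(), cfg)
  ds <- render_widefield(ph, zernike_vector(), cfg, doubled_support = TRUE)
  s1 <- spectral_resolution(wf, cfg$voxel_xy, cfg$voxel_z)
  s2 <- spectral_resolution(ds, cfg$voxel_xy, cfg$voxel_z)
  expect_equal(s2$lateral_cutoff_um / s1$lateral_cutoff_um, 2,
               tolerance = 0.15)
})

test_that("modulation contrast reads the pattern depth and tracks the budget", {
  cfg <- test_config()
  # closed form: frames that are the raw pattern itself (uniform scene,
  # no blur) return exactly the first-harmonic depth at the focal plane
  m <- 0.6
  frames <- array(0, c(32, 32, 5, 3, 1, 1))
  for (a in 0:2) for (p in 0:4) {
    frames[, , p + 1, a + 1, 1, 1] <-
      sim_pattern_field(sim_pattern(a, p, modulation_depth = m), cfg,
                        c(32, 32, 1))[, , 1]
  }
  stk <- raw_sim_stack(frames, 80, 125, 0)
  ct <- modulation_contrast(stk)
  expect_equal(ct$contrast, rep(m, 3), tolerance = 1e-3)
  # zero modulation depth: contrast at the noise floor
  ph <- test_bead_phantom(fov = c(32, 32, 1), n = 3)
  reps <- vapply(1:5, function(s) {
    stk0 <- render_sim_stack(ph, zernike_vector(), cfg, z_positions = 0,
                             modulation_depth = 0,
                             noise = noise_model(seed = s))
    mean(modulation_contrast(stk0)$contrast)
  }, numeric(1))
  stk_m <- render_sim_stack(ph, zernike_vector(), cfg, z_positions = 0,
                            modulation_depth = 1,
                            noise = noise_model(seed = 1))
  expect_lt(mean(reps), mean(modulation_contrast(stk_m)$contrast) / 3)
  # contrast decreases as the photon budget shrinks (scattering-like SNR)
  budgets <- c(2000, 200, 20)
  cs <- vapply(budgets, function(b) {
    stk <- render_sim_stack(ph, zernike_vector(), cfg, z_positions = 0,
                            noise = noise_model(photon_budget = b, seed = 2))
    mean(modulation_contrast(stk)$contrast)
  }, numeric(1))
  expect_gt(cs[1], cs[3])
})

test_that("axial degradation is monotone in spherical aberration", {
  cfg <- test_config()
  ph <- make_bead_phantom(1, fov = c(48, 48, 41), seed = 1)
  amps <- c(0, 0.5, 1.0, 1.5)
  direct_width <- function(prof) {
    f <- stats::approx(seq_along(prof), prof / max(prof),
                       xout = seq(1, length(prof), 0.05))
    diff(range(f$x[f$y >= 0.5])) * 125
  }
  vols <- lapply(amps, function(a) {
    render_widefield(ph, zernike_vector(11, a), cfg)
  })
  # direct half-maximum width of the axial profile: monotone over the full
  # amplitude range, including where the profile becomes multi-lobed
  w <- vapply(vols, function(v) {
    det <- detect_beads(v, 80, 125, min_separation = 800)
    p <- round(det[1, 1:3])
    direct_width(v[p[1], p[2], ])
  }, numeric(1))
  expect_true(all(diff(w) > 0))
  # the Gaussian-fit estimator agrees while the profile stays unimodal
  # (beyond ~1 rad the axial profile splits and a Gaussian no longer
  # describes it)
  ax <- vapply(vols[1:3], function(v) {
    det <- detect_beads(v, 80, 125, min_separation = 800)
    bead_fwhm(v, det, 80, 125, window_z = 20)$axial_mean_nm
  }, numeric(1))
  expect_true(all(diff(ax) > 0))
})
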