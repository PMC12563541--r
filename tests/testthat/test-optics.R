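# Pupil construction, FFT PSF/OTF physics, Strehl, and equivalence with the
# direct-quadrature diffraction reference.

test_that("pupil amplitude is confined to the aperture with the stated phase RMS", {
  cfg <- optical_config(voxel_xy = 110, pupil_grid_size = 512)
  p0 <- build_pupil(cfg)
  expect_true(all(p0$amplitude[p0$rho > 1] == 0))
  expect_equal(p0$phase, matrix(0, 512, 512))
  # single-mode RMS and quadrature addition of orthogonal modes
  p1 <- build_pupil(cfg, zernike_vector(11, 1))
  expect_equal(pupil_phase_rms(p1), 1, tolerance = 0.01)
  p2 <- build_pupil(cfg, zernike_vector(c(5, 6), c(0.5, 0.5)))
  expect_equal(pupil_phase_rms(p2), sqrt(0.5), tolerance = 0.01)
})

test_that("pupil support beyond the grid Nyquist is rejected", {
  cfg <- suppressWarnings(optical_config(voxel_xy = 300))
  expect_error(build_pupil(cfg, n_pix = 32), "Nyquist")
})

test_that("PSF energy conservation and axial symmetry", {
  cfg <- test_config()
  z <- seq(-750, 750, 250)
  psf0 <- pupil_to_psf(build_pupil(cfg), z_planes = z, out_size = 64)
  expect_equal(sum(psf0$intensity), 1, tolerance = 1e-9)
  expect_true(all(psf0$intensity >= 0))
  # z -> -z mirror for an aberration-free pupil
  flipped <- psf0$intensity[, , rev(seq_along(z))]
  expect_lt(max(abs(psf0$intensity - flipped)), 1e-6 * max(psf0$intensity))
  # phase-only aberrations preserve total energy (Parseval, full grid)
  psf0f <- pupil_to_psf(build_pupil(cfg), z_planes = z)
  psfaf <- pupil_to_psf(build_pupil(cfg, zernike_vector(c(7, 11), c(1, 1))),
                        z_planes = z)
  expect_equal(psfaf$total_energy / psf0f$total_energy, 1, tolerance = 1e-3)
})

test_that("OTF has DC maximum, Hermitian symmetry, and the analytic lateral support", {
  cfg <- test_config()
  psf <- pupil_to_psf(build_pupil(cfg, zernike_vector(8, 0.7), n_pix = 128),
                      z_planes = seq(-750, 750, 250))
  otf <- psf_to_otf(psf)
  m <- Mod(otf$values)
  ctr <- dim(m) %/% 2 + 1L
  expect_equal(which(m == max(m), arr.ind = TRUE)[1, ], ctr,
               ignore_attr = TRUE)
  expect_true(all(m <= m[ctr[1], ctr[2], ctr[3]] + 1e-9))
  # Hermitian symmetry of the DFT of a real volume: in the DC-centred
  # layout the conjugate of index i sits at 2 * ctr - i
  d <- dim(m)
  i <- c(20, 31, 5); j <- 2 * (d %/% 2 + 1) - i
  expect_equal(otf$values[i[1], i[2], i[3]],
               Conj(otf$values[j[1], j[2], j[3]]), tolerance = 1e-9)
  # lateral support within one frequency bin of 2 NA / lambda_em
  prof <- m[ctr[1]:d[1], ctr[2], ctr[3]]
  kx <- (seq_along(prof) - 1) * otf$freq_step[1]
  support <- max(kx[prof > 1e-7 * max(prof)])
  cutoff <- 2 * cfg$na / (cfg$lambda_em / 1000)
  expect_lt(abs(support - cutoff), otf$freq_step[1])
})

test_that("delta PSF gives a flat OTF modulus", {
  delta <- array(0, c(16, 16, 1))
  delta[9, 9, 1] <- 1
  otf <- psf_to_otf(delta, voxel_xy = 80, voxel_z = 125)
  expect_lt(max(abs(Mod(otf$values) - 1)), 1e-12)
})

test_that("Strehl matches the Marechal approximation and decreases with aberration", {
  cfg <- test_config()
  ideal <- pupil_to_psf(build_pupil(cfg, n_pix = 256), out_size = 128)
  expect_equal(strehl(ideal, ideal), 1)
  ab <- pupil_to_psf(build_pupil(cfg, zernike_vector(11, 1), n_pix = 256),
                     out_size = 128)
  expect_equal(strehl(ab, ideal), exp(-1), tolerance = 0.05)
  amps <- seq(0, 1.5, 0.25)
  s <- vapply(amps, function(a) {
    strehl(pupil_to_psf(build_pupil(cfg, zernike_vector(11, a), n_pix = 256),
                        out_size = 128), ideal)
  }, numeric(1))
  expect_true(all(diff(s) < 0))
  expect_error(strehl(ab, pupil_to_psf(build_pupil(cfg, n_pix = 128),
                                       out_size = 64)), "grids differ")
})

test_that("FFT PSF agrees with the direct-quadrature diffraction reference", {
  cfg <- test_config()
  z <- seq(-500, 500, length.out = 5)
  for (ab in list(zernike_vector(), zernike_vector(11, 1))) {
    oracle <- debye_psf(cfg, ab, n_pix = 32, z_planes = z)
    fftp <- pupil_to_psf(build_pupil(cfg, ab, n_pix = 256),
                         z_planes = z, out_size = 32)
    rel_rms <- sqrt(mean((fftp$intensity - oracle$intensity)^2)) /
      sqrt(mean(oracle$intensity^2))
    expect_lt(rel_rms, 0.01)
  }
  # lateral FWHM of the unaberrated PSF within 5% of the reference
  prof_fwhm <- function(v, step) {
    p <- v / max(v)
    x <- (seq_along(p) - which.max(p)) * step
    f <- stats::approx(x, p, xout = seq(min(x), max(x), length.out = 2000))
    diff(range(f$x[f$y >= 0.5]))
  }
  o <- debye_psf(cfg, n_pix = 32, z_planes = 0)
  f <- pupil_to_psf(build_pupil(cfg, n_pix = 256), z_planes = 0,
                    out_size = 32)
  ctr <- 17
  expect_equal(prof_fwhm(f$intensity[, ctr, 1], cfg$voxel_xy),
               prof_fwhm(o$intensity[, ctr, 1], cfg$voxel_xy),
               tolerance = 0.05)
})
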