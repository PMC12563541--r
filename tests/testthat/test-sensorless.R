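# Sensorless modal AO: scan planning, the Fourier metric, the Gaussian
# optimum fit, and closed-loop parameter recovery on the virtual bench.

test_that("bias-scan plans count images and validate their inputs", {
  expect_equal(plan_bias_scan()$n_images, 40)        # 8 modes x 5 biases
  expect_equal(base_correction_modes(), c(5:11, 22))
  expect_equal(plan_bias_scan(7, c(-1, -0.5, 0, 0.5, 1))$n_images, 5)
  expect_error(plan_bias_scan(integer(0)), "non-empty")
  expect_error(plan_bias_scan(5, c(-1, 1)), "contain 0")
})

test_that("the Fourier metric sits at its noise floor for pure noise", {
  cfg <- test_config()
  vals <- vapply(1:50, function(s) {
    img <- with_seed(s, matrix(stats::rnorm(64^2, 100, 5), 64, 64))
    fourier_metric(img, metric_config(), cfg)
  }, numeric(1))
  # zero lies within 3 resampling SDs of the distribution
  expect_lt(abs(mean(vals)), 3 * stats::sd(vals))
})

test_that("the metric prefers sharp images over aberrated ones (paired)", {
  cfg <- test_config()
  ph <- test_bead_phantom(n = 10)
  wins <- vapply(1:20, function(s) {
    nm <- noise_model(seed = s)
    sharp <- render_widefield(ph, zernike_vector(), cfg, noise = nm)[, , 1]
    blurred <- render_widefield(ph, zernike_vector(11, 1), cfg,
                                noise = nm)[, , 1]
    fourier_metric(sharp, metric_config(), cfg) >
      fourier_metric(blurred, metric_config(), cfg)
  }, logical(1))
  # one-sided sign test at alpha = 0.01
  expect_gte(sum(wins), 15)
})

test_that("the metric is invariant to intensity scaling with DC normalisation", {
  cfg <- test_config()
  ph <- test_bead_phantom(n = 6)
  img <- render_widefield(ph, zernike_vector(), cfg)[, , 1]
  mc <- metric_config(noise_band = 0.25, normalize_dc = TRUE)
  m1 <- fourier_metric(img, mc, cfg)
  m2 <- fourier_metric(5 * img, mc, cfg)
  expect_equal(m1, m2, tolerance = 1e-9)
  expect_warning(fourier_metric(matrix(3, 32, 32), metric_config(), cfg),
                 "constant")
})

test_that("the Gaussian fit recovers exact optima and falls back when it must", {
  # symmetric metrics about zero give optimum exactly zero
  b <- c(-1, -0.5, 0, 0.5, 1)
  sym <- c(0.2, 0.7, 1.0, 0.7, 0.2)
  f <- fit_gaussian_optimum(b, sym)
  expect_equal(f$optimum, 0, tolerance = 1e-9)
  expect_false(f$fallback)
  # self-consistency on noiseless Gaussian data
  truth <- 0.1 + 0.9 * exp(-(b - 0.3)^2 / (2 * 0.7^2))
  f2 <- fit_gaussian_optimum(b, truth)
  expect_equal(f2$optimum, 0.3, tolerance = 1e-6)
  expect_equal(f2$sd, 0.7, tolerance = 1e-4)
  # monotone metrics: fall back to the best scanned bias
  f3 <- fit_gaussian_optimum(b, c(1, 2, 3, 4, 5))
  expect_true(f3$fallback)
  expect_equal(f3$optimum, 1)
  expect_error(fit_gaussian_optimum(c(0, 1), c(1, 2)), ">= 4")
})

test_that("correct_plane recovers single-mode injections on a noiseless bench", {
  for (inj in list(zernike_vector(7, 0.6), zernike_vector(11, -0.4))) {
    sc <- test_scope(sample_aberration = inj)
    res <- correct_plane(sc, plan_bias_scan())
    expect_equal(res$n_images, 40)
    expect_equal(sc$render_count, 40L)  # no hidden acquisitions
    expect_lt(recovery_error(res$sample_correction, inj,
                             base_correction_modes()), 0.05)
  }
  # zero injected aberration: all optima near zero
  sc0 <- test_scope()
  res0 <- correct_plane(sc0, plan_bias_scan())
  expect_lt(max(abs(zv_amplitude(res0$sample_correction,
                                 base_correction_modes()))), 0.05)
})

test_that("a second correction pass removes modal crosstalk of the metric", {
  # secondary spherical couples into primary spherical within a single
  # pass; the repeat pass reduces the residual (composition property)
  inj <- zernike_vector(22, 0.6)
  sc1 <- test_scope(sample_aberration = inj)
  r1 <- correct_plane(sc1, plan_bias_scan())
  sc2 <- test_scope(sample_aberration = inj)
  r2 <- correct_plane(sc2, plan_bias_scan(), passes = 2)
  err1 <- recovery_error(r1$sample_correction, inj, base_correction_modes())
  err2 <- recovery_error(r2$sample_correction, inj, base_correction_modes())
  expect_lte(err2, err1)
  expect_lt(err2, 0.05)
  # residual wavefront RMS never grows with the second pass
  resid1 <- zv_rms(inj + r1$sample_correction)
  resid2 <- zv_rms(inj + r2$sample_correction)
  expect_lte(resid2, resid1 + 1e-6)
})

test_that("corrected imaging beats uncorrected imaging at default noise", {
  cfg <- test_config()
  inj <- zernike_vector(11, 1)
  wins <- vapply(1:10, function(s) {
    sc <- virtual_scope(test_bead_phantom(seed = s), cfg,
                        sample_aberration = inj,
                        noise = noise_model(seed = s), pupil_grid = 128)
    res <- correct_plane(sc, plan_bias_scan(), passes = 2)
    ideal <- pupil_to_psf(build_pupil(cfg, n_pix = 128), out_size = 64)
    corr <- pupil_to_psf(build_pupil(cfg, inj + res$sample_correction,
                                     n_pix = 128), out_size = 64)
    raw <- pupil_to_psf(build_pupil(cfg, inj, n_pix = 128), out_size = 64)
    strehl(corr, ideal) > strehl(raw, ideal)
  }, logical(1))
  expect_equal(sum(wins), 10)
})

test_that("the system flat is measured first and kept separate", {
  sysab <- zernike_vector(6, 0.4)
  sc <- test_scope(system_aberration = sysab)
  flat <- system_flat_calibration(sc, plan_bias_scan())
  expect_lt(recovery_error(flat, sysab, base_correction_modes()), 0.05)
  # sample correction on top of the flat reports the two parts separately
  inj <- zernike_vector(7, 0.5)
  sc2 <- test_scope(system_aberration = sysab, sample_aberration = inj)
  res <- correct_plane(sc2, plan_bias_scan(), initial = flat)
  expect_zv_equal(res$system_flat, flat)
  expect_zv_equal(res$combined, flat + res$sample_correction)
  expect_lt(recovery_error(res$sample_correction, inj,
                           base_correction_modes()), 0.05)
})

test_that("scan results export as a long-format table", {
  sc <- test_scope(sample_aberration = zernike_vector(7, 0.3))
  res <- correct_plane(sc, plan_bias_scan(c(7, 11), c(-1, -0.5, 0, 0.5, 1)))
  tab <- scan_table(res)
  expect_equal(nrow(tab), 10)
  expect_setequal(unique(tab$mode), c(7, 11))
  expect_named(tab, c("pass", "mode", "bias", "metric", "optimum",
                      "fallback"))
})
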