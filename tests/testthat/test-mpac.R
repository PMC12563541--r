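# Multi-position aberration correction: linear per-mode depth fits.

test_that("two anchors are interpolated exactly", {
  tab <- mpac_fit(list(
    list(z = 0, correction = zernike_vector(11, 0)),
    list(z = 10, correction = zernike_vector(11, 1))))
  f <- tab$fit[["11"]]
  expect_equal(f$slope, 0.1)
  expect_equal(f$intercept, 0)
  expect_equal(zv_amplitude(mpac_predict(tab, 5), 11), 0.5)
  expect_equal(zv_amplitude(mpac_predict(tab, 0), 11), 0)
  expect_equal(zv_amplitude(mpac_predict(tab, 10), 11), 1)
  expect_error(mpac_fit(list(list(z = 0, correction = zernike_vector()))),
               ">= 2")
  expect_error(mpac_fit(list(list(z = 1, correction = zernike_vector()),
                             list(z = 1, correction = zernike_vector()))),
               "distinct")
})

test_that("collinear anchors leave zero residual; missing modes count as zero", {
  tab <- mpac_fit(list(
    list(z = 0, correction = zernike_vector(c(6, 11), c(0.1, 0.0))),
    list(z = 5, correction = zernike_vector(c(6, 11), c(0.1, 0.5))),
    list(z = 10, correction = zernike_vector(11, 1.0))))  # 6 absent -> 0
  expect_equal(tab$fit[["11"]]$residual_rms, 0, tolerance = 1e-12)
  # mode 6 data are (0.1, 0.1, 0): not collinear, residual reported
  expect_gt(tab$fit[["6"]]$residual_rms, 0)
  # midpoint of two anchors is the per-mode arithmetic mean
  tab2 <- mpac_fit(list(
    list(z = 2, correction = zernike_vector(c(5, 11), c(0.2, -0.4))),
    list(z = 8, correction = zernike_vector(c(5, 11), c(0.6, 0.0)))))
  expect_equal(zv_amplitude(mpac_predict(tab2, 5), c(5, 11)), c(0.4, -0.2))
})

test_that("any affine depth model is recovered exactly from two anchors", {
  with_seed(42, {
    for (rep in 1:5) {
      modes <- sort(sample(c(4:15, 22), 4))
      slopes <- stats::runif(4, -0.1, 0.1)
      offsets <- stats::runif(4, -0.5, 0.5)
      model <- depth_aberration_model(zernike_vector(modes, slopes),
                                      zernike_vector(modes, offsets))
      za <- sort(stats::runif(2, 0, 20))
      anchors <- lapply(za, function(z) {
        list(z = z, correction = zv_scale(aberration_at_depth(model, z), -1))
      })
      tab <- mpac_fit(anchors)
      for (z in c(mean(za), 3, 18)) {
        pred <- suppressWarnings(mpac_predict(tab, z))
        truth <- zv_scale(aberration_at_depth(model, z), -1)
        expect_equal(zv_amplitude(pred, modes), zv_amplitude(truth, modes),
                     tolerance = 1e-9)
      }
    }
  })
})

test_that("extrapolation beyond the anchor span warns but proceeds", {
  tab <- mpac_fit(list(
    list(z = 0, correction = zernike_vector(11, 0)),
    list(z = 10, correction = zernike_vector(11, 1))))
  expect_warning(mpac_predict(tab, 15), "extrapolates")
  expect_equal(zv_amplitude(suppressWarnings(mpac_predict(tab, 15)), 11),
               1.5)
})

test_that("anchors measured by the correction routine predict intermediate depths", {
  # depth model with a spherical slope; correct at z = 0 and z = 10 via the
  # sensorless routine, then ask MPAC for z = 6
  model <- depth_aberration_model(slopes = zernike_vector(11, 0.05),
                                  offsets = zernike_vector(6, 0.2))
  anchors <- lapply(c(0, 10), function(z) {
    sc <- virtual_scope(test_bead_phantom(), test_config(),
                        sample_aberration = model, depth_um = z,
                        pupil_grid = 128)
    res <- correct_plane(sc, plan_bias_scan(), passes = 2)
    list(z = z, correction = res$sample_correction)
  })
  tab <- mpac_fit(anchors)
  pred <- mpac_predict(tab, 6)
  truth <- zv_scale(aberration_at_depth(model, 6), -1)
  err <- max(abs(zv_amplitude(pred, base_correction_modes()) -
                 zv_amplitude(truth, base_correction_modes())))
  expect_lt(err, 0.1)
})

test_that("per-plane command tables enumerate every section", {
  tab <- mpac_fit(list(
    list(z = 0, correction = zernike_vector(c(6, 11), c(0.1, 0))),
    list(z = 10, correction = zernike_vector(c(6, 11), c(0.1, 1)))))
  cmd <- mpac_command_table(tab, seq(0, 10, 2.5))
  expect_equal(nrow(cmd), 5 * 2)
  expect_equal(cmd$amplitude_rad[cmd$mode == 11 & cmd$z_um == 5], 0.5)
})
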