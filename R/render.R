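# Image formation: widefield and structured-illumination rendering of
# phantoms through the aberrated scalar PSF, with seeded camera noise.
# Convolutions are circular (periodic boundaries); phantoms keep their
# structures away from the FOV edge, which the generators do by default.

conv_fft <- function(a, kern_corner) {
  re <- Re(stats::fft(stats::fft(a) * stats::fft(kern_corner), inverse = TRUE)) /
    length(a)
  pmax(re, 0)   # clip the tiny negative ringing of finite-precision FFTs
}

# PSF volume -> corner-origin convolution kernel matching a phantom grid.
psf_kernel <- function(config, aberration, n_xy, n_z, voxel_z,
                       pupil_grid = max(config$pupil_grid_size, n_xy)) {
  zoff <- (seq_len(n_z) - (n_z %/% 2 + 1L)) * voxel_z
  pupil <- build_pupil(config, aberration, n_pix = pupil_grid)
  psf <- pupil_to_psf(pupil, z_planes = zoff, out_size = n_xy)
  k <- psf$intensity / sum(psf$intensity)
  fft_shift(k, inverse = TRUE)
}

# Expected photon gain of a scene: photon_budget / peak of the unaberrated
# render, so aberrated images of the same scene are dimmer at equal budget.
scene_gain <- function(phantom, config, noise) {
  if (is.null(noise)) return(1)
  d <- dim(phantom$intensity)
  kern <- psf_kernel(config, zernike_vector(), d[1], d[3], phantom$voxel_z)
  ideal <- conv_fft(phantom$intensity, kern)
  noise$photon_budget / max(ideal)
}

#' Render a widefield image volume of a phantom
#'
#' Convolves the phantom with the PSF of the given aberration and adds
#' Poisson shot noise and Gaussian read noise if a noise model is supplied.
#' With a [depth_aberration_model()] the volume is rendered plane by plane
#' with the depth-local PSF (a locally shift-invariant approximation); with
#' a plain [zernike_vector()] a single 3D convolution is used.
#'
#' @param phantom a [make_bead_phantom()]-style `phantom`.
#' @param aberration a [zernike_vector()] or a [depth_aberration_model()].
#' @param config an [optical_config()].
#' @param noise a [noise_model()] or `NULL` for noiseless rendering.
#' @param depth_offset_um depth (um) of the phantom's central plane, used to
#'   evaluate a depth model.
#' @param doubled_support render through an idealised doubled-support PSF:
#'   the widefield PSF of a system with twice the cutoff (half the
#'   wavelength), i.e. an OTF of doubled support with undiminished pass-band
#'   amplitude, emulating the effective response of a well-reconstructed SIM
#'   volume when only the frequency support matters. Requires sampling fine
#'   enough for the doubled support (`voxel_xy <= lambda_em / (8 NA)`).
#' @param gain photons per phantom-intensity unit; computed from the noise
#'   model's photon budget when `NULL`.
#' @return numeric array, same dimensions as the phantom volume. Noisy
#'   output is clamped at zero (camera counts).
#' @export
render_widefield <- function(phantom, aberration = zernike_vector(),
                             config = optical_config(), noise = NULL,
                             depth_offset_um = 0, doubled_support = FALSE,
                             gain = NULL) {
  stopifnot(inherits(phantom, "phantom"))
  d <- dim(phantom$intensity)
  if (d[1] != d[2]) stop("square lateral FOV required", call. = FALSE)
  if (is.null(gain)) gain <- scene_gain(phantom, config, noise)
  mk <- function(ab) {
    cfg_eff <- config
    if (doubled_support) {
      cfg_eff$lambda_em <- config$lambda_em / 2
      cfg_eff$lambda_ex <- config$lambda_ex / 2
    }
    psf_kernel(cfg_eff, ab, d[1], d[3], phantom$voxel_z)
  }
  if (inherits(aberration, "depth_aberration_model")) {
    out <- array(0, d)
    zc <- d[3] %/% 2 + 1L
    for (iz in seq_len(d[3])) {
      depth <- max(0, depth_offset_um + (iz - zc) * phantom$voxel_z / 1000)
      kern <- mk(aberration_at_depth(aberration, depth))
      out[, , iz] <- conv_fft(phantom$intensity, kern)[, , iz]
    }
  } else {
    out <- conv_fft(phantom$intensity, mk(aberration))
  }
  expected <- out * gain
  if (is.null(noise)) return(expected)
  res <- apply_noise(expected, noise, frame_index = 0L)
  pmax(res, 0)
}

#' Raw SIM stack container
#'
#' Ordered raw-frame container of a 3D-SIM acquisition: a 6D array indexed
#' `[x, y, phase, angle, z, channel]` with the standard 5-phase x 3-angle
#' complement, plus acquisition metadata.
#'
#' @param frames 6D numeric array `[x, y, 5, 3, n_z, n_channels]`,
#'   non-negative.
#' @param voxel_xy,voxel_z voxel sizes, nm.
#' @param z_positions axial plane positions, nm.
#' @param metadata free-form list (patterns, focus mode, DM state,
#'   exposure).
#' @return object of class `raw_sim_stack`.
#' @export
raw_sim_stack <- function(frames, voxel_xy, voxel_z, z_positions,
                          metadata = list()) {
  d <- dim(frames)
  if (length(d) != 6 || d[3] != 5 || d[4] != 3) {
    stop("frames must be [x, y, 5 phases, 3 angles, z, channel]", call. = FALSE)
  }
  if (length(z_positions) != d[5]) stop("z_positions length mismatch", call. = FALSE)
  if (any(frames < 0)) stop("frames must be non-negative", call. = FALSE)
  structure(list(frames = frames, voxel_xy = voxel_xy, voxel_z = voxel_z,
                 z_positions = z_positions, metadata = metadata),
            class = "raw_sim_stack")
}

#' @export
print.raw_sim_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<raw_sim_stack> %d x %d px, %d phases x %d angles x %d z x %d channel(s) = %d frames\n",
    d[1], d[2], d[3], d[4], d[5], d[6], prod(d[3:6])))
  invisible(x)
}

#' Number of raw frames in a stack
#' @param stack a `raw_sim_stack`.
#' @return integer frame count.
#' @export
n_frames <- function(stack) {
  prod(dim(stack$frames)[3:6])
}

#' Render a raw 3D-SIM stack of a phantom
#'
#' For every (phase, angle, z, channel) frame: illuminate the phantom with
#' the SI pattern (whose axial modulation origin tracks the focal plane, as
#' in synchronised pattern/focus scanning), blur with the (depth-local) PSF,
#' extract the focal plane, and add seeded noise. Frame order for noise
#' seeding is canonical: phase fastest, then angle, z, channel.
#'
#' @param phantom a `phantom`.
#' @param aberration a [zernike_vector()] or [depth_aberration_model()].
#' @param config an [optical_config()].
#' @param z_positions focal-plane positions, nm, relative to the phantom
#'   centre; each must coincide with a phantom z plane.
#' @param n_channels number of channels (identical optics per channel).
#' @param noise a [noise_model()] or `NULL`.
#' @param freq_frac,axial_modulation,modulation_depth pattern parameters,
#'   see [sim_pattern()].
#' @param depth_offset_um depth (um) of the phantom's central plane.
#' @param focus_mode `"mechanical"` or `"remote"` (metadata; the rendered
#'   physics is identical because pattern and focal plane move together in
#'   both modes).
#' @return a [raw_sim_stack()].
#' @export
render_sim_stack <- function(phantom, aberration = zernike_vector(),
                             config = optical_config(),
                             z_positions = 0, n_channels = 1, noise = NULL,
                             freq_frac = 0.8, axial_modulation = TRUE,
                             modulation_depth = 1, depth_offset_um = 0,
                             focus_mode = c("mechanical", "remote")) {
  focus_mode <- match.arg(focus_mode)
  stopifnot(inherits(phantom, "phantom"))
  if (is.unsorted(z_positions, strictly = TRUE) && length(z_positions) > 1) {
    stop("z_positions must be strictly increasing", call. = FALSE)
  }
  d <- dim(phantom$intensity)
  zc <- d[3] %/% 2 + 1L
  iz_of <- round(z_positions / phantom$voxel_z) + zc
  if (any(iz_of < 1 | iz_of > d[3]) ||
      any(abs(z_positions - (iz_of - zc) * phantom$voxel_z) > 1e-6)) {
    stop("each z position must coincide with a phantom plane", call. = FALSE)
  }
  gain <- scene_gain(phantom, config, noise)
  nz <- length(z_positions)
  frames <- array(0, c(d[1], d[2], 5, 3, nz, n_channels))
  depth_model <- inherits(aberration, "depth_aberration_model")
  kern_const <- if (!depth_model) {
    psf_kernel(config, aberration, d[1], d[3], phantom$voxel_z)
  }
  idx <- 0L
  for (ch in seq_len(n_channels)) {
    for (zi in seq_len(nz)) {
      kern <- if (depth_model) {
        depth <- max(0, depth_offset_um +
                       (iz_of[zi] - zc) * phantom$voxel_z / 1000)
        psf_kernel(config, aberration_at_depth(aberration, depth),
                   d[1], d[3], phantom$voxel_z)
      } else kern_const
      for (a in 0:2) {
        for (p in 0:4) {
          pat <- sim_pattern(a, p, freq_frac, axial_modulation,
                             modulation_depth)
          illum <- sim_pattern_field(pat, config, d,
                                     voxel_xy = phantom$voxel_xy,
                                     voxel_z = phantom$voxel_z,
                                     z_origin_nm = z_positions[zi])
          blurred <- conv_fft(phantom$intensity * illum, kern)
          expected <- blurred[, , iz_of[zi]] * gain
          idx <- idx + 1L
          fr <- apply_noise(expected, noise, frame_index = idx)
          frames[, , p + 1L, a + 1L, zi, ch] <- pmax(fr, 0)
        }
      }
    }
  }
  raw_sim_stack(frames, phantom$voxel_xy, phantom$voxel_z, z_positions,
                metadata = list(freq_frac = freq_frac,
                                axial_modulation = axial_modulation,
                                modulation_depth = modulation_depth,
                                focus_mode = focus_mode,
                                depth_offset_um = depth_offset_um,
                                gain = gain,
                                noise = noise))
}
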