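# Depth-dependent aberrations, the deformable-mirror model, and the camera
# noise model: the "imperfections" half of the virtual microscope.

#' Depth-dependent aberration model
#'
#' Dominant sample-induced aberrations (notably spherical, from refractive
#' index mismatch) grow in proportion to imaging depth. The model is affine
#' per mode: `a_j(depth) = offset_j + slope_j * depth`, optionally plus a
#' seeded random high-order perturbation whose amplitude also scales with
#' depth (so evaluation at depth 0 returns the offsets exactly).
#'
#' @param slopes [zernike_vector()] of per-mode slopes, rad per um of depth.
#' @param offsets [zernike_vector()] of constant offsets, rad.
#' @param perturb_modes optional Noll indices receiving the random
#'   perturbation.
#' @param perturb_sd SD of the perturbation, rad per um of depth.
#' @param seed seed fixing the perturbation draw.
#' @return object of class `depth_aberration_model`.
#' @export
depth_aberration_model <- function(slopes = zernike_vector(),
                                   offsets = zernike_vector(),
                                   perturb_modes = NULL, perturb_sd = 0,
                                   seed = 1) {
  draw <- if (!is.null(perturb_modes) && perturb_sd > 0) {
    with_seed(seed, stats::rnorm(length(perturb_modes)))
  } else numeric(0)
  structure(list(slopes = slopes, offsets = offsets,
                 perturb_modes = perturb_modes, perturb_sd = perturb_sd,
                 perturb_draw = draw, seed = seed),
            class = "depth_aberration_model")
}

#' Evaluate a depth-aberration model
#'
#' @param model a [depth_aberration_model()].
#' @param depth_um imaging depth, um (>= 0).
#' @return a [zernike_vector()] of modal amplitudes at that depth.
#' @export
aberration_at_depth <- function(model, depth_um) {
  stopifnot(inherits(model, "depth_aberration_model"), depth_um >= 0)
  out <- model$offsets + zv_scale(model$slopes, depth_um)
  if (length(model$perturb_draw)) {
    out <- out + zernike_vector(model$perturb_modes,
                                model$perturb_sd * depth_um * model$perturb_draw)
  }
  out
}

#' Deformable-mirror model
#'
#' An idealised membrane DM: it can only reproduce a finite set of Zernike
#' modes, each to a stated fidelity, with a hard amplitude clip, and
#' (optionally) a slow single-exponential creep of the achieved shape.
#' Defaults describe an ideal mirror so correction logic can be tested in
#' isolation; a `bypass_dm()` (flat mirror, nothing correctable) stands in
#' for imaging without AO.
#'
#' @param correctable Noll indices the mirror can produce.
#' @param fidelity achieved fraction of the requested amplitude, scalar or
#'   per-mode named vector.
#' @param clip_rad hard limit on per-mode achieved amplitude, rad.
#' @param creep_amplitude fractional drift of the held shape at t = Inf
#'   (0 disables creep).
#' @param creep_tau_s creep time constant, seconds.
#' @param settle_time_ms settle time after a shape change (metadata only).
#' @return object of class `dm_model`.
#' @export
dm_model <- function(correctable = 2:28, fidelity = 1, clip_rad = Inf,
                     creep_amplitude = 0, creep_tau_s = 30,
                     settle_time_ms = 1) {
  structure(list(correctable = as.integer(correctable), fidelity = fidelity,
                 clip_rad = clip_rad, creep_amplitude = creep_amplitude,
                 creep_tau_s = creep_tau_s, settle_time_ms = settle_time_ms),
            class = "dm_model")
}

#' @rdname dm_model
#' @export
bypass_dm <- function() dm_model(correctable = integer(0))

#' Apply a requested Zernike shape to the DM model
#'
#' @param dm a [dm_model()].
#' @param requested [zernike_vector()] of requested amplitudes, rad.
#' @param t_s time (s) the shape has been held, for the creep term.
#' @return list with `achieved` (a `zernike_vector`), `residual` (the
#'   uncorrectable / lost part, requested - achieved) and `uncorrectable`
#'   (Noll indices outside the mirror's mode set).
#' @export
dm_apply <- function(dm, requested, t_s = 0) {
  stopifnot(inherits(dm, "dm_model"), inherits(requested, "zernike_vector"))
  j <- zv_modes(requested)
  amp <- zv_amplitude(requested, j)
  ok <- j %in% dm$correctable
  fid <- if (length(dm$fidelity) > 1) {
    f <- dm$fidelity[as.character(j)]
    f[is.na(f)] <- 1
    f
  } else rep(dm$fidelity, length(j))
  ach <- ifelse(ok, fid * pmax(-dm$clip_rad, pmin(dm$clip_rad, amp)), 0)
  if (dm$creep_amplitude != 0) {
    ach <- ach * (1 + dm$creep_amplitude * (1 - exp(-t_s / dm$creep_tau_s)))
  }
  achieved <- zernike_vector(j, ach,
                             reference_wavelength = requested$reference_wavelength)
  list(achieved = achieved, residual = requested - achieved,
       uncorrectable = j[!ok])
}

#' Camera/illumination noise model
#'
#' Poisson shot noise on the expected photon signal plus Gaussian read
#' noise, with a constant background. The photon budget is the expected peak
#' photon count of the aberration-free image of the scene, so aberrated
#' images are genuinely dimmer at equal budget. Defaults make
#' metric-optimisation tests realistically noisy.
#'
#' @param photon_budget expected peak photons/frame of the unaberrated
#'   render.
#' @param read_noise_sd read noise SD, electrons.
#' @param background constant background, photons.
#' @param seed base RNG seed; each frame uses `seed + frame index` so
#'   acquisitions are reproducible frame-by-frame.
#' @return object of class `noise_model`, or `NULL` semantics (pass
#'   `noise = NULL` to render noiselessly).
#' @export
noise_model <- function(photon_budget = 500, read_noise_sd = 2,
                        background = 5, seed = 1) {
  stopifnot(photon_budget >= 0, read_noise_sd >= 0, background >= 0)
  structure(list(photon_budget = photon_budget,
                 read_noise_sd = read_noise_sd,
                 background = background, seed = seed),
            class = "noise_model")
}

#' Apply the noise model to an expected photon image
#'
#' Returns a noisy realisation (Poisson shot noise + Gaussian read noise on
#' top of the background), deterministic in `(noise$seed, frame_index)`.
#' A `NULL` noise model returns the input unchanged.
#'
#' @param expected expected photon image (any-dimensional array).
#' @param noise a [noise_model()] or `NULL`.
#' @param frame_index frame counter combined with the base seed.
#' @return array of the same shape.
#' @export
apply_noise <- function(expected, noise, frame_index = 0L) {
  if (is.null(noise)) return(expected)
  d <- dim(expected)
  lam <- pmax(0, expected + noise$background)
  with_seed(noise$seed + frame_index, {
    counts <- stats::rpois(length(lam), lam) +
      stats::rnorm(length(lam), 0, noise$read_noise_sd)
    array(counts, d)
  })
}
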