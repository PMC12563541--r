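# The virtual microscope handle: a self-contained bench that renders
# widefield frames of a phantom on demand, through a configurable chain of
# system aberration + depth-dependent sample aberration + deformable-mirror
# state + camera noise. The sensorless-AO and calibration routines only ever
# talk to this interface, mirroring how they would drive real hardware.

#' Create a virtual microscope
#'
#' @param phantom a `phantom`; its z-projection is treated as a thin
#'   fluorescent layer at the focal plane (the standard sparse-bead
#'   calibration geometry).
#' @param config an [optical_config()].
#' @param system_aberration fixed instrument-intrinsic [zernike_vector()].
#' @param sample_aberration a [zernike_vector()] or a
#'   [depth_aberration_model()] evaluated at `depth_um`.
#' @param depth_um imaging depth of the focal plane, um.
#' @param dm a [dm_model()] (ideal by default); use [bypass_dm()] for the
#'   no-AO control arm.
#' @param noise a [noise_model()] or `NULL` for a noiseless bench.
#' @param pupil_grid FFT grid used for the scope's PSFs.
#' @return object of class `virtual_scope` (environment). The fields
#'   `render_count` and `noise_counter` track acquisition bookkeeping.
#' @export
virtual_scope <- function(phantom, config = optical_config(),
                          system_aberration = zernike_vector(),
                          sample_aberration = zernike_vector(),
                          depth_um = 0, dm = dm_model(), noise = NULL,
                          pupil_grid = max(config$pupil_grid_size,
                                           dim(phantom$intensity)[1])) {
  stopifnot(inherits(phantom, "phantom"), inherits(config, "optical_config"))
  e <- new.env(parent = emptyenv())
  e$phantom <- phantom
  e$config <- config
  e$system_aberration <- system_aberration
  e$sample_aberration <- sample_aberration
  e$depth_um <- depth_um
  e$dm <- dm
  e$noise <- noise
  e$n <- dim(phantom$intensity)[1]
  e$N <- as.integer(pupil_grid)
  layer <- apply(phantom$intensity, c(1, 2), sum)
  e$layerF <- stats::fft(layer)
  # pupil geometry on the N-grid, cached once
  geo <- build_pupil(config, zernike_vector(), n_pix = e$N)
  e$mask_idx <- which(geo$mask)
  e$rho <- geo$rho[e$mask_idx]
  e$theta <- geo$theta[e$mask_idx]
  e$nu_z <- axial_frequency(geo)[e$mask_idx]
  e$basis <- new.env(parent = emptyenv())
  e$render_count <- 0L
  e$noise_counter <- 0L
  # photon gain referenced to the ideal (zero-aberration) frame peak
  e$gain <- 1
  if (!is.null(noise)) {
    ideal <- scope_expected_frame(structure(e, class = "virtual_scope"),
                                  total_override = zernike_vector())
    e$gain <- noise$photon_budget / max(ideal)
  }
  structure(e, class = "virtual_scope")
}

#' @export
print.virtual_scope <- function(x, ...) {
  cat(sprintf(
    "<virtual_scope> %d px frames, depth %g um, %s, %d frame(s) rendered\n",
    x$n, x$depth_um, if (is.null(x$noise)) "noiseless" else "noisy",
    x$render_count))
  invisible(x)
}

scope_basis <- function(scope, j) {
  key <- as.character(j)
  if (is.null(scope$basis[[key]])) {
    scope$basis[[key]] <- zernike_eval(j, scope$rho, scope$theta,
                                       outside = "zero")
  }
  scope$basis[[key]]
}

# Aberration actually present in the imaging path for a DM request.
scope_total_aberration <- function(scope, applied = zernike_vector(),
                                   t_s = 0) {
  sample <- if (inherits(scope$sample_aberration, "depth_aberration_model")) {
    aberration_at_depth(scope$sample_aberration, scope$depth_um)
  } else scope$sample_aberration
  achieved <- dm_apply(scope$dm, applied, t_s = t_s)$achieved
  scope$system_aberration + sample + achieved
}

# Expected (noise-free, unit-gain) in-focus frame for a total pupil phase;
# optionally at an axial offset z_nm of the detection plane.
scope_expected_frame <- function(scope, applied = zernike_vector(),
                                 z_nm = 0, t_s = 0, total_override = NULL) {
  total <- if (is.null(total_override)) {
    scope_total_aberration(scope, applied, t_s)
  } else total_override
  N <- scope$N
  n <- scope$n
  phase <- numeric(length(scope$mask_idx))
  for (j in zv_modes(total)) {
    a <- zv_amplitude(total, j)
    if (a != 0) phase <- phase + a * scope_basis(scope, j)
  }
  if (z_nm != 0) phase <- phase + 2 * pi * scope$nu_z * z_nm
  pupil <- matrix(0+0i, N, N)
  pupil[scope$mask_idx] <- exp(1i * phase)
  field <- stats::fft(pupil)
  psf <- Mod(field)^2
  psf <- psf / sum(psf)
  if (N != n) {
    ctr <- N %/% 2 + 1L
    half <- n %/% 2
    rows <- (ctr - half):(ctr - half + n - 1L)
    psf <- fft_shift(fft_shift(psf)[rows, rows], inverse = TRUE)
  }
  img <- Re(stats::fft(scope$layerF * stats::fft(psf), inverse = TRUE)) / n^2
  pmax(img, 0)
}

#' Acquire one widefield frame from the virtual microscope
#'
#' Applies `applied` to the DM, forms the in-focus image of the scene
#' through system + sample + DM aberrations, scales to the photon gain and
#' adds seeded noise. Every call increments the scope's `render_count` (the
#' acquisition budget) and its noise counter (so repeated acquisitions of
#' the same state differ by shot noise, reproducibly for a fresh scope).
#'
#' @param scope a [virtual_scope()].
#' @param applied requested DM shape, a [zernike_vector()].
#' @param z_nm axial offset of the detection focal plane, nm (used by
#'   remote-focus calibration scans).
#' @param t_s DM hold time for the creep model.
#' @return 2D numeric frame.
#' @export
scope_render <- function(scope, applied = zernike_vector(), z_nm = 0,
                         t_s = 0) {
  img <- scope_expected_frame(scope, applied, z_nm = z_nm, t_s = t_s) *
    scope$gain
  scope$render_count <- scope$render_count + 1L
  if (is.null(scope$noise)) return(img)
  scope$noise_counter <- scope$noise_counter + 1L
  pmax(apply_noise(img, scope$noise, frame_index = scope$noise_counter), 0)
}

#' Acquire a through-focus bead volume from the virtual microscope
#'
#' A mechanical z-scan of the detection plane: one frame per plane, each
#' counted against the acquisition budget.
#'
#' @param scope a [virtual_scope()].
#' @param applied requested DM shape.
#' @param z_planes_nm detection-plane offsets, nm.
#' @return array `[n, n, length(z_planes_nm)]`.
#' @export
scope_render_volume <- function(scope, applied = zernike_vector(),
                                z_planes_nm = 0) {
  out <- array(0, c(scope$n, scope$n, length(z_planes_nm)))
  for (i in seq_along(z_planes_nm)) {
    out[, , i] <- scope_render(scope, applied, z_nm = z_planes_nm[i])
  }
  out
}

#' Reset the acquisition bookkeeping of a scope
#' @param scope a [virtual_scope()].
#' @return the scope, invisibly.
#' @export
scope_reset <- function(scope) {
  scope$render_count <- 0L
  scope$noise_counter <- 0L
  invisible(scope)
}
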