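#' Optical configuration of the virtual microscope
#'
#' Bundles the physical parameters that every Fourier-optics computation
#' needs. Defaults describe a 60x/1.1 NA water-immersion system imaging a
#' green channel (488 nm excitation, 525 nm emission).
#'
#' @param na numerical aperture; must satisfy `0 < na < n_immersion`.
#' @param lambda_ex,lambda_em excitation / emission wavelengths, nm.
#' @param n_immersion,n_sample refractive indices of immersion medium and
#'   sample (water by default).
#' @param voxel_xy,voxel_z sampling of rendered volumes, nm. For
#'   SIM-resolution work `voxel_xy` should satisfy the doubled-support
#'   Nyquist bound `lambda_em / (4 * na)`; a warning is issued otherwise.
#' @param pupil_grid_size FFT grid size (samples per axis) used when
#'   computing pupils and PSFs; the clear aperture occupies
#'   `2 * na * voxel_xy * pupil_grid_size / lambda_em` of those samples, so
#'   the default 256 leaves at least two-fold zero padding at the default
#'   sampling.
#' @return object of class `optical_config`.
#' @examples
#' cfg <- optical_config()
#' cfg$na
#' @export
optical_config <- function(na = 1.1, lambda_ex = 488, lambda_em = 525,
                           n_immersion = 1.33, n_sample = 1.33,
                           voxel_xy = 80, voxel_z = 125,
                           pupil_grid_size = 256) {
  if (!(na > 0 && na < n_immersion)) {
    stop("require 0 < na < n_immersion", call. = FALSE)
  }
  if (lambda_ex <= 0 || lambda_em <= 0) stop("wavelengths must be > 0", call. = FALSE)
  if (voxel_xy <= 0 || voxel_z <= 0) stop("voxel sizes must be > 0", call. = FALSE)
  if (voxel_xy > lambda_em / (4 * na)) {
    warning(sprintf(
      "voxel_xy = %g nm exceeds the SIM Nyquist bound lambda_em/(4 na) = %.1f nm",
      voxel_xy, lambda_em / (4 * na)), call. = FALSE)
  }
  structure(list(na = na, lambda_ex = lambda_ex, lambda_em = lambda_em,
                 n_immersion = n_immersion, n_sample = n_sample,
                 voxel_xy = voxel_xy, voxel_z = voxel_z,
                 pupil_grid_size = as.integer(pupil_grid_size)),
            class = "optical_config")
}

#' @export
print.optical_config <- function(x, ...) {
  cat(sprintf(paste0("<optical_config> NA %.2f, ex/em %g/%g nm, n %g/%g, ",
                     "voxel %g x %g nm, pupil grid %d\n"),
              x$na, x$lambda_ex, x$lambda_em, x$n_immersion, x$n_sample,
              x$voxel_xy, x$voxel_z, x$pupil_grid_size))
  invisible(x)
}

#' DFT sample frequencies
#'
#' Frequencies of an `n`-point DFT with sample spacing `d`, in cycles per
#' unit of `d`, unshifted (DC first), matching `stats::fft` ordering.
#'
#' @param n number of samples.
#' @param d sample spacing.
#' @return numeric vector of length `n`.
#' @export
fft_freq <- function(n, d = 1) {
  k <- c(seq.int(0L, ceiling(n / 2) - 1L), seq.int(-floor(n / 2), -1L))
  k / (n * d)
}

#' Shift the DC component of an array to (or from) the centre
#'
#' Moves DC from element `[1, 1, ...]` to the centre index
#' (`n %/% 2 + 1` per axis); `inverse = TRUE` undoes it.
#'
#' @param x vector, matrix or array.
#' @param inverse logical.
#' @return `x` with permuted elements.
#' @export
fft_shift <- function(x, inverse = FALSE) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  idx <- lapply(d, function(n) {
    # forward: element 1 (DC) lands on n %/% 2 + 1; inverse undoes it.
    # the two differ for odd n.
    s <- if (inverse) n %/% 2 else n - n %/% 2
    1L + (seq_len(n) - 1L + s) %% n
  })
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

#' Build a pupil function from an optical configuration and an aberration
#'
#' Samples the back-focal-plane complex amplitude on the Fourier grid of an
#' `n_pix`-pixel image with `voxel_xy` sampling: uniform amplitude inside the
#' clear aperture (radius `na / lambda` in frequency space), zero outside,
#' and phase equal to the Zernike expansion of `aberration`. The rim is a
#' hard cut by default; one-sample anti-aliasing of the rim is available
#' behind a flag but slightly apodises the aperture, so it is off by default.
#'
#' @param config an [optical_config()].
#' @param aberration a [zernike_vector()] of phase radians (empty for an
#'   unaberrated pupil).
#' @param n_pix FFT grid size; defaults to `config$pupil_grid_size`.
#' @param lambda wavelength (nm) defining the aperture cutoff; emission by
#'   default.
#' @param edge_smooth logical, anti-alias the aperture rim.
#' @return object of class `pupil_function`.
#' @export
build_pupil <- function(config, aberration = zernike_vector(),
                        n_pix = config$pupil_grid_size,
                        lambda = config$lambda_em, edge_smooth = FALSE) {
  stopifnot(inherits(config, "optical_config"))
  dx_um <- config$voxel_xy / 1000
  dk <- 1 / (n_pix * dx_um)              # um^-1 per frequency sample
  f_na <- config$na / (lambda / 1000)    # coherent aperture radius, um^-1
  if (f_na > (n_pix / 2 - 1) * dk) {
    stop(sprintf(
      "pupil support (%.2f um^-1) exceeds the grid Nyquist (%.2f um^-1); increase n_pix or reduce voxel_xy",
      f_na, (n_pix / 2 - 1) * dk), call. = FALSE)
  }
  k <- fft_freq(n_pix, dx_um)
  kx <- matrix(k, n_pix, n_pix)
  ky <- matrix(k, n_pix, n_pix, byrow = TRUE)
  kr <- sqrt(kx^2 + ky^2)
  rho <- kr / f_na
  theta <- atan2(ky, kx)
  if (edge_smooth) {
    drho <- dk / f_na
    amp <- pmin(1, pmax(0, (1 - rho) / drho + 0.5))
  } else {
    amp <- (rho <= 1) * 1
  }
  mask <- amp > 0
  phase <- matrix(0, n_pix, n_pix)
  for (j in zv_modes(aberration)) {
    a <- zv_amplitude(aberration, j)
    if (a != 0) {
      phase[mask] <- phase[mask] +
        a * zernike_eval(j, rho[mask], theta[mask], outside = "zero")
    }
  }
  structure(list(amplitude = amp, phase = phase, mask = mask,
                 rho = rho, theta = theta, n_pix = n_pix, dk = dk,
                 f_na = f_na, lambda = lambda, config = config,
                 aberration = aberration),
            class = "pupil_function")
}

#' Pupil-weighted RMS of the pupil phase
#' @param pupil a `pupil_function`.
#' @return RMS phase over the aperture, radians (amplitude^2-weighted).
#' @export
pupil_phase_rms <- function(pupil) {
  w <- pupil$amplitude^2
  mu <- sum(w * pupil$phase) / sum(w)
  sqrt(sum(w * (pupil$phase - mu)^2) / sum(w))
}

# Axial propagation frequency nu_z(rho) in cycles/nm for a focal shift z (nm).
# Exact high-NA form by default; parabolic low-NA approximation optional.
axial_frequency <- function(pupil, low_na = FALSE) {
  cfg <- pupil$config
  n <- cfg$n_immersion
  s <- cfg$na * pmin(pupil$rho, 1) / n
  if (low_na) {
    (n / pupil$lambda) * (1 - s^2 / 2)
  } else {
    (n / pupil$lambda) * sqrt(pmax(0, 1 - s^2))
  }
}

#' Compute a 3D intensity PSF from a pupil function
#'
#' Scalar diffraction: each axial plane applies the high-NA defocus phase
#' `2 pi (n / lambda) z sqrt(1 - (NA rho / n)^2)` to the pupil and takes the
#' squared modulus of its 2D Fourier transform. The volume is centred (the
#' origin sits at the middle voxel) and sum-normalised by default.
#'
#' @param pupil a `pupil_function` from [build_pupil()].
#' @param z_planes axial offsets, nm (typically symmetric about 0).
#' @param out_size lateral size of the returned volume (cropped about the
#'   centre); defaults to the full FFT grid.
#' @param normalization `"sum"` (volume sums to 1) or `"peak"` (max 1).
#' @param low_na_defocus use the parabolic defocus approximation.
#' @return object of class `psf_volume` with fields `intensity`
#'   (`out_size x out_size x length(z_planes)`), `z_planes`, `voxel_xy`,
#'   `voxel_z`, `center`, `normalization`.
#' @export
pupil_to_psf <- function(pupil, z_planes = 0, out_size = pupil$n_pix,
                         normalization = c("sum", "peak"),
                         low_na_defocus = FALSE) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(pupil, "pupil_function"))
  n_pix <- pupil$n_pix
  if (out_size > n_pix) stop("out_size exceeds the FFT grid", call. = FALSE)
  nu_z <- axial_frequency(pupil, low_na = low_na_defocus)
  p0 <- pupil$amplitude * exp(1i * pupil$phase)
  vol <- array(0, c(out_size, out_size, length(z_planes)))
  ctr <- n_pix %/% 2 + 1L
  half <- out_size %/% 2
  rows <- (ctr - half):(ctr - half + out_size - 1L)
  for (iz in seq_along(z_planes)) {
    pz <- p0 * exp(2i * pi * nu_z * z_planes[iz])
    field <- stats::fft(pz)
    plane <- fft_shift(Mod(field)^2)
    vol[, , iz] <- plane[rows, rows]
  }
  tot <- sum(vol)
  vol <- if (normalization == "sum") vol / tot else vol / max(vol)
  dz <- if (length(z_planes) > 1) diff(z_planes)[1] else pupil$config$voxel_z
  structure(list(intensity = vol, z_planes = z_planes,
                 voxel_xy = pupil$config$voxel_xy, voxel_z = dz,
                 center = c(half + 1L, half + 1L, which.min(abs(z_planes))),
                 normalization = normalization,
                 total_energy = tot, config = pupil$config),
            class = "psf_volume")
}

#' Fourier transform of a PSF volume
#'
#' 3D DFT of the intensity PSF. The returned complex array has DC at the
#' centre index (`dim %/% 2 + 1`) of every axis; frequency steps are
#' `1 / (n * voxel)` per axis in inverse micrometres.
#'
#' @param psf a `psf_volume` (or a bare 3D array plus voxel sizes).
#' @param voxel_xy,voxel_z voxel sizes in nm when `psf` is a bare array.
#' @return object of class `otf_volume` with fields `values` (complex,
#'   DC-centred), `freq_step` (per-axis, um^-1).
#' @export
psf_to_otf <- function(psf, voxel_xy = NULL, voxel_z = NULL) {
  if (inherits(psf, "psf_volume")) {
    arr <- psf$intensity
    voxel_xy <- psf$voxel_xy
    voxel_z <- psf$voxel_z
  } else {
    arr <- psf
    if (is.null(voxel_xy) || is.null(voxel_z)) {
      stop("voxel sizes required for a bare array", call. = FALSE)
    }
  }
  if (any(!is.finite(arr))) stop("PSF must be finite", call. = FALSE)
  d <- dim(arr)
  # undo the spatial centring so the DFT phase is referred to the volume centre
  otf <- fft_shift(stats::fft(fft_shift(arr, inverse = TRUE)))
  structure(list(values = otf,
                 freq_step = c(1 / (d[1] * voxel_xy / 1000),
                               1 / (d[2] * voxel_xy / 1000),
                               1 / (d[3] * voxel_z / 1000)),
                 dim = d),
            class = "otf_volume")
}

#' Strehl ratio of an aberrated PSF
#'
#' Peak intensity of the aberrated PSF relative to the diffraction-limited
#' one, both brought to equal total energy first. 1 means aberration-free;
#' the Marechal approximation predicts `exp(-sigma^2)` for small RMS phase
#' `sigma`.
#'
#' @param psf,psf_ideal `psf_volume` objects on identical grids.
#' @return scalar in `[0, 1]` up to numerical error.
#' @export
strehl <- function(psf, psf_ideal) {
  stopifnot(inherits(psf, "psf_volume"), inherits(psf_ideal, "psf_volume"))
  if (!identical(dim(psf$intensity), dim(psf_ideal$intensity))) {
    stop("PSF grids differ", call. = FALSE)
  }
  a <- psf$intensity / sum(psf$intensity)
  b <- psf_ideal$intensity / sum(psf_ideal$intensity)
  max(a) / max(b)
}

#' Direct-quadrature (Debye-type) PSF reference
#'
#' Computes the same scalar-diffraction PSF as [pupil_to_psf()] but by direct
#' numerical evaluation of the diffraction integral on a Gauss-Legendre (rho)
#' x uniform (theta) quadrature of the pupil, with a hard aperture edge and
#' no FFT. It is orders of magnitude slower and exists as an independent
#' numerical cross-check of the FFT pipeline.
#'
#' @param config an [optical_config()].
#' @param aberration a [zernike_vector()].
#' @param n_pix lateral output size (pixels, `voxel_xy` sampling).
#' @param z_planes axial offsets, nm.
#' @param n_rho,n_theta quadrature orders.
#' @param lambda wavelength, nm (emission by default).
#' @return a `psf_volume` (sum-normalised).
#' @export
debye_psf <- function(config, aberration = zernike_vector(),
                      n_pix = 64, z_planes = 0,
                      n_rho = 36, n_theta = 72,
                      lambda = config$lambda_em) {
  stopifnot(inherits(config, "optical_config"))
  gl <- pracma::gaussLegendre(n_rho, 0, 1)
  th <- (seq_len(n_theta) - 1) * 2 * pi / n_theta
  rho <- rep(gl$x, times = n_theta)
  theta <- rep(th, each = n_rho)
  w <- rep(gl$w, times = n_theta) * rho * (2 * pi / n_theta)
  phase <- numeric(length(rho))
  for (j in zv_modes(aberration)) {
    a <- zv_amplitude(aberration, j)
    if (a != 0) phase <- phase + a * zernike_eval(j, rho, theta)
  }
  f_na <- config$na / (lambda / 1000)           # um^-1
  n_imm <- config$n_immersion
  nu_z <- (n_imm / lambda) * sqrt(pmax(0, 1 - (config$na * rho / n_imm)^2))
  dx <- config$voxel_xy / 1000                  # um
  xs <- (seq_len(n_pix) - (n_pix %/% 2 + 1)) * dx
  pts_x <- rep(xs, times = n_pix)
  pts_y <- rep(xs, each = n_pix)
  # phase matrix: (pixels) x (quadrature nodes); built once, reused per plane
  M <- exp(2i * pi * f_na * (outer(pts_x, rho * cos(theta)) +
                             outer(pts_y, rho * sin(theta))))
  base <- w * exp(1i * phase)
  vol <- array(0, c(n_pix, n_pix, length(z_planes)))
  for (iz in seq_along(z_planes)) {
    v <- base * exp(2i * pi * nu_z * z_planes[iz])
    field <- M %*% v
    vol[, , iz] <- matrix(Mod(field)^2, n_pix, n_pix)
  }
  vol <- vol / sum(vol)
  dz <- if (length(z_planes) > 1) diff(z_planes)[1] else config$voxel_z
  structure(list(intensity = vol, z_planes = z_planes,
                 voxel_xy = config$voxel_xy, voxel_z = dz,
                 center = c(n_pix %/% 2 + 1L, n_pix %/% 2 + 1L,
                            which.min(abs(z_planes))),
                 normalization = "sum", total_energy = sum(vol),
                 config = config),
            class = "psf_volume")
}
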