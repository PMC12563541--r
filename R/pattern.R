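# Structured-illumination patterns: three-beam (0 and +/-1 order)
# interference at the sample plane, parameterised the way the acquisition
# uses them (3 orientation angles x 5 phase steps of 2*pi/5).

#' Structured-illumination pattern specification
#'
#' Describes one SI pattern of the standard 3D-SIM complement. The lateral
#' pattern frequency `freq_frac` is stated as a fraction of the emission
#' incoherent cutoff `2 NA / lambda_em` and refers to the finest lateral
#' harmonic of the pattern (the +/-1-order interference term); the
#' zero-order/first-order term sits at half that frequency and carries the
#' axial modulation of 3D SI. The five phase offsets are uniform steps of
#' `2*pi/5`, so the pattern averaged over the five phases is exactly
#' uniform.
#'
#' @param angle_index orientation index 0..2 (azimuths 0, 60, 120 degrees).
#' @param phase_index phase index 0..4 (offsets `phase_index * 2*pi/5`).
#' @param freq_frac lateral pattern frequency as a fraction of the emission
#'   incoherent cutoff.
#' @param axial_modulation logical; `TRUE` gives three-beam 3D SI with an
#'   axially modulated first harmonic, `FALSE` a two-beam (2D-SIM) pattern.
#' @param modulation_depth m in `[0, 1]`: depth of the first harmonic
#'   (three-beam) or of the single harmonic (two-beam).
#' @return object of class `sim_pattern`.
#' @export
sim_pattern <- function(angle_index = 0, phase_index = 0, freq_frac = 0.8,
                        axial_modulation = TRUE, modulation_depth = 1) {
  stopifnot(angle_index %in% 0:2, phase_index %in% 0:4,
            freq_frac > 0, modulation_depth >= 0, modulation_depth <= 1)
  structure(list(angle_index = as.integer(angle_index),
                 azimuth = angle_index * pi / 3,
                 phase_index = as.integer(phase_index),
                 phase_offset = phase_index * 2 * pi / 5,
                 freq_frac = freq_frac,
                 axial_modulation = axial_modulation,
                 modulation_depth = modulation_depth),
            class = "sim_pattern")
}

# Beam amplitude ratio beta = a1/a0 of the three-beam geometry giving a
# first-harmonic modulation depth m = 4*beta/(1 + 2*beta^2).
beam_ratio_for_depth <- function(m) {
  if (m == 0) return(0)
  (2 - sqrt(4 - 2 * m^2)) / (2 * m)
}

#' Evaluate a SIM illumination pattern on a voxel grid
#'
#' Three-beam interference intensity of the 0 and +/-1 diffraction orders:
#' an axially modulated lateral sinusoid at half the pattern frequency plus
#' an unmodulated lateral second harmonic at the full pattern frequency,
#' normalised to unit mean. The axial origin of the modulation is
#' `z_origin_nm`, which tracks the focal plane during synchronised axial
#' scanning.
#'
#' @param pattern a [sim_pattern()].
#' @param config an [optical_config()].
#' @param dim integer `c(nx, ny, nz)` voxel grid.
#' @param voxel_xy,voxel_z grid sampling, nm (defaults from `config`).
#' @param z_origin_nm axial position (nm) of maximum axial modulation.
#' @return 3D array of illumination intensity, mean 1.
#' @export
sim_pattern_field <- function(pattern, config, dim,
                              voxel_xy = config$voxel_xy,
                              voxel_z = config$voxel_z, z_origin_nm = 0) {
  stopifnot(inherits(pattern, "sim_pattern"), inherits(config, "optical_config"))
  cutoff_em <- 2 * config$na / config$lambda_em        # cycles/nm
  f2 <- pattern$freq_frac * cutoff_em                  # finest harmonic
  f1 <- f2 / 2                                         # beam-offset frequency
  f_ex_coherent <- config$na / config$lambda_ex
  if (f1 > f_ex_coherent + 1e-12) {
    stop(sprintf(
      "pattern beam frequency %.3g/um exceeds the excitation coherent cutoff %.3g/um",
      f1 * 1000, f_ex_coherent * 1000), call. = FALSE)
  }
  m <- pattern$modulation_depth
  nx <- dim[1]; ny <- dim[2]; nz <- dim[3]
  x <- (seq_len(nx) - 0.5) * voxel_xy
  y <- (seq_len(ny) - 0.5) * voxel_xy
  z <- ((seq_len(nz) - (nz %/% 2 + 1)) * voxel_z) - z_origin_nm
  u <- outer(x * cos(pattern$azimuth), y * sin(pattern$azimuth), "+")
  if (!pattern$axial_modulation) {
    lateral <- 1 + m * cos(2 * pi * f2 * u + 2 * pattern$phase_offset)
    return(array(rep(lateral, nz), c(nx, ny, nz)))
  }
  beta <- beam_ratio_for_depth(m)
  norm <- 1 + 2 * beta^2
  # axial frequency of the 0 <-> +/-1 interference term
  sin_a <- f1 * config$lambda_ex / config$n_immersion
  nu_z <- (config$n_immersion / config$lambda_ex) * (1 - sqrt(1 - sin_a^2))
  th1 <- 2 * pi * f1 * u + pattern$phase_offset
  c1 <- (4 * beta / norm) * cos(th1)
  c2 <- (2 * beta^2 / norm) * cos(2 * th1)
  out <- array(0, c(nx, ny, nz))
  for (iz in seq_len(nz)) {
    out[, , iz] <- 1 + c1 * cos(2 * pi * nu_z * z[iz]) + c2
  }
  out
}

#' The full 15-pattern SIM complement
#'
#' @param freq_frac,axial_modulation,modulation_depth as in [sim_pattern()].
#' @return list of 15 [sim_pattern()]s, phase index fastest, then angle.
#' @export
sim_pattern_set <- function(freq_frac = 0.8, axial_modulation = TRUE,
                            modulation_depth = 1) {
  out <- list()
  for (a in 0:2) for (p in 0:4) {
    out[[length(out) + 1L]] <- sim_pattern(a, p, freq_frac,
                                           axial_modulation, modulation_depth)
  }
  out
}
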