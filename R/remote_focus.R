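# Deformable-mirror remote focusing: compute the pupil phase that moves the
# focal plane axially, express it on the DM's low-order spherical modes,
# calibrate commanded-vs-achieved shift against the virtual microscope, and
# drive synchronised z-stacks without any mechanical motion.

#' Zernike decomposition of the remote-focusing pupil phase
#'
#' The exact high-NA phase for an axial focal shift `z` is
#' `2 pi (n / lambda) z sqrt(1 - (NA rho / n)^2)`; projected (piston
#' removed) onto the rotationally symmetric Zernike modes — defocus (#4),
#' primary (#11) and secondary (#22) spherical by default, the dominant
#' terms of its expansion. Convention: a positive shift focuses deeper into
#' the sample, so the point response referenced to the nominal detection
#' plane peaks at `-shift`.
#'
#' @param shift_um focal shift, um; `|shift|` must not exceed `max_shift_um`.
#' @param config an [optical_config()].
#' @param modes radially symmetric Noll modes of the decomposition.
#' @param max_shift_um reliability limit of the mirror.
#' @param lambda wavelength (nm) referencing the phase radians.
#' @return a [zernike_vector()] with attributes `residual_rms` (rad, the
#'   part of the exact phase the mode set cannot express — reported, never
#'   silently dropped) and `piston` (rad, removed).
#' @export
refocus_phase <- function(shift_um, config = optical_config(),
                          modes = c(4, 11, 22), max_shift_um = 10,
                          lambda = config$lambda_em) {
  stopifnot(inherits(config, "optical_config"))
  if (abs(shift_um) > max_shift_um) {
    stop(sprintf("shift %g um beyond the declared +/-%g um range",
                 shift_um, max_shift_um), call. = FALSE)
  }
  nm <- noll_to_nm(modes)
  if (any(nm$m != 0)) stop("refocus modes must be radially symmetric", call. = FALSE)
  gl <- pracma::gaussLegendre(256, 0, 1)
  rho <- gl$x
  w <- gl$w * 2 * rho                      # disk measure, unit total mass
  n_imm <- config$n_immersion
  phi <- 2 * pi * (n_imm / lambda) * (shift_um * 1000) *
    sqrt(pmax(0, 1 - (config$na * rho / n_imm)^2))
  piston <- sum(w * phi)
  coefs <- vapply(modes, function(j) {
    sum(w * phi * zernike_eval(j, rho, 0))
  }, numeric(1))
  recon <- piston
  for (i in seq_along(modes)) {
    recon <- recon + coefs[i] * zernike_eval(modes[i], rho, 0)
  }
  residual_rms <- sqrt(sum(w * (phi - recon)^2))
  out <- zernike_vector(modes, coefs, reference_wavelength = lambda)
  attr(out, "residual_rms") <- residual_rms
  attr(out, "piston") <- piston
  attr(out, "shift_um") <- shift_um
  out
}

# Sub-voxel axial peak: centre of mass within +/-3 samples of the maximum,
# then a parabola through the 3 samples nearest the CoM. Ties break toward
# smaller z (which.max returns the first maximum on an ascending grid).
locate_axial_peak <- function(profile, z_positions) {
  i0 <- which.max(profile)
  win <- max(1, i0 - 3):min(length(profile), i0 + 3)
  wts <- profile[win] - min(profile[win])
  ic <- if (sum(wts) > 0) sum(win * wts) / sum(wts) else i0
  ic <- max(2, min(length(profile) - 1, round(ic)))
  y <- profile[(ic - 1):(ic + 1)]
  denom <- y[1] - 2 * y[2] + y[3]
  delta <- if (abs(denom) > 0) 0.5 * (y[1] - y[3]) / denom else 0
  delta <- max(-0.5, min(0.5, delta))
  stats::approx(seq_along(z_positions), z_positions, xout = ic + delta,
                rule = 2)$y
}

#' Calibrate remote focusing against the virtual microscope
#'
#' Two-step calibration. Step one (precision): for each commanded shift,
#' apply the refocusing pattern through the DM, acquire a through-focus
#' bead volume, locate the axial image peak with sub-voxel precision, and
#' regress achieved shift on command — the response must be linear with
#' R-squared >= `min_r_squared` over the requested range. Step two
#' (accuracy): a monotone cubic interpolant of the measured
#' command-to-shift map absorbs any smooth systematic deviation (e.g. a DM
#' that only reaches a fraction of the requested stroke), so commands
#' looked up through the calibration hit their target even when the raw
#' response is scaled or gently distorted.
#'
#' @param scope a [virtual_scope()] viewing a bead phantom.
#' @param commands_um commanded shifts spanning the target range, um.
#' @param z_search_um half-width of the mechanical search scan, um.
#' @param z_step_nm search-scan step, nm.
#' @param refocus_modes mode set of [refocus_phase()].
#' @param min_r_squared linearity requirement of step one.
#' @param tolerance_nm residual tolerance defining the validated range.
#' @return object of class `remote_focus_calib`: `slope`, `intercept`,
#'   `r_squared`, `commands_um`, `achieved_um`, `validated_range_um`, and
#'   the secondary inverse map.
#' @export
calibrate_remote_focus <- function(scope, commands_um = seq(-5, 5, by = 1),
                                   z_search_um = 1.5 * max(abs(commands_um)),
                                   z_step_nm = scope$config$voxel_z,
                                   refocus_modes = c(4, 11, 22),
                                   min_r_squared = 0.99,
                                   tolerance_nm = 100) {
  stopifnot(inherits(scope, "virtual_scope"))
  max_cmd <- max(abs(commands_um))
  z_planes <- seq(-z_search_um * 1000, z_search_um * 1000, by = z_step_nm)
  achieved <- vapply(commands_um, function(u) {
    pat <- refocus_phase(u, scope$config, modes = refocus_modes,
                         max_shift_um = max(10, 2 * max_cmd))
    vol <- scope_render_volume(scope, pat, z_planes)
    profile <- apply(vol, 3, max)
    # the bead layer appears at -peak when the focus moved +u into the sample
    -locate_axial_peak(profile, z_planes) / 1000
  }, numeric(1))
  fit <- stats::lm(achieved ~ commands_um)
  r2 <- summary(fit)$r.squared
  resid_nm <- 1000 * abs(stats::resid(fit))
  if (r2 < min_r_squared) {
    ok <- resid_nm <= tolerance_nm
    usable <- if (any(ok)) range(commands_um[ok]) else c(NA, NA)
    stop(sprintf(
      "remote-focus calibration failed: R^2 = %.4f < %.2f; usable sub-range approximately %g..%g um",
      r2, min_r_squared, usable[1], usable[2]), call. = FALSE)
  }
  ord <- order(achieved)
  inverse <- stats::splinefun(achieved[ord], commands_um[ord],
                              method = "hyman")
  # pad the usable range by the peak-localisation grid step, so targets at
  # the nominal end of the scan remain addressable
  pad <- z_step_nm / 1000
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 commands_um = commands_um, achieved_um = achieved,
                 residual_nm = 1000 * stats::resid(fit),
                 validated_range_um = range(achieved) + c(-pad, pad),
                 tolerance_nm = tolerance_nm,
                 refocus_modes = refocus_modes,
                 inverse = inverse),
            class = "remote_focus_calib")
}

#' @export
print.remote_focus_calib <- function(x, ...) {
  cat(sprintf(
    "<remote_focus_calib> slope %.4f, R2 %.5f, validated %g..%g um\n",
    x$slope, x$r_squared, x$validated_range_um[1], x$validated_range_um[2]))
  invisible(x)
}

#' Command achieving a target focal shift
#'
#' Looks the target up through the secondary (accuracy) calibration map;
#' enforces the validated range.
#'
#' @param calib a [calibrate_remote_focus()] result.
#' @param z_um target shift(s), um.
#' @return commanded shift(s), um.
#' @export
calib_command_for <- function(calib, z_um) {
  stopifnot(inherits(calib, "remote_focus_calib"))
  bad <- z_um < calib$validated_range_um[1] - 1e-9 |
    z_um > calib$validated_range_um[2] + 1e-9
  if (any(bad)) {
    stop(sprintf("target(s) outside the validated range: %s um",
                 paste(signif(z_um[bad], 4), collapse = ", ")), call. = FALSE)
  }
  calib$inverse(z_um)
}

#' Combine an aberration correction with a refocusing pattern
#'
#' Correction and remote focusing are controlled independently, each with
#' its own Zernike set; when used simultaneously their DM patterns are
#' summed index-wise. Provenance of both addends is kept in attributes.
#'
#' @param correction,refocus [zernike_vector()]s.
#' @return their index-wise sum, with `correction` and `refocus` attributes.
#' @export
combine_patterns <- function(correction, refocus) {
  out <- correction + refocus
  attr(out, "correction") <- correction
  attr(out, "refocus") <- refocus
  out
}

#' Acquire a z-stack by remote focusing
#'
#' For every target plane: look up the refocusing command through the
#' calibration, optionally add the MPAC-predicted correction for that
#' depth, apply the summed pattern to the DM and acquire — the detection
#' plane never moves. The output layout is identical to a mechanical
#' z-stack of the same targets.
#'
#' @param scope a [virtual_scope()].
#' @param z_targets_um target planes, um.
#' @param calib a [calibrate_remote_focus()] result.
#' @param mpac_table optional [mpac_fit()] table of per-depth corrections.
#' @return array `[n, n, length(z_targets_um)]`.
#' @export
remote_z_stack <- function(scope, z_targets_um, calib, mpac_table = NULL) {
  stopifnot(inherits(scope, "virtual_scope"))
  out <- array(0, c(scope$n, scope$n, length(z_targets_um)))
  for (i in seq_along(z_targets_um)) {
    cmd <- calib_command_for(calib, z_targets_um[i])
    pat <- refocus_phase(cmd, scope$config, modes = calib$refocus_modes,
                         max_shift_um = max(10, 2 * abs(cmd) + 1))
    applied <- if (!is.null(mpac_table)) {
      combine_patterns(suppressWarnings(mpac_predict(mpac_table,
                                                     z_targets_um[i])), pat)
    } else pat
    out[, , i] <- scope_render(scope, applied, z_nm = 0)
  }
  out
}

#' Acquire a mechanical z-stack (reference for stage equivalence)
#'
#' Moves the detection plane mechanically; the DM holds only the optional
#' per-depth MPAC correction.
#'
#' @inheritParams remote_z_stack
#' @return array `[n, n, length(z_targets_um)]`.
#' @export
mechanical_z_stack <- function(scope, z_targets_um, mpac_table = NULL) {
  stopifnot(inherits(scope, "virtual_scope"))
  out <- array(0, c(scope$n, scope$n, length(z_targets_um)))
  for (i in seq_along(z_targets_um)) {
    applied <- if (!is.null(mpac_table)) {
      suppressWarnings(mpac_predict(mpac_table, z_targets_um[i]))
    } else zernike_vector()
    out[, , i] <- scope_render(scope, applied, z_nm = z_targets_um[i] * 1000)
  }
  out
}
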