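# Quantitative image analysis: pseudo-widefield projection of raw SI data,
# bead detection, Gaussian FWHM estimation, spectral (OTF-support)
# resolution with the 1% normalised-log-power threshold, and SI
# modulation-contrast QC.

#' Pseudo-widefield volume from a raw SIM stack
#'
#' Averages the raw SI frames over the 5 phases and 3 angles per (z,
#' channel). Because the five phase offsets are uniform steps of 2*pi/5,
#' the pattern averages to uniform illumination exactly, so the PWF of a
#' noiseless stack equals the widefield render of the same scene.
#'
#' @param stack a [raw_sim_stack()].
#' @return array `[x, y, z, channel]`.
#' @export
pseudo_widefield <- function(stack) {
  stopifnot(inherits(stack, "raw_sim_stack"))
  d <- dim(stack$frames)
  if (any(!is.finite(stack$frames))) {
    bad <- which(!is.finite(stack$frames), arr.ind = TRUE)
    stop(sprintf("non-finite frame at (phase %d, angle %d, z %d, channel %d)",
                 bad[1, 3], bad[1, 4], bad[1, 5], bad[1, 6]), call. = FALSE)
  }
  out <- array(0, c(d[1], d[2], d[5], d[6]))
  for (ch in seq_len(d[6])) {
    for (zi in seq_len(d[5])) {
      out[, , zi, ch] <- apply(stack$frames[, , , , zi, ch, drop = FALSE],
                               c(1, 2), mean)
    }
  }
  out
}

#' Detect beads in an image volume
#'
#' Local maxima above an intensity floor, with non-maximum suppression at
#' the stated minimum separation and a centre-of-mass sub-voxel refinement.
#'
#' @param volume 3D numeric array.
#' @param voxel_xy,voxel_z voxel sizes, nm.
#' @param min_separation suppression radius, nm.
#' @param intensity_floor absolute threshold; peaks below it are ignored.
#'   Default: 20% of the volume maximum.
#' @return matrix with columns `x`, `y`, `z` (voxel coordinates, possibly
#'   fractional) and `intensity`; zero rows if nothing is found.
#' @export
detect_beads <- function(volume, voxel_xy, voxel_z,
                         min_separation = 1000,
                         intensity_floor = 0.2 * max(volume)) {
  d <- dim(volume)
  cand <- which(volume >= intensity_floor)
  if (length(cand) == 0) {
    return(matrix(numeric(0), 0, 4,
                  dimnames = list(NULL, c("x", "y", "z", "intensity"))))
  }
  idx <- arrayInd(cand, d)
  vals <- volume[cand]
  ord <- order(vals, decreasing = TRUE)
  idx <- idx[ord, , drop = FALSE]
  vals <- vals[ord]
  # local-maximum check over the 3x3x(3) neighbourhood
  is_max <- vapply(seq_len(nrow(idx)), function(i) {
    p <- idx[i, ]
    xr <- max(1, p[1] - 1):min(d[1], p[1] + 1)
    yr <- max(1, p[2] - 1):min(d[2], p[2] + 1)
    zr <- max(1, p[3] - 1):min(d[3], p[3] + 1)
    vals[i] >= max(volume[xr, yr, zr])
  }, logical(1))
  idx <- idx[is_max, , drop = FALSE]
  vals <- vals[is_max]
  # non-maximum suppression, strongest first
  keep <- logical(nrow(idx))
  pos_nm <- cbind(idx[, 1] * voxel_xy, idx[, 2] * voxel_xy,
                  idx[, 3] * voxel_z)
  for (i in seq_len(nrow(idx))) {
    if (i == 1 || all(sqrt(rowSums(
      sweep(pos_nm[keep, , drop = FALSE], 2, pos_nm[i, ])^2)) >=
      min_separation)) {
      keep[i] <- TRUE
    }
  }
  idx <- idx[keep, , drop = FALSE]
  vals <- vals[keep]
  # sub-voxel centre of mass over the neighbourhood
  ref <- t(vapply(seq_len(nrow(idx)), function(i) {
    p <- idx[i, ]
    xr <- max(1, p[1] - 1):min(d[1], p[1] + 1)
    yr <- max(1, p[2] - 1):min(d[2], p[2] + 1)
    zr <- max(1, p[3] - 1):min(d[3], p[3] + 1)
    w <- volume[xr, yr, zr, drop = FALSE]
    sw <- sum(w)
    c(sum(slice.index(w, 1) * w) / sw + xr[1] - 1,
      sum(slice.index(w, 2) * w) / sw + yr[1] - 1,
      sum(slice.index(w, 3) * w) / sw + zr[1] - 1)
  }, numeric(3)))
  cbind(x = ref[, 1], y = ref[, 2], z = ref[, 3], intensity = vals)
}

# 1D Gaussian + offset fit; returns FWHM in physical units or NULL.
fit_profile_fwhm <- function(values, step_nm) {
  n <- length(values)
  x <- (seq_len(n) - (n + 1) / 2) * step_nm
  fit <- gaussian_offset_fit(
    x, values,
    start = c(c0 = min(values), A = max(values) - min(values),
              mu = x[which.max(values)], s = n * step_nm / 6),
    lower = c(-Inf, 0, min(x), step_nm / 10),
    upper = c(Inf, Inf, max(x), n * step_nm))
  if (is.null(fit)) return(NULL)
  list(fwhm = 2 * sqrt(2 * log(2)) * fit$par[["s"]],
       r_squared = fit$r_squared,
       center = fit$par[["mu"]])
}

#' Bead FWHM report
#'
#' Fits 1D Gaussian-plus-offset curves along x, y (averaged to one lateral
#' number, assuming isotropy) and z through each bead centre and reports
#' `FWHM = 2 sqrt(2 ln 2) sigma`. Beads are rejected — with a reason — when
#' a fit fails or has R-squared < 0.95, when the FWHM exceeds 3x the
#' stated diffraction estimate, or when a neighbour sits within the
#' exclusion radius.
#'
#' @param volume 3D numeric array.
#' @param locations matrix from [detect_beads()] (columns x, y, z in voxel
#'   units).
#' @param voxel_xy,voxel_z voxel sizes, nm.
#' @param window_xy,window_z profile half-widths, voxels.
#' @param diffraction_fwhm_nm lateral diffraction estimate used by the 3x
#'   rejection rule (`Inf` disables it).
#' @param neighbor_exclusion_nm reject beads with a neighbour closer than
#'   this (`NULL` disables).
#' @param min_r_squared fit-quality floor.
#' @return object of class `fwhm_report`: per-bead table, lateral/axial
#'   means and SDs, rejected list with reasons.
#' @export
bead_fwhm <- function(volume, locations, voxel_xy, voxel_z,
                      window_xy = 8, window_z = 8,
                      diffraction_fwhm_nm = Inf,
                      neighbor_exclusion_nm = NULL,
                      min_r_squared = 0.95) {
  d <- dim(volume)
  if (nrow(locations) == 0) stop("no bead locations supplied", call. = FALSE)
  rows <- list()
  rejected <- list()
  for (i in seq_len(nrow(locations))) {
    p <- round(locations[i, 1:3])
    reason <- NULL
    if (!is.null(neighbor_exclusion_nm) && nrow(locations) > 1) {
      others <- locations[-i, , drop = FALSE]
      dist <- sqrt(((others[, 1] - locations[i, 1]) * voxel_xy)^2 +
                   ((others[, 2] - locations[i, 2]) * voxel_xy)^2 +
                   ((others[, 3] - locations[i, 3]) * voxel_z)^2)
      if (min(dist) < neighbor_exclusion_nm) reason <- "neighbor too close"
    }
    if (is.null(reason)) {
      xr <- max(1, p[1] - window_xy):min(d[1], p[1] + window_xy)
      yr <- max(1, p[2] - window_xy):min(d[2], p[2] + window_xy)
      zr <- max(1, p[3] - window_z):min(d[3], p[3] + window_z)
      fx <- fit_profile_fwhm(volume[xr, p[2], p[3]], voxel_xy)
      fy <- fit_profile_fwhm(volume[p[1], yr, p[3]], voxel_xy)
      fz <- if (d[3] >= 5) fit_profile_fwhm(volume[p[1], p[2], zr], voxel_z)
      if (is.null(fx) || is.null(fy)) {
        reason <- "lateral fit failed"
      } else if (min(fx$r_squared, fy$r_squared) < min_r_squared) {
        reason <- "lateral fit R2 below threshold"
      } else if (max(fx$fwhm, fy$fwhm) > 3 * diffraction_fwhm_nm) {
        reason <- "FWHM exceeds 3x diffraction estimate"
      }
    }
    if (!is.null(reason)) {
      rejected[[length(rejected) + 1L]] <- data.frame(bead = i,
                                                      reason = reason)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      bead = i,
      fwhm_lateral_nm = (fx$fwhm + fy$fwhm) / 2,
      fwhm_axial_nm = if (!is.null(fz)) fz$fwhm else NA_real_,
      r_squared = min(fx$r_squared, fy$r_squared))
  }
  if (length(rows) == 0) stop("all beads rejected", call. = FALSE)
  tab <- do.call(rbind, rows)
  structure(list(
    beads = tab,
    lateral_mean_nm = mean(tab$fwhm_lateral_nm),
    lateral_sd_nm = stats::sd(tab$fwhm_lateral_nm),
    axial_mean_nm = mean(tab$fwhm_axial_nm),
    axial_sd_nm = stats::sd(tab$fwhm_axial_nm),
    rejected = if (length(rejected)) do.call(rbind, rejected) else
      data.frame(bead = integer(0), reason = character(0))),
    class = "fwhm_report")
}

#' @export
print.fwhm_report <- function(x, ...) {
  cat(sprintf(
    "<fwhm_report> %d bead(s): lateral %.1f +/- %.1f nm, axial %.1f +/- %.1f nm (%d rejected)\n",
    nrow(x$beads), x$lateral_mean_nm, x$lateral_sd_nm,
    x$axial_mean_nm, x$axial_sd_nm, nrow(x$rejected)))
  invisible(x)
}

# normalised log-power profile -> first crossing below `threshold`,
# linearly interpolated between bins. Returns frequency (um^-1) or NA.
threshold_crossing <- function(freq, profile, threshold) {
  below <- which(profile < threshold)
  below <- below[below > 1]
  if (length(below) == 0) return(NA_real_)
  i <- below[1]
  f0 <- freq[i - 1]; f1 <- freq[i]
  p0 <- profile[i - 1]; p1 <- profile[i]
  if (p0 == p1) return(f1)
  f0 + (p0 - threshold) / (p0 - p1) * (f1 - f0)
}

#' Spectral (OTF-support) resolution estimate
#'
#' 3D DFT of the volume; the lateral profile is the radial average of
#' log-power in the central kxy plane, the axial profile averages the two
#' kz directions of the central kxz plane and then averages along kx. Each
#' profile's log-power is normalised to `[0, 1]` between its noise floor
#' (median log-power of the top 10% frequency band) and its maximum; the
#' first crossing below `threshold` defines the cutoff frequency, and the
#' reported resolution is exactly its inverse.
#'
#' @param volume 3D numeric array (>= 32 voxels per lateral axis).
#' @param voxel_xy,voxel_z voxel sizes, nm.
#' @param threshold normalised log-power threshold (default 0.01, i.e. 1%).
#' @param window apply a Hann window before the DFT.
#' @param floor_db dynamic-range cap of the normalisation: the floor is
#'   never taken more than this far below the profile maximum, so noiseless
#'   simulated volumes (whose numerical floor is FFT leakage many decades
#'   down) are normalised over a physically meaningful range. Real noisy
#'   data have their noise floor well inside the cap, which is then
#'   inactive.
#' @return object of class `spectral_report`: lateral/axial profiles,
#'   cutoffs (um^-1), resolutions (nm), and `grid_limited` flags set when a
#'   profile never crosses the threshold.
#' @export
spectral_resolution <- function(volume, voxel_xy, voxel_z, threshold = 0.01,
                                window = TRUE, floor_db = 60) {
  d <- dim(volume)
  if (d[1] < 32 || d[2] < 32) stop("need >= 32 voxels per lateral axis", call. = FALSE)
  v <- volume - min(volume)
  if (window) {
    wz <- if (d[3] > 1) 0.5 - 0.5 * cos(2 * pi * (seq_len(d[3]) - 1) / (d[3] - 1)) else 1
    w <- outer(outer(0.5 - 0.5 * cos(2 * pi * (seq_len(d[1]) - 1) / (d[1] - 1)),
                     0.5 - 0.5 * cos(2 * pi * (seq_len(d[2]) - 1) / (d[2] - 1))), wz)
    v <- v * w
  }
  P <- fft_shift(Mod(stats::fft(v))^2)
  eps <- max(P) * 1e-15
  L <- log10(P + eps)
  cx <- d[1] %/% 2 + 1L; cy <- d[2] %/% 2 + 1L; cz <- d[3] %/% 2 + 1L
  kx <- fft_shift(fft_freq(d[1], voxel_xy / 1000))
  kz <- if (d[3] > 1) fft_shift(fft_freq(d[3], voxel_z / 1000)) else 0
  ## lateral: radial average of the central kxy plane
  kxy <- sqrt(outer(kx^2, fft_shift(fft_freq(d[2], voxel_xy / 1000))^2, "+"))
  plane <- L[, , cz]
  dk <- 1 / (d[1] * voxel_xy / 1000)
  nb <- floor(max(kxy) / dk)
  bins <- findInterval(kxy, (seq_len(nb) - 0.5) * dk) + 1L
  lat_prof <- vapply(seq_len(nb), function(b) {
    mean(plane[bins == b])
  }, numeric(1))
  lat_freq <- (seq_len(nb) - 1L) * dk
  ## axial: central kxz plane, fold +/- kz, then average along kx
  ax_n <- d[3] - cz + 1L
  ax_prof <- rep(NA_real_, ax_n)
  if (d[3] >= 8) {
    plane_xz <- L[, cy, ]                        # [kx, kz]
    ax_prof <- vapply(seq_len(ax_n), function(i) {
      up <- cz + i - 1L
      dn <- cz - i + 1L
      mean((plane_xz[, up] + plane_xz[, dn]) / 2)
    }, numeric(1))
  }
  ax_freq <- (seq_len(ax_n) - 1L) * (if (d[3] > 1) 1 / (d[3] * voxel_z / 1000) else 0)
  norm01 <- function(prof) {
    hi <- max(prof)
    ntail <- max(2L, ceiling(length(prof) * 0.1))
    floor_est <- max(stats::median(utils::tail(prof, ntail)),
                     hi - floor_db / 10)
    pmax(0, (prof - floor_est) / (hi - floor_est))
  }
  lat01 <- norm01(lat_prof)
  lat_cut <- threshold_crossing(lat_freq, lat01, threshold)
  lat_limited <- is.na(lat_cut)
  if (lat_limited) lat_cut <- max(lat_freq)
  ax01 <- if (d[3] >= 8) norm01(ax_prof) else ax_prof
  ax_cut <- if (d[3] >= 8) threshold_crossing(ax_freq, ax01, threshold) else NA_real_
  ax_limited <- d[3] >= 8 && is.na(ax_cut)
  if (ax_limited) ax_cut <- max(ax_freq)
  structure(list(
    lateral_profile = data.frame(freq_um = lat_freq, log_power = lat_prof,
                                 normalized = lat01),
    axial_profile = data.frame(freq_um = ax_freq, log_power = ax_prof,
                               normalized = ax01),
    threshold = threshold,
    lateral_cutoff_um = lat_cut,
    axial_cutoff_um = ax_cut,
    lateral_resolution_nm = 1000 / lat_cut,
    axial_resolution_nm = if (is.na(ax_cut) || ax_cut == 0) NA_real_ else 1000 / ax_cut,
    grid_limited = c(lateral = lat_limited, axial = ax_limited)),
    class = "spectral_report")
}

#' @export
print.spectral_report <- function(x, ...) {
  cat(sprintf(
    "<spectral_report> lateral %.2f um^-1 (%.0f nm), axial %s (threshold %g)\n",
    x$lateral_cutoff_um, x$lateral_resolution_nm,
    if (is.na(x$axial_cutoff_um)) "n/a" else
      sprintf("%.2f um^-1 (%.0f nm)", x$axial_cutoff_um,
              x$axial_resolution_nm),
    x$threshold))
  invisible(x)
}

#' SI modulation contrast of a raw SIM stack
#'
#' For every (angle, z, channel): per-pixel 5-point DFT over the phase
#' sequence; the contrast is the mean single-cycle amplitude
#' (`2/5 |sum_p I_p e^{-2 pi i p / 5}|`) divided by the mean DC amplitude.
#' On a noiseless uniform scene this equals the pattern's first-harmonic
#' modulation depth at the focal plane. Low values predict reconstruction
#' artefacts.
#'
#' @param stack a [raw_sim_stack()].
#' @return data.frame with columns `angle`, `z_index`, `channel`,
#'   `contrast`.
#' @export
modulation_contrast <- function(stack) {
  stopifnot(inherits(stack, "raw_sim_stack"))
  d <- dim(stack$frames)
  om <- exp(-2i * pi * (0:4) / 5)
  out <- expand.grid(angle = 1:3, z_index = seq_len(d[5]),
                     channel = seq_len(d[6]))
  out$contrast <- NA_real_
  for (r in seq_len(nrow(out))) {
    fr <- stack$frames[, , , out$angle[r], out$z_index[r], out$channel[r]]
    dim(fr) <- c(d[1] * d[2], 5)
    a1 <- (2 / 5) * Mod(fr %*% om)
    dc <- rowMeans(fr)
    out$contrast[r] <- mean(a1) / mean(dc)
  }
  out
}
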