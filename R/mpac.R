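# Multi-position aberration correction (MPAC): run the sensorless routine
# at a few anchor depths and interpolate the per-mode corrections linearly
# in z for every other section of the volume. Works because the dominant
# depth-induced aberrations (spherical above all) grow in proportion to
# imaging depth.

#' Fit an MPAC correction table from anchor corrections
#'
#' Independent least-squares line per Zernike mode over the union of modes
#' present at the anchors (a mode missing from an anchor counts as 0
#' there). Two anchors are interpolated exactly.
#'
#' @param anchors list of anchors, each `list(z = <um>, correction =
#'   <zernike_vector>)`; at least 2 with distinct z.
#' @return object of class `mpac_table`: per-mode `slope` (rad/um),
#'   `intercept` (rad), `residual_rms`, and the anchor span.
#' @examples
#' tab <- mpac_fit(list(
#'   list(z = 0,  correction = zernike_vector(11, 0)),
#'   list(z = 10, correction = zernike_vector(11, 1))))
#' zv_amplitude(mpac_predict(tab, 5), 11)   # 0.5
#' @export
mpac_fit <- function(anchors) {
  if (length(anchors) < 2) stop("need >= 2 anchors", call. = FALSE)
  z <- vapply(anchors, `[[`, numeric(1), "z")
  if (anyDuplicated(z)) stop("anchor z positions must be distinct", call. = FALSE)
  modes <- sort(unique(unlist(lapply(anchors, function(a) {
    zv_modes(a$correction)
  }))))
  fit <- lapply(modes, function(j) {
    a <- vapply(anchors, function(an) zv_amplitude(an$correction, j),
                numeric(1))
    co <- stats::coef(stats::lm(a ~ z))
    res <- a - (co[1] + co[2] * z)
    list(intercept = unname(co[1]), slope = unname(co[2]),
         residual_rms = sqrt(mean(res^2)))
  })
  names(fit) <- as.character(modes)
  structure(list(modes = modes, fit = fit, z_range = range(z),
                 anchors = anchors),
            class = "mpac_table")
}

#' @export
print.mpac_table <- function(x, ...) {
  cat(sprintf("<mpac_table> %d mode(s), anchors spanning %g..%g um\n",
              length(x$modes), x$z_range[1], x$z_range[2]))
  for (j in x$modes) {
    f <- x$fit[[as.character(j)]]
    cat(sprintf("  #%-3d slope %+.4f rad/um, intercept %+.4f rad (res RMS %.2g)\n",
                j, f$slope, f$intercept, f$residual_rms))
  }
  invisible(x)
}

#' Predict the correction at a depth from an MPAC table
#'
#' Affine per-mode evaluation. Depths beyond the anchor span are allowed
#' (the two-anchor workflow routinely brackets, not covers, the volume) but
#' flagged with a warning.
#'
#' @param table an [mpac_fit()] table.
#' @param z depth, um.
#' @return a [zernike_vector()] correction for that plane.
#' @export
mpac_predict <- function(table, z) {
  stopifnot(inherits(table, "mpac_table"))
  if (z < table$z_range[1] || z > table$z_range[2]) {
    warning(sprintf("z = %g um extrapolates beyond the anchor span [%g, %g]",
                    z, table$z_range[1], table$z_range[2]), call. = FALSE)
  }
  amps <- vapply(table$modes, function(j) {
    f <- table$fit[[as.character(j)]]
    f$intercept + f$slope * z
  }, numeric(1))
  zernike_vector(table$modes, amps)
}

#' Per-plane DM command table for an acquisition volume
#'
#' Precomputes `mpac_predict` at every section, the way per-plane
#' corrections are stored in a DM driver ahead of a triggered acquisition.
#'
#' @param table an `mpac_table`.
#' @param z_um vector of section depths, um.
#' @return data.frame in long format: `z_um`, `mode`, `amplitude_rad`.
#' @export
mpac_command_table <- function(table, z_um) {
  do.call(rbind, lapply(z_um, function(z) {
    zv <- suppressWarnings(mpac_predict(table, z))
    data.frame(z_um = z, mode = zv_modes(zv),
               amplitude_rad = zv_amplitude(zv, zv_modes(zv)))
  }))
}
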