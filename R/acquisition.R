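# Acquisition planning and bookkeeping: frame counts, z ranges, frame
# ordering, and the per-frame device-state (trigger) tables that a
# real-time controller would iterate during an acquisition.

#' Plan an acquisition
#'
#' A SIM acquisition always carries the full 5-phase x 3-angle complement
#' per section and channel; widefield needs one frame per section and
#' channel. The frame descriptor list records the ordering permutation
#' (default: phase fastest, then angle, then z, then channel).
#'
#' @param n_channels,n_z positive integers.
#' @param z_step_nm axial step, nm.
#' @param mode `"sim"` or `"widefield"`.
#' @param focus `"mechanical"` or `"remote"`.
#' @param ordering permutation of `c("phase", "angle", "z", "channel")`,
#'   fastest-varying first.
#' @param n_phases,n_angles the SIM complement (fixed at 5 x 3 by the
#'   acquisition standard; changeable only for non-standard experiments).
#' @return object of class `acquisition_plan` with `n_frames` and a frame
#'   descriptor data.frame in acquisition order.
#' @examples
#' plan_acquisition(n_channels = 2, n_z = 7)$n_frames       # 210
#' plan_acquisition(n_channels = 1, n_z = 80)$n_frames      # 1200
#' @export
plan_acquisition <- function(n_channels = 1, n_z = 1, z_step_nm = 125,
                             mode = c("sim", "widefield"),
                             focus = c("mechanical", "remote"),
                             ordering = c("phase", "angle", "z", "channel"),
                             n_phases = 5, n_angles = 3) {
  mode <- match.arg(mode)
  focus <- match.arg(focus)
  if (n_channels < 1 || n_z < 1 || z_step_nm <= 0 ||
      n_channels != round(n_channels) || n_z != round(n_z)) {
    stop("channel/z counts must be positive integers, z step > 0", call. = FALSE)
  }
  if (!setequal(ordering, c("phase", "angle", "z", "channel"))) {
    stop("ordering must permute phase, angle, z, channel", call. = FALSE)
  }
  if (mode == "widefield") {
    n_phases <- 1
    n_angles <- 1
  }
  z_nm <- (seq_len(n_z) - 1) * z_step_nm
  grid_vars <- list(phase = seq_len(n_phases), angle = seq_len(n_angles),
                    z = seq_len(n_z), channel = seq_len(n_channels))
  frames <- do.call(expand.grid, grid_vars[ordering])
  frames <- frames[, c("phase", "angle", "z", "channel")]
  frames$z_nm <- z_nm[frames$z]
  frames$frame <- seq_len(nrow(frames))
  structure(list(n_phases = n_phases, n_angles = n_angles,
                 n_channels = n_channels, n_z = n_z, z_step_nm = z_step_nm,
                 mode = mode, focus = focus, ordering = ordering,
                 z_nm = z_nm,
                 n_frames = nrow(frames),
                 frames = frames[, c("frame", "phase", "angle", "z",
                                     "z_nm", "channel")]),
            class = "acquisition_plan")
}

#' @export
print.acquisition_plan <- function(x, ...) {
  cat(sprintf(
    "<acquisition_plan> %s/%s: %d phase x %d angle x %d z (step %g nm) x %d channel = %d frames\n",
    x$mode, x$focus, x$n_phases, x$n_angles, x$n_z, x$z_step_nm,
    x$n_channels, x$n_frames))
  invisible(x)
}

#' Axial span of a section series
#'
#' `(n_sections - 1) * step`: 129 sections 125 nm apart span 16 um.
#'
#' @param n_sections number of sections (>= 1).
#' @param step_nm section spacing, nm.
#' @return span in um.
#' @examples
#' z_span(129, 125)   # 16
#' @export
z_span <- function(n_sections, step_nm) {
  if (n_sections < 1 || step_nm <= 0) {
    stop("need n_sections >= 1 and step > 0", call. = FALSE)
  }
  (n_sections - 1) * step_nm / 1000
}

#' Per-frame device-state (trigger) table
#'
#' One row per frame of the plan: SLM pattern id (phase/angle combination),
#' polarisation state id (per angle), laser channel, camera id, DM pattern
#' id and z target. DM patterns are precomputed per z section — the
#' combination of the MPAC-predicted correction and the remote-focusing
#' pattern — and deduplicated, mirroring a driver that stores a finite
#' pattern set and iterates it by hardware triggers.
#'
#' @param plan an [acquisition_plan()].
#' @param mpac_table optional [mpac_fit()] table (depths in um).
#' @param calib a [calibrate_remote_focus()] result; required when the
#'   plan uses remote focus.
#' @return object of class `trigger_table`: data.frame `rows` plus the
#'   `dm_patterns` list the ids reference.
#' @export
build_trigger_table <- function(plan, mpac_table = NULL, calib = NULL) {
  stopifnot(inherits(plan, "acquisition_plan"))
  if (plan$focus == "remote" && is.null(calib)) {
    stop("remote focus requires a remote_focus_calib", call. = FALSE)
  }
  z_um <- plan$z_nm / 1000
  if (plan$focus == "remote") {
    bad <- z_um < calib$validated_range_um[1] | z_um > calib$validated_range_um[2]
    if (any(bad)) {
      stop(sprintf("z target(s) outside calibrated range: %s um",
                   paste(signif(z_um[bad], 4), collapse = ", ")),
           call. = FALSE)
    }
  }
  dm_patterns <- lapply(seq_along(z_um), function(i) {
    corr <- if (!is.null(mpac_table)) {
      suppressWarnings(mpac_predict(mpac_table, z_um[i]))
    } else zernike_vector()
    refoc <- if (plan$focus == "remote") {
      refocus_phase(calib_command_for(calib, z_um[i]),
                    modes = calib$refocus_modes)
    } else zernike_vector()
    combine_patterns(corr, refoc)
  })
  key <- vapply(dm_patterns, function(p) {
    paste(zv_modes(p), signif(zv_amplitude(p, zv_modes(p)), 12),
          collapse = ";")
  }, character(1))
  uniq <- !duplicated(key)
  dm_id_of_z <- match(key, key[uniq])
  rows <- plan$frames
  rows$slm_pattern_id <- if (plan$mode == "sim") {
    (rows$angle - 1L) * plan$n_phases + rows$phase
  } else 0L
  rows$polarization_id <- if (plan$mode == "sim") rows$angle else 0L
  rows$laser_channel <- rows$channel
  rows$camera_id <- rows$channel
  rows$dm_pattern_id <- dm_id_of_z[rows$z]
  rows$z_target_nm <- rows$z_nm
  structure(list(rows = rows, dm_patterns = dm_patterns[uniq],
                 n_dm_patterns = sum(uniq)),
            class = "trigger_table")
}

#' @export
print.trigger_table <- function(x, ...) {
  cat(sprintf("<trigger_table> %d row(s), %d distinct DM pattern(s)\n",
              nrow(x$rows), x$n_dm_patterns))
  invisible(x)
}

#' Duration of one acquisition volume at a fixed frame rate
#'
#' @param plan an [acquisition_plan()].
#' @param frame_rate_fps frames per second (> 0).
#' @return seconds.
#' @examples
#' volume_duration(plan_acquisition(2, 7), 20)   # 10.5 s
#' @export
volume_duration <- function(plan, frame_rate_fps) {
  stopifnot(inherits(plan, "acquisition_plan"))
  if (frame_rate_fps <= 0) stop("frame rate must be > 0", call. = FALSE)
  plan$n_frames / frame_rate_fps
}
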