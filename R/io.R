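# File I/O: multi-page 32-bit float TIFF for stacks and volumes with a YAML
# sidecar carrying dimensions, ordering and voxel sizes; YAML for
# configuration objects; the seeded fixture generator; and the end-to-end
# pipeline runner.

sidecar_path <- function(path) paste0(path, ".yaml")

# TIFF pages store values in [0, 1]; data are divided by a power-of-two
# scale (recorded in the sidecar) so the scaling itself is exact in binary
# floating point.
tiff_scale <- function(x) {
  mx <- max(x, 0)
  if (mx <= 1) 1 else 2^ceiling(log2(mx))
}

#' Write a raw SIM stack as multi-page TIFF + sidecar
#'
#' Pages are written in the declared dimension order (default canonical:
#' phase fastest, then angle, z, channel); the sidecar records dimensions,
#' ordering, voxel sizes and metadata so the reader can restore canonical
#' order from any permutation.
#'
#' @param stack a [raw_sim_stack()].
#' @param path output TIFF path; the sidecar goes to `<path>.yaml`.
#' @param order page ordering, fastest-varying first.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path,
                        order = c("phase", "angle", "z", "channel")) {
  stopifnot(inherits(stack, "raw_sim_stack"))
  if (!setequal(order, c("phase", "angle", "z", "channel"))) {
    stop("order must permute phase, angle, z, channel", call. = FALSE)
  }
  d <- dim(stack$frames)
  names(d) <- c("x", "y", "phase", "angle", "z", "channel")
  perm <- c(1L, 2L, match(order, c("phase", "angle", "z", "channel")) + 2L)
  arr <- aperm(stack$frames, perm)
  scale <- tiff_scale(arr)
  npage <- prod(d[3:6])
  pages <- lapply(seq_len(npage), function(i) {
    matrix(arr[(i - 1) * d[1] * d[2] + seq_len(d[1] * d[2])],
           d[1], d[2]) / scale
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32, compression = "none")
  yaml::write_yaml(list(
    type = "raw_sim_stack",
    dims = as.list(d[3:6]),
    n_pixels = unname(d[1:2]),
    page_order = order,
    data_scale = scale,
    voxel_xy_nm = stack$voxel_xy, voxel_z_nm = stack$voxel_z,
    z_positions_nm = stack$z_positions,
    metadata = stack$metadata[setdiff(names(stack$metadata), "noise")]),
    sidecar_path(path))
  invisible(path)
}

#' Read a raw SIM stack (or plain volume) from TIFF
#'
#' Restores canonical (phase, angle, z, channel) ordering using the sidecar
#' or a declared page order. A dimension mismatch between file and
#' declaration is an error stating both shapes; a plain (sidecar-less)
#' multi-page TIFF is returned as an `[x, y, z]` volume.
#'
#' @param path TIFF path.
#' @param declared_order page ordering to assume when it differs from the
#'   sidecar (or when no sidecar exists).
#' @return a [raw_sim_stack()], or a 3D array for a plain volume.
#' @export
read_stack <- function(path, declared_order = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  sc <- sidecar_path(path)
  if (!file.exists(sc)) {
    vol <- array(unlist(pages), c(dim(pages[[1]]), length(pages)))
    return(vol)
  }
  meta <- yaml::read_yaml(sc)
  if (identical(meta$type, "volume")) {
    vol <- array(unlist(pages), c(dim(pages[[1]]), length(pages))) *
      meta$data_scale
    attr(vol, "voxel_xy_nm") <- meta$voxel_xy_nm
    attr(vol, "voxel_z_nm") <- meta$voxel_z_nm
    return(vol)
  }
  order <- if (!is.null(declared_order)) declared_order else
    unlist(meta$page_order)
  dims <- unlist(meta$dims)[c("phase", "angle", "z", "channel")]
  if (length(pages) != prod(dims)) {
    stop(sprintf("page count %d does not match declared dims [%s]",
                 length(pages), paste(dims, collapse = " x ")),
         call. = FALSE)
  }
  np <- dim(pages[[1]])
  arr <- array(unlist(pages), c(np, unname(dims[order])))
  # invert the write permutation back to canonical
  perm <- c(1L, 2L, match(order, c("phase", "angle", "z", "channel")) + 2L)
  frames <- aperm(arr, order(perm)) * meta$data_scale
  raw_sim_stack(frames, meta$voxel_xy_nm, meta$voxel_z_nm,
                unlist(meta$z_positions_nm), meta$metadata)
}

#' Write an image volume (e.g. a PSF) as float TIFF with voxel metadata
#'
#' @param volume 3D numeric array, or a `psf_volume`.
#' @param path output path.
#' @param voxel_xy,voxel_z voxel sizes (nm) for bare arrays.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, voxel_xy = NULL, voxel_z = NULL) {
  if (inherits(volume, "psf_volume")) {
    voxel_xy <- volume$voxel_xy
    voxel_z <- volume$voxel_z
    volume <- volume$intensity
  }
  scale <- tiff_scale(volume)
  pages <- lapply(seq_len(dim(volume)[3]), function(i) volume[, , i] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32, compression = "none")
  yaml::write_yaml(list(type = "volume", data_scale = scale,
                        voxel_xy_nm = voxel_xy, voxel_z_nm = voxel_z),
                   sidecar_path(path))
  invisible(path)
}

#' Serialise configuration objects to YAML
#'
#' Supports [optical_config()], [zernike_vector()] and [noise_model()];
#' all physical quantities carry explicit units in their key names.
#'
#' @param x the object.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_config_yaml <- function(x, path) {
  out <- if (inherits(x, "optical_config")) {
    list(type = "optical_config", na = x$na,
         lambda_ex_nm = x$lambda_ex, lambda_em_nm = x$lambda_em,
         n_immersion = x$n_immersion, n_sample = x$n_sample,
         voxel_xy_nm = x$voxel_xy, voxel_z_nm = x$voxel_z,
         pupil_grid_size = x$pupil_grid_size)
  } else if (inherits(x, "zernike_vector")) {
    list(type = "zernike_vector",
         reference_wavelength_nm = x$reference_wavelength,
         coefficients_rad = as.list(x$coefficients))
  } else if (inherits(x, "noise_model")) {
    list(type = "noise_model", photon_budget = x$photon_budget,
         read_noise_sd_e = x$read_noise_sd, background_photons = x$background,
         seed = x$seed)
  } else stop("unsupported object", call. = FALSE)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  switch(y$type,
    optical_config = optical_config(
      na = y$na, lambda_ex = y$lambda_ex_nm, lambda_em = y$lambda_em_nm,
      n_immersion = y$n_immersion, n_sample = y$n_sample,
      voxel_xy = y$voxel_xy_nm, voxel_z = y$voxel_z_nm,
      pupil_grid_size = y$pupil_grid_size),
    zernike_vector = zernike_vector(
      as.integer(names(y$coefficients_rad)),
      as.numeric(unlist(y$coefficients_rad)),
      reference_wavelength = y$reference_wavelength_nm),
    noise_model = noise_model(y$photon_budget, y$read_noise_sd_e,
                              y$background_photons, y$seed),
    stop("unknown config type: ", y$type, call. = FALSE))
}

#' Generate a canonical on-disk test scene
#'
#' Deterministic scene bundles standing in for the laboratory specimens the
#' methods are developed on: `bead_slide` (sparse 100 nm beads on glass),
#' `deep_bead_slide` (a bead layer under 130 um of aberrating tissue,
#' described by a depth model with a spherical slope), `filament_cell`
#' (sub-diffraction tubules) and `mosaic_brain` (an epithelial mosaic of
#' cell outlines). Each bundle holds the phantom volume (TIFF), the optical
#' configuration (YAML) and a manifest with the generator parameters.
#'
#' @param name one of `"bead_slide"`, `"deep_bead_slide"`,
#'   `"filament_cell"`, `"mosaic_brain"`.
#' @param seed generator seed.
#' @param dir output directory (created if needed).
#' @return list of written paths plus the in-memory `phantom` and scene
#'   parameters.
#' @export
make_fixture <- function(name, seed = 1, dir = tempfile("fixture_")) {
  choices <- c("bead_slide", "deep_bead_slide", "filament_cell",
               "mosaic_brain")
  if (!name %in% choices) {
    stop("unknown fixture '", name, "'; choices: ",
         paste(choices, collapse = ", "), call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  config <- optical_config()
  depth_um <- 0
  depth_model <- NULL
  phantom <- switch(name,
    bead_slide = make_bead_phantom(15, fov = c(128, 128, 1),
                                   min_separation = 1500, seed = seed),
    deep_bead_slide = {
      depth_um <- 130
      depth_model <- list(slope_mode = 11, slope_rad_per_um = 0.02,
                          offset_modes = c(6, 11), offset_rad = c(0.2, 0.4))
      make_bead_phantom(15, fov = c(128, 128, 1), min_separation = 1500,
                        seed = seed)
    },
    filament_cell = make_filament_phantom(6, width_nm = 100,
                                          curvature_scale = 0.08,
                                          fov = c(128, 128, 1), seed = seed),
    mosaic_brain = make_mosaic_phantom(30, fov = c(128, 128, 1),
                                       seed = seed))
  paths <- list(
    phantom_path = file.path(dir, "phantom.tif"),
    config_path = file.path(dir, "optical_config.yaml"),
    manifest_path = file.path(dir, "manifest.yaml"))
  write_volume(phantom$intensity, paths$phantom_path,
               voxel_xy = phantom$voxel_xy, voxel_z = phantom$voxel_z)
  write_config_yaml(config, paths$config_path)
  yaml::write_yaml(list(
    name = name, seed = seed, kind = phantom$kind,
    params = phantom$params, depth_um = depth_um,
    depth_model = depth_model,
    n_primitives = if (!is.null(phantom$primitives$centers)) {
      nrow(phantom$primitives$centers)
    } else length(phantom$primitives$paths)),
    paths$manifest_path)
  c(paths, list(phantom = phantom, config = config, depth_um = depth_um,
                depth_model = depth_model, dir = dir))
}

fixture_depth_model <- function(fx) {
  dm <- fx$depth_model
  if (is.null(dm)) return(NULL)
  depth_aberration_model(
    slopes = zernike_vector(dm$slope_mode, dm$slope_rad_per_um),
    offsets = zernike_vector(dm$offset_modes, dm$offset_rad))
}

#' Run the simulate - correct - acquire - analyze pipeline
#'
#' Executes the declared chain against a fixture scene, persisting every
#' intermediate (corrections as YAML, scan table as CSV, raw stack as
#' TIFF, analysis reports as CSV) plus a structured log with seeds. A run
#' is reproducible from its configuration alone.
#'
#' @param config list with elements `scene` (fixture name), `seed`,
#'   `out_dir`, and optional `correct` (logical, default TRUE), `noise`
#'   (a [noise_model()] or NULL), `n_z`, `z_step_nm`, `modes`, `biases`,
#'   `passes`. May also be a path to a YAML file holding these fields.
#' @return list with `correction`, `stack_path`, `contrast`, `log_path`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(!is.null(config$scene), !is.null(config$out_dir))
  seed <- config$seed %||% 1
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  log <- list(r_version = R.version.string,
              package_version = as.character(utils::packageVersion("aosim")),
              seed = seed, started = format(Sys.time()))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      log$failed_stage <- name
      yaml::write_yaml(log, file.path(out_dir, "run_log.yaml"))
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  ## simulate
  sim <- stage("simulate", {
    fx <- make_fixture(config$scene, seed = seed,
                       dir = file.path(out_dir, "scene"))
    noise <- config$noise %||% noise_model(seed = seed)
    sample_ab <- fixture_depth_model(fx) %||% zernike_vector()
    scope <- virtual_scope(fx$phantom, fx$config,
                           sample_aberration = sample_ab,
                           depth_um = fx$depth_um, noise = noise)
    list(fx = fx, scope = scope, noise = noise)
  })
  ## correct
  correction <- stage("correct", {
    if (isFALSE(config$correct)) {
      zernike_vector()
    } else {
      plan <- plan_bias_scan(config$modes %||% base_correction_modes(),
                             config$biases %||% c(-1, -0.5, 0, 0.5, 1))
      res <- correct_plane(sim$scope, plan,
                           passes = config$passes %||% 1)
      write_config_yaml(res$combined, file.path(out_dir, "correction.yaml"))
      utils::write.csv(scan_table(res),
                       file.path(out_dir, "bias_scans.csv"),
                       row.names = FALSE)
      log$n_correction_images <- res$n_images
      res$combined
    }
  })
  ## acquire
  stack_path <- stage("acquire", {
    n_z <- config$n_z %||% 1
    z_step <- config$z_step_nm %||% sim$fx$phantom$voxel_z
    nz_ph <- dim(sim$fx$phantom$intensity)[3]
    z_pos <- if (n_z == 1) 0 else
      (seq_len(n_z) - (n_z + 1) / 2) * z_step
    residual <- (fixture_depth_model(sim$fx) %||% zernike_vector())
    eff <- if (inherits(residual, "zernike_vector")) residual else
      aberration_at_depth(residual, sim$fx$depth_um)
    stack <- render_sim_stack(sim$fx$phantom,
                              aberration = eff + correction,
                              config = sim$fx$config,
                              z_positions = if (nz_ph == 1) 0 else z_pos,
                              noise = sim$noise)
    p <- file.path(out_dir, "raw_stack.tif")
    write_stack(stack, p)
    p
  })
  ## analyze
  contrast <- stage("analyze", {
    stk <- read_stack(stack_path)
    ct <- modulation_contrast(stk)
    utils::write.csv(ct, file.path(out_dir, "modulation_contrast.csv"),
                     row.names = FALSE)
    ct
  })
  log$finished <- format(Sys.time())
  log_path <- file.path(out_dir, "run_log.yaml")
  yaml::write_yaml(log, log_path)
  list(correction = correction, stack_path = stack_path,
       contrast = contrast, log_path = log_path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
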