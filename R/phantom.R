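# Seeded synthetic specimens. All phantoms are deterministic functions of
# (kind, parameters, seed): the generator saves and restores the caller's RNG
# state, so regeneration is bit-identical and never perturbs user code.

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state, so
#' seeded generators never perturb user code.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

new_phantom <- function(kind, intensity, voxel_xy, voxel_z, params, seed,
                        primitives = NULL) {
  stopifnot(all(intensity >= 0))
  structure(list(kind = kind, intensity = intensity,
                 voxel_xy = voxel_xy, voxel_z = voxel_z,
                 params = params, seed = seed, primitives = primitives),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("<phantom> kind '%s', %d x %d x %d voxels (%g x %g nm), seed %s\n",
              x$kind, d[1], d[2], d[3], x$voxel_xy, x$voxel_z,
              format(x$seed)))
  invisible(x)
}

# Deposit a soft (one-voxel anti-aliased) sphere of radius r_nm at a
# continuous position (nm); per-primitive mass is normalised to `mass`.
deposit_sphere <- function(vol, pos_nm, r_nm, voxel_xy, voxel_z, mass = 1) {
  d <- dim(vol)
  rx <- ceiling((r_nm + voxel_xy) / voxel_xy)
  rz <- ceiling((r_nm + voxel_z) / voxel_z)
  ix <- max(1, floor(pos_nm[1] / voxel_xy) + 1 - rx):min(d[1], floor(pos_nm[1] / voxel_xy) + 1 + rx)
  iy <- max(1, floor(pos_nm[2] / voxel_xy) + 1 - rx):min(d[2], floor(pos_nm[2] / voxel_xy) + 1 + rx)
  iz <- max(1, floor(pos_nm[3] / voxel_z) + 1 - rz):min(d[3], floor(pos_nm[3] / voxel_z) + 1 + rz)
  gx <- (ix - 0.5) * voxel_xy - pos_nm[1]
  gy <- (iy - 0.5) * voxel_xy - pos_nm[2]
  gz <- (iz - 0.5) * voxel_z - pos_nm[3]
  dist <- sqrt(outer(outer(gx^2, gy^2, "+"), gz^2, "+"))
  blob <- pmin(1, pmax(0, (r_nm - dist) / voxel_xy + 0.5))
  s <- sum(blob)
  if (s > 0) vol[ix, iy, iz] <- vol[ix, iy, iz] + blob * (mass / s)
  vol
}

#' Seeded sub-resolution bead-field phantom
#'
#' Places `n_beads` spheres (default diameter 100 nm, emulating standard
#' green fluorescent calibration beads on a cover slip) at uniformly random
#' positions with a minimum pairwise separation, then renders them as
#' anti-aliased diameter-matched spheres on the voxel grid. With
#' `layer = "plane"` (default) all beads sit on the central z plane, like
#' beads deposited on glass.
#'
#' @param n_beads number of beads.
#' @param diameter_nm bead diameter (nm).
#' @param fov integer vector `c(nx, ny, nz)` of the volume in voxels.
#' @param min_separation minimum centre-to-centre distance, nm.
#' @param seed RNG seed; identical seeds give bit-identical phantoms.
#' @param voxel_xy,voxel_z voxel sizes, nm.
#' @param layer `"plane"` (all beads on the central plane) or `"volume"`.
#' @param margin_nm keep-out border from the lateral FOV edges.
#' @return a `phantom`; bead centres (nm) are kept in `$primitives$centers`.
#' @export
make_bead_phantom <- function(n_beads, diameter_nm = 100,
                              fov = c(128, 128, 1), min_separation = 1000,
                              seed = 1, voxel_xy = 80, voxel_z = 125,
                              layer = c("plane", "volume"),
                              margin_nm = 4 * diameter_nm) {
  layer <- match.arg(layer)
  fov <- as.integer(fov)
  ext <- c(fov[1] * voxel_xy, fov[2] * voxel_xy, fov[3] * voxel_z)
  if (2 * margin_nm >= ext[1] || 2 * margin_nm >= ext[2]) {
    stop("margin leaves no room in the FOV", call. = FALSE)
  }
  centers <- with_seed(seed, {
    pts <- matrix(NA_real_, 0, 3)
    tries <- 0L
    while (nrow(pts) < n_beads) {
      if (tries > 200L * n_beads) {
        stop("could not place beads at the requested separation", call. = FALSE)
      }
      tries <- tries + 1L
      cand <- c(stats::runif(1, margin_nm, ext[1] - margin_nm),
                stats::runif(1, margin_nm, ext[2] - margin_nm),
                if (layer == "plane") ext[3] / 2 else stats::runif(1, 0, ext[3]))
      if (nrow(pts) == 0 ||
          min(sqrt(rowSums(sweep(pts, 2, cand)^2))) >= min_separation) {
        pts <- rbind(pts, cand)
      }
    }
    pts
  })
  if (n_beads == 1) {
    centers[1, 1:2] <- ext[1:2] / 2   # single bead: centred, a point-source test
  }
  vol <- array(0, fov)
  for (i in seq_len(nrow(centers))) {
    vol <- deposit_sphere(vol, centers[i, ], diameter_nm / 2,
                          voxel_xy, voxel_z)
  }
  new_phantom("bead_field", vol, voxel_xy, voxel_z,
              params = list(n_beads = n_beads, diameter_nm = diameter_nm,
                            min_separation = min_separation, layer = layer),
              seed = seed, primitives = list(centers = centers))
}

#' Seeded curvilinear filament phantom
#'
#' Smooth random-walk tubes of sub-diffraction width, emulating microtubule
#' or ER tubule preparations used as resolution test structures.
#'
#' @param n_filaments number of filaments.
#' @param width_nm tube diameter (should be below the lateral diffraction
#'   limit for a meaningful resolution test).
#' @param curvature_scale SD (radians) of the per-step random change of
#'   direction; 0 gives straight filaments.
#' @param fov,voxel_xy,voxel_z,seed as in [make_bead_phantom()].
#' @return a `phantom` with control points in `$primitives$paths`.
#' @export
make_filament_phantom <- function(n_filaments = 5, width_nm = 100,
                                  curvature_scale = 0.1,
                                  fov = c(128, 128, 1), seed = 1,
                                  voxel_xy = 80, voxel_z = 125) {
  fov <- as.integer(fov)
  ext <- c(fov[1] * voxel_xy, fov[2] * voxel_xy, fov[3] * voxel_z)
  step <- voxel_xy / 2
  paths <- with_seed(seed, {
    lapply(seq_len(n_filaments), function(i) {
      pos <- c(stats::runif(1, 0.1, 0.9) * ext[1],
               stats::runif(1, 0.1, 0.9) * ext[2])
      ang <- stats::runif(1, 0, 2 * pi)
      pts <- matrix(NA_real_, 0, 2)
      for (s in seq_len(ceiling(1.5 * max(ext[1:2]) / step))) {
        pts <- rbind(pts, pos)
        ang <- ang + stats::rnorm(1, 0, curvature_scale)
        pos <- pos + step * c(cos(ang), sin(ang))
        if (any(pos < 0) || pos[1] > ext[1] || pos[2] > ext[2]) break
      }
      pts
    })
  })
  vol <- array(0, fov)
  zc <- ext[3] / 2
  for (p in paths) {
    for (i in seq_len(nrow(p))) {
      vol <- deposit_sphere(vol, c(p[i, ], zc), width_nm / 2,
                            voxel_xy, voxel_z, mass = step / voxel_xy)
    }
  }
  new_phantom("filaments", vol, voxel_xy, voxel_z,
              params = list(n_filaments = n_filaments, width_nm = width_nm,
                            curvature_scale = curvature_scale),
              seed = seed, primitives = list(paths = paths))
}

#' Seeded epithelial-mosaic phantom
#'
#' Labelled cell outlines of a packed epithelial monolayer (a Voronoi mosaic
#' of random cell centres), emulating junction-marker expression in
#' neuroepithelial sheets.
#'
#' @param n_cells number of cells in the FOV.
#' @param outline_width_nm width of the outline signal.
#' @param fov,voxel_xy,voxel_z,seed as in [make_bead_phantom()].
#' @return a `phantom`.
#' @export
make_mosaic_phantom <- function(n_cells = 25, outline_width_nm = 150,
                                fov = c(128, 128, 1), seed = 1,
                                voxel_xy = 80, voxel_z = 125) {
  fov <- as.integer(fov)
  ext <- c(fov[1] * voxel_xy, fov[2] * voxel_xy)
  centers <- with_seed(seed, cbind(stats::runif(n_cells, 0, ext[1]),
                                   stats::runif(n_cells, 0, ext[2])))
  gx <- (seq_len(fov[1]) - 0.5) * voxel_xy
  gy <- (seq_len(fov[2]) - 0.5) * voxel_xy
  plane <- matrix(0, fov[1], fov[2])
  d2 <- array(Inf, c(fov[1], fov[2], 2))   # two smallest squared distances
  for (i in seq_len(n_cells)) {
    di <- outer(gx - centers[i, 1], rep(1, fov[2]))^2 +
      outer(rep(1, fov[1]), gy - centers[i, 2])^2
    better1 <- di < d2[, , 1]
    d2[, , 2][better1] <- d2[, , 1][better1]
    d2[, , 1][better1] <- di[better1]
    better2 <- !better1 & di < d2[, , 2]
    d2[, , 2][better2] <- di[better2]
  }
  gap <- sqrt(d2[, , 2]) - sqrt(d2[, , 1])   # ~0 on Voronoi boundaries
  plane <- pmin(1, pmax(0, (outline_width_nm - gap) / voxel_xy + 0.5))
  vol <- array(0, fov)
  vol[, , (fov[3] + 1L) %/% 2L] <- plane
  new_phantom("mosaic", vol, voxel_xy, voxel_z,
              params = list(n_cells = n_cells,
                            outline_width_nm = outline_width_nm),
              seed = seed, primitives = list(centers = centers))
}
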