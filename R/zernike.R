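#' Convert a Noll index to radial and azimuthal orders
#'
#' Zernike modes are indexed throughout the package by Noll's single index
#' scheme (j = 1 piston, 2/3 tip/tilt, 4 defocus, 5/6 primary astigmatism,
#' 11 primary spherical, 22 secondary spherical, ...). This returns the
#' radial order `n` and the signed azimuthal order `m` of each mode; negative
#' `m` denotes the sine (odd) harmonic, positive `m` the cosine (even) one.
#'
#' @param j integer vector of Noll indices (>= 1).
#' @return a data.frame with columns `j`, `n`, `m`.
#' @examples
#' noll_to_nm(c(4, 5, 11, 22))
#' @export
noll_to_nm <- function(j) {
  if (any(j < 1) || any(j != round(j)) || any(!is.finite(j))) {
    stop("Noll indices must be integers >= 1", call. = FALSE)
  }
  j <- as.integer(round(j))
  one <- function(jj) {
    n <- 0L
    j1 <- jj - 1L
    while (j1 > n) {
      n <- n + 1L
      j1 <- j1 - n
    }
    sgn <- if (jj %% 2L == 0L) 1L else -1L
    m <- sgn * ((n %% 2L) + 2L * ((j1 + ((n + 1L) %% 2L)) %/% 2L))
    c(n, m)
  }
  nm <- vapply(j, one, integer(2))
  data.frame(j = j, n = nm[1L, ], m = nm[2L, ])
}

#' Convert radial/azimuthal orders to the Noll index
#'
#' Inverse of [noll_to_nm()].
#'
#' @param n radial order (>= 0).
#' @param m signed azimuthal order, `abs(m) <= n`, `n - abs(m)` even.
#' @return integer vector of Noll indices.
#' @export
nm_to_noll <- function(n, m) {
  if (length(n) != length(m)) stop("n and m must have equal length", call. = FALSE)
  if (any(abs(m) > n) || any((n - abs(m)) %% 2 != 0)) {
    stop("require abs(m) <= n with n - abs(m) even", call. = FALSE)
  }
  vapply(seq_along(n), function(i) {
    base <- n[i] * (n[i] + 1L) / 2 + 1L
    cand <- seq.int(base, base + n[i])
    nm <- noll_to_nm(cand)
    cand[nm$n == n[i] & nm$m == m[i]]
  }, numeric(1))
}

# Common-name labels for the low-order modes used in modal AO.
.noll_labels <- c(
  `1` = "piston", `2` = "tip", `3` = "tilt", `4` = "defocus",
  `5` = "primary oblique astigmatism", `6` = "primary vertical astigmatism",
  `7` = "primary vertical coma", `8` = "primary horizontal coma",
  `9` = "oblique trefoil", `10` = "vertical trefoil",
  `11` = "primary spherical", `12` = "secondary vertical astigmatism",
  `13` = "secondary oblique astigmatism", `22` = "secondary spherical"
)

#' Human-readable name of a Noll mode
#' @param j Noll index vector.
#' @return character vector; `"Z<j> (n=.., m=..)"` for unnamed high orders.
#' @export
noll_label <- function(j) {
  nm <- noll_to_nm(j)
  out <- .noll_labels[as.character(j)]
  miss <- is.na(out)
  out[miss] <- sprintf("Z%d (n=%d, m=%d)", j[miss], nm$n[miss], nm$m[miss])
  unname(out)
}

# Zernike radial polynomial R_n^|m|(rho), standard finite sum.
zernike_radial <- function(n, m, rho) {
  m <- abs(m)
  val <- numeric(length(rho))
  for (s in 0:((n - m) / 2)) {
    val <- val + (-1)^s * factorial(n - s) /
      (factorial(s) * factorial((n + m) / 2 - s) * factorial((n - m) / 2 - s)) *
      rho^(n - 2 * s)
  }
  val
}

#' Evaluate an RMS-normalised Zernike polynomial
#'
#' Uses the Noll normalisation: every mode with j >= 2 has unit mean-square
#' value over the unit disk, so a coefficient of `a` radians contributes `a`
#' radians RMS of wavefront phase. Piston (j = 1) evaluates to 1.
#'
#' @param j single Noll index.
#' @param rho radial coordinate(s) in `[0, 1]`.
#' @param theta azimuth(s), radians. Recycled against `rho`.
#' @param outside behaviour for `rho > 1`: `"error"` or `"zero"` (mask).
#' @return numeric vector of polynomial values.
#' @examples
#' zernike_eval(4, 0, 0)   # -sqrt(3): defocus at pupil centre
#' @export
zernike_eval <- function(j, rho, theta = 0, outside = c("error", "zero")) {
  outside <- match.arg(outside)
  if (length(j) != 1L) stop("j must be a single index", call. = FALSE)
  bad <- rho > 1 + 1e-12
  if (any(bad & is.finite(rho))) {
    if (outside == "error") stop("rho must lie in [0, 1]", call. = FALSE)
  }
  nm <- noll_to_nm(j)
  n <- nm$n
  m <- nm$m
  rad <- zernike_radial(n, m, pmin(rho, 1))
  val <- if (m == 0) {
    sqrt(n + 1) * rad
  } else if (m > 0) {
    sqrt(2 * (n + 1)) * rad * cos(m * theta)
  } else {
    sqrt(2 * (n + 1)) * rad * sin(-m * theta)
  }
  if (outside == "zero") val[bad] <- 0
  val
}

#' Construct a Zernike coefficient vector
#'
#' The common currency of aberration, correction and refocusing: a sparse map
#' from Noll index (>= 2; piston carries no image information and is excluded)
#' to modal amplitude in radians of RMS wavefront phase at a stated reference
#' wavelength.
#'
#' @param indices integer Noll indices (>= 2), or a named numeric vector of
#'   amplitudes whose names are Noll indices (then `amplitudes` is ignored).
#' @param amplitudes numeric amplitudes (rad RMS), same length as `indices`.
#' @param reference_wavelength wavelength (nm) at which the phase radians are
#'   referenced; used only by unit conversions.
#' @return object of class `zernike_vector`.
#' @examples
#' zernike_vector(c(5, 11), c(0.3, -0.5))
#' zernike_vector(c(`11` = 1.0))
#' @export
zernike_vector <- function(indices = integer(), amplitudes = numeric(),
                           reference_wavelength = 525) {
  if (!is.null(names(indices)) && length(indices) > 0) {
    amplitudes <- as.numeric(indices)
    indices <- as.numeric(names(indices))
  }
  if (length(indices) != length(amplitudes)) {
    stop("indices and amplitudes must have equal length", call. = FALSE)
  }
  if (length(indices) > 0) {
    if (any(indices < 2) || any(indices != round(indices))) {
      stop("Noll indices must be integers >= 2 (piston excluded)", call. = FALSE)
    }
    if (any(!is.finite(amplitudes))) stop("amplitudes must be finite", call. = FALSE)
  }
  # collapse duplicates index-wise
  amp <- tapply(amplitudes, as.integer(round(indices)), sum)
  keep <- amp != 0 | TRUE  # keep explicit zeros: they are meaningful scan states
  x <- as.numeric(amp[keep])
  names(x) <- names(amp)[keep]
  x <- x[order(as.integer(names(x)))]
  structure(list(coefficients = x, reference_wavelength = reference_wavelength),
            class = "zernike_vector")
}

#' @export
print.zernike_vector <- function(x, ...) {
  cat(sprintf("<zernike_vector> %d mode(s), reference %g nm\n",
              length(x$coefficients), x$reference_wavelength))
  if (length(x$coefficients)) {
    j <- as.integer(names(x$coefficients))
    for (i in seq_along(j)) {
      cat(sprintf("  #%-3d %-32s %+.4f rad\n", j[i], noll_label(j[i]),
                  x$coefficients[i]))
    }
  }
  invisible(x)
}

#' Amplitude of one mode of a Zernike vector
#' @param zv a `zernike_vector`.
#' @param j Noll index vector.
#' @return numeric amplitudes (0 for absent modes).
#' @export
zv_amplitude <- function(zv, j) {
  stopifnot(inherits(zv, "zernike_vector"))
  out <- zv$coefficients[as.character(as.integer(j))]
  out[is.na(out)] <- 0
  unname(out)
}

#' Noll indices present in a Zernike vector
#' @param zv a `zernike_vector`.
#' @return integer vector.
#' @export
zv_modes <- function(zv) {
  as.integer(names(zv$coefficients))
}

#' @export
`+.zernike_vector` <- function(e1, e2) {
  stopifnot(inherits(e1, "zernike_vector"), inherits(e2, "zernike_vector"))
  j <- union(zv_modes(e1), zv_modes(e2))
  zernike_vector(j, zv_amplitude(e1, j) + zv_amplitude(e2, j),
                 reference_wavelength = e1$reference_wavelength)
}

#' @export
`-.zernike_vector` <- function(e1, e2) {
  if (missing(e2)) return(zv_scale(e1, -1))
  e1 + zv_scale(e2, -1)
}

#' Scale every coefficient of a Zernike vector
#' @param zv a `zernike_vector`.
#' @param s scalar factor.
#' @return scaled `zernike_vector`.
#' @export
zv_scale <- function(zv, s) {
  zernike_vector(zv_modes(zv), s * zv_amplitude(zv, zv_modes(zv)),
                 reference_wavelength = zv$reference_wavelength)
}

#' Root-mean-square wavefront amplitude of a Zernike vector
#'
#' Because the modes are orthonormal on the unit disk, modal amplitudes add in
#' quadrature: the wavefront RMS equals `sqrt(sum(a_j^2))`.
#'
#' @param zv a `zernike_vector`.
#' @return RMS phase, radians.
#' @export
zv_rms <- function(zv) {
  sqrt(sum(zv_amplitude(zv, zv_modes(zv))^2))
}

#' Convert modal amplitudes between phase radians and nm of wavefront
#'
#' `a` radians of phase at wavelength `lambda` corresponds to
#' `a * lambda / (2 * pi)` nanometres of optical path difference.
#'
#' @param zv a `zernike_vector` with amplitudes in radians.
#' @return for `zv_rad_to_nm`, a `zernike_vector`-shaped object whose
#'   amplitudes are nm of wavefront; for `zv_nm_to_rad` the reverse.
#' @export
zv_rad_to_nm <- function(zv) {
  out <- zv_scale(zv, zv$reference_wavelength / (2 * pi))
  out
}

#' @rdname zv_rad_to_nm
#' @export
zv_nm_to_rad <- function(zv) {
  zv_scale(zv, 2 * pi / zv$reference_wavelength)
}
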