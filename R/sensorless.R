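# Sensorless modal adaptive optics: estimate aberrations without a
# wavefront sensor by scanning per-mode DM biases, scoring every frame with
# a noise-aware Fourier image-quality metric, and fitting a Gaussian to the
# (bias, metric) points; the fitted mean is the modal correction.

#' The base set of correction modes
#'
#' The eight Zernike modes scanned by default: Noll #5 (primary oblique
#' astigmatism) through #11 (primary spherical), plus #22 (secondary
#' spherical) for depth-induced spherical error.
#'
#' @return integer vector of Noll indices.
#' @export
base_correction_modes <- function() {
  c(5:11, 22L)
}

#' Plan a per-mode bias scan
#'
#' @param modes Noll indices to scan, in scan order.
#' @param biases bias amplitudes, rad; must contain 0 (the unbiased
#'   reference point).
#' @return object of class `bias_scan_plan` with the total image count
#'   `n_images = length(modes) * length(biases)`.
#' @examples
#' plan_bias_scan(base_correction_modes(), c(-1, -0.5, 0, 0.5, 1))$n_images
#' @export
plan_bias_scan <- function(modes = base_correction_modes(),
                           biases = c(-1, -0.5, 0, 0.5, 1)) {
  if (length(modes) == 0 || length(biases) == 0) {
    stop("modes and biases must be non-empty", call. = FALSE)
  }
  if (!any(abs(biases) < 1e-12)) {
    stop("biases must contain 0 (the unbiased reference)", call. = FALSE)
  }
  structure(list(modes = as.integer(modes), biases = sort(biases),
                 n_images = length(modes) * length(biases)),
            class = "bias_scan_plan")
}

#' Configuration of the Fourier image-quality metric
#'
#' The metric integrates windowed spectral power over an annulus of the
#' OTF passband and subtracts a noise floor estimated from frequencies
#' beyond the emission cutoff, where a well-sampled image carries no signal.
#'
#' @param annulus `c(low, high)` bounds of the signal annulus as fractions
#'   of the emission incoherent cutoff `2 NA / lambda_em`; `0 < low < high
#'   <= 1`.
#' @param noise_band width of the noise-floor band, as a fraction of the
#'   cutoff, starting at the cutoff (entirely above it).
#' @param window apodisation window: `"hann"` or `"none"`.
#' @param normalize_dc divide the spectrum by its DC power first, making
#'   the metric invariant to global intensity scaling.
#' @return object of class `metric_config`.
#' @export
metric_config <- function(annulus = c(0.1, 0.8), noise_band = 0.25,
                          window = c("hann", "none"), normalize_dc = FALSE) {
  window <- match.arg(window)
  if (!(annulus[1] > 0 && annulus[1] < annulus[2] && annulus[2] <= 1)) {
    stop("require 0 < low < high <= 1 for the annulus", call. = FALSE)
  }
  structure(list(annulus = annulus, noise_band = noise_band,
                 window = window, normalize_dc = normalize_dc),
            class = "metric_config")
}

# Levenberg-Marquardt fit of y = c0 + A exp(-(x - mu)^2 / (2 s^2)) via
# minpack.lm::nls.lm (which, unlike the nls wrappers, also handles exactly
# noise-free data). Returns list(par, r_squared) or NULL on failure.
gaussian_offset_fit <- function(x, y, start, lower, upper) {
  resid_fn <- function(p) {
    y - (p[1] + p[2] * exp(-(x - p[3])^2 / (2 * p[4]^2)))
  }
  out <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = resid_fn,
                       lower = lower, upper = upper,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(out) || !out$info %in% 1:4) return(NULL)
  ss_res <- sum(resid_fn(out$par)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(par = out$par,
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_)
}

hann_window <- function(n) {
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  outer(w, w)
}

#' Noise-aware Fourier image-quality metric
#'
#' Sharp, aberration-free images put more power into mid-to-high spatial
#' frequencies; aberrations attenuate it. The metric is the total windowed
#' spectral power inside the configured annulus of the passband, minus an
#' area-scaled noise floor estimated beyond the cutoff, floored at zero.
#'
#' @param image 2D numeric frame.
#' @param config a [metric_config()].
#' @param optics an [optical_config()] (for voxel size and cutoff).
#' @return scalar metric value >= 0. A constant image returns 0 with a
#'   warning.
#' @export
fourier_metric <- function(image, config = metric_config(),
                           optics = optical_config()) {
  stopifnot(is.matrix(image))
  if (any(!is.finite(image))) stop("image must be finite", call. = FALSE)
  if (max(image) - min(image) < .Machine$double.eps * max(abs(image), 1)) {
    warning("constant image: metric is 0", call. = FALSE)
    return(0)
  }
  n <- nrow(image)
  w <- if (config$window == "hann") hann_window(n) else matrix(1, n, n)
  F <- stats::fft(image * w)
  pw <- Mod(F)^2
  if (config$normalize_dc) pw <- pw / pw[1, 1]
  k <- fft_freq(n, optics$voxel_xy / 1000)           # um^-1
  kr <- sqrt(outer(k^2, k^2, "+"))
  cutoff <- 2 * optics$na / (optics$lambda_em / 1000)
  sig <- kr >= config$annulus[1] * cutoff & kr <= config$annulus[2] * cutoff
  nb <- kr > cutoff & kr <= cutoff * (1 + config$noise_band)
  floor_est <- if (any(nb)) mean(pw[nb]) else 0
  max(0, sum(pw[sig]) - sum(sig) * floor_est)
}

#' Fit a Gaussian through bias-scan metric points
#'
#' Fits `metric = offset + A * exp(-(bias - mean)^2 / (2 sd^2))` by
#' nonlinear least squares; the fitted mean is the modal optimum. If the
#' fit fails, or lands outside 1.5x the scanned bias range, the scan falls
#' back to the bias with the highest metric and flags it.
#'
#' @param biases bias amplitudes, rad (>= 4 points).
#' @param metrics metric values, same length.
#' @return object of class `bias_scan_fit`: `optimum`, `mean`, `sd`,
#'   `amplitude`, `offset`, `r_squared`, `converged`, `fallback`.
#' @export
fit_gaussian_optimum <- function(biases, metrics) {
  if (length(biases) < 4 || length(metrics) != length(biases)) {
    stop("need >= 4 (bias, metric) points", call. = FALSE)
  }
  lo <- min(biases)
  hi <- max(biases)
  span <- hi - lo
  wts <- pmax(metrics - min(metrics), 0)
  mu0 <- if (sum(wts) > 0) sum(biases * wts) / sum(wts) else 0
  fit <- gaussian_offset_fit(
    biases, metrics,
    start = c(c0 = min(metrics), A = max(metrics) - min(metrics),
              mu = mu0, s = span / 3),
    lower = c(-Inf, 0, lo - 2 * span, span / 20),
    upper = c(Inf, Inf, hi + 2 * span, 10 * span))
  mk <- function(optimum, pars, r2, conv, fb) {
    structure(list(optimum = optimum, mean = pars[["mu"]], sd = pars[["s"]],
                   amplitude = pars[["A"]], offset = pars[["c0"]],
                   r_squared = r2, converged = conv, fallback = fb,
                   biases = biases, metrics = metrics),
              class = "bias_scan_fit")
  }
  fb_pars <- c(mu = NA_real_, s = NA_real_, A = NA_real_, c0 = NA_real_)
  if (is.null(fit)) {
    return(mk(biases[which.max(metrics)], fb_pars, NA_real_, FALSE, TRUE))
  }
  pars <- fit$par
  r2 <- fit$r_squared
  mu <- pars[["mu"]]
  in_range <- mu >= 1.5 * lo - 0.5 * hi && mu <= 1.5 * hi - 0.5 * lo
  if (!is.finite(mu) || !in_range) {
    return(mk(biases[which.max(metrics)], pars, r2, TRUE, TRUE))
  }
  mk(mu, pars, r2, TRUE, FALSE)
}

#' @export
print.bias_scan_fit <- function(x, ...) {
  cat(sprintf("<bias_scan_fit> optimum %+.4f rad (R2 %.3f%s)\n",
              x$optimum, x$r_squared,
              if (x$fallback) ", FALLBACK to max-metric bias" else ""))
  invisible(x)
}

#' Sensorless aberration correction of one plane
#'
#' The scanning routine: for each mode of the plan in turn, acquire one
#' widefield frame per bias on top of the corrections accumulated so far,
#' score each frame with the Fourier metric, fit the Gaussian, and take its
#' mean as the modal correction before moving to the next mode. The total
#' number of frames equals the plan's image count times the number of
#' passes; nothing is acquired beyond the plan.
#'
#' Sign convention: returned corrections are the amplitudes applied to the
#' DM, so `combined = system_flat + sample_correction` is directly
#' applicable.
#'
#' @param scope a [virtual_scope()].
#' @param plan a [plan_bias_scan()].
#' @param metric_cfg a [metric_config()].
#' @param initial correction already applied throughout (typically the
#'   system flat), a [zernike_vector()].
#' @param passes number of full passes over the mode list (1 by default).
#' @return object of class `correction_result`: `system_flat` (= `initial`),
#'   `sample_correction`, `combined`, `scans` (per-mode
#'   [fit_gaussian_optimum()] results), `n_images`.
#' @export
correct_plane <- function(scope, plan = plan_bias_scan(),
                          metric_cfg = metric_config(),
                          initial = zernike_vector(), passes = 1) {
  stopifnot(inherits(scope, "virtual_scope"), inherits(plan, "bias_scan_plan"))
  correction <- zernike_vector()
  scans <- list()
  n0 <- scope$render_count
  for (pass in seq_len(passes)) {
    for (j in plan$modes) {
      mets <- numeric(length(plan$biases))
      for (bi in seq_along(plan$biases)) {
        applied <- initial + correction +
          zernike_vector(j, plan$biases[bi])
        frame <- scope_render(scope, applied)
        mets[bi] <- fourier_metric(frame, metric_cfg, scope$config)
      }
      fit <- fit_gaussian_optimum(plan$biases, mets)
      fit$mode <- j
      scans[[paste0("pass", pass, "_mode", j)]] <- fit
      correction <- correction + zernike_vector(j, fit$optimum)
    }
  }
  if (all(vapply(scans, `[[`, logical(1), "fallback"))) {
    stop("correction unreliable: every mode scan fell back", call. = FALSE)
  }
  structure(list(system_flat = initial, sample_correction = correction,
                 combined = initial + correction, scans = scans,
                 n_images = scope$render_count - n0),
            class = "correction_result")
}

#' @export
print.correction_result <- function(x, ...) {
  cat(sprintf("<correction_result> %d image(s) acquired\n", x$n_images))
  print(x$sample_correction)
  invisible(x)
}

#' Calibrate the system flat on a sparse-bead scene
#'
#' Instrument-intrinsic aberrations are corrected first, on a sparse bead
#' sample with no sample-induced term; the result is the 'system flat' on
#' top of which all sample corrections are applied.
#'
#' @param scope a [virtual_scope()] viewing a sparse-bead phantom.
#' @param plan,metric_cfg as in [correct_plane()].
#' @return a [zernike_vector()]: the system-flat DM correction.
#' @export
system_flat_calibration <- function(scope, plan = plan_bias_scan(),
                                    metric_cfg = metric_config()) {
  res <- correct_plane(scope, plan, metric_cfg)
  res$sample_correction
}

#' Export bias-scan results as a long-format table
#'
#' @param result a `correction_result`.
#' @return data.frame with columns `pass`, `mode`, `bias`, `metric`,
#'   `optimum`, `fallback`.
#' @export
scan_table <- function(result) {
  stopifnot(inherits(result, "correction_result"))
  do.call(rbind, lapply(names(result$scans), function(nm) {
    s <- result$scans[[nm]]
    pass <- as.integer(sub("pass(\\d+)_mode\\d+", "\\1", nm))
    data.frame(pass = pass, mode = s$mode, bias = s$biases,
               metric = s$metrics, optimum = s$optimum,
               fallback = s$fallback)
  }))
}
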