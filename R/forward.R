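#' Photon-budget settings for the forward model
#'
#' @param incident_flux Incident photon flux I0 in photons um^-2 s^-1.
#' @param efficiency Detector quantum efficiency eta, between 0 and 1.
#' @param exposure Exposure time Dt in seconds.
#' @param fluence_dynamic,fluence_static Region fluences I_D, I_S in
#'   photons um^-2 for the differential-flux model (default `NA`, unused by
#'   the uniform-flux model).
#' @return A `flux_settings` list.
#' @export
flux_settings <- function(incident_flux = 1e11, efficiency = 0.8,
                          exposure = 1e-3,
                          fluence_dynamic = NA_real_,
                          fluence_static = NA_real_) {
  if (efficiency < 0 || efficiency > 1) {
    stop("efficiency must lie in [0, 1]", call. = FALSE)
  }
  vals <- c(incident_flux, exposure, fluence_dynamic, fluence_static)
  if (any(vals[!is.na(vals)] < 0)) {
    stop("flux settings must be non-negative", call. = FALSE)
  }
  structure(list(incident_flux = incident_flux, efficiency = efficiency,
                 exposure = exposure, fluence_dynamic = fluence_dynamic,
                 fluence_static = fluence_static),
            class = "flux_settings")
}

# Thomson scale factor mapping |FFT(exit wave in electrons/pixel)|^2 to
# expected photon counts, for a fluence in photons um^-2:
#   eta * fluence * (r_e lambda / (N dr))^2
# with fluence converted to m^-2. N dr is the reconstruction array extent,
# equal to a*sigma1 by the definition of the oversampling ratio.
intensity_scale <- function(fluence_um2, efficiency, wavelength, n, pixel_size) {
  efficiency * fluence_um2 * 1e12 *
    (cdi_constants$r_e * wavelength / (n * pixel_size))^2
}

#' Expected diffraction intensity (uniform flux)
#'
#' Centered discrete Fourier transform of the exit wave, squared magnitude,
#' scaled by `I0 eta Dt (r_e lambda / (a sigma1))^2` where `a sigma1` is the
#' array extent `N dr`. The exit wave is expected in projected-electron
#' (electrons per pixel) units, as produced by [thickness_to_density()]
#' multiplied by the illumination.
#'
#' @param exit_wave A `complex_field` (sample plane) or complex matrix.
#' @param flux A [flux_settings()] object.
#' @param wavelength Wavelength in metres.
#' @param pixel_size Pixel size in metres (taken from `exit_wave` when it is
#'   a `complex_field`).
#' @return Matrix of expected counts per detector pixel (centered ordering,
#'   zero frequency at `center_index(N)`).
#' @export
diffraction_intensity <- function(exit_wave, flux, wavelength,
                                  pixel_size = NULL) {
  psi <- field_values(exit_wave)
  px <- field_pixel_size(exit_wave, default = pixel_size)
  scale <- intensity_scale(flux$incident_flux * flux$exposure,
                           flux$efficiency, wavelength, nrow(psi), px)
  scale * Mod(fft2_centered(psi))^2
}

#' Expected diffraction intensity with differential flux
#'
#' Two-region forward model: with per-region fluences I_D and I_S
#' (photons um^-2) the expected counts are
#' `eta (r_e lambda/(a sigma1))^2 { I_D |Psi_D|^2 + I_S |Psi_S|^2 +
#'  sqrt(I_D I_S) (Psi_D Psi_S^* + Psi_D^* Psi_S) }`,
#' computed as `|sqrt(I_D) Psi_D + sqrt(I_S) Psi_S|^2` (identical expansion,
#' manifestly non-negative). With I_D = I_S = I0 Dt this reduces exactly to
#' the uniform-flux model of [diffraction_intensity()].
#'
#' @param dynamic_wave,static_wave Exit waves of the two regions
#'   (`complex_field` or matrices, electrons per pixel).
#' @param flux A [flux_settings()] with `fluence_dynamic` and
#'   `fluence_static` set (photons um^-2).
#' @param wavelength Wavelength in metres.
#' @param pixel_size Pixel size in metres if the waves are bare matrices.
#' @return Matrix of expected counts per pixel (centered ordering).
#' @export
dual_flux_intensity <- function(dynamic_wave, static_wave, flux, wavelength,
                                pixel_size = NULL) {
  fd <- flux$fluence_dynamic
  fs <- flux$fluence_static
  if (is.na(fd) || is.na(fs) || fd < 0 || fs < 0) {
    stop("fluence_dynamic and fluence_static must be set and non-negative",
         call. = FALSE)
  }
  pd <- field_values(dynamic_wave)
  ps <- field_values(static_wave)
  stopifnot(all(dim(pd) == dim(ps)))
  px <- field_pixel_size(dynamic_wave, default = pixel_size)
  scale <- intensity_scale(1, flux$efficiency, wavelength, nrow(pd), px)
  amp <- fft2_centered(sqrt(fd) * pd + sqrt(fs) * ps)
  pmax(scale * Mod(amp)^2 * 1, 0)
}

#' Draw Poisson-noisy counts
#'
#' Independent Poisson draw per pixel, deterministic given the seed. For
#' expected counts above 1e7 a rounded-normal approximation is used (relative
#' error below ~3e-4 there, and exact Poisson sampling overflows 32-bit
#' integers near 2^31).
#'
#' @param expected Matrix of expected counts (>= 0).
#' @param seed Integer seed.
#' @param exposure Exposure time recorded on the frame (s).
#' @param index Frame index recorded on the frame.
#' @return A `diffraction_frame`: list with `counts`, logical `valid` (all
#'   TRUE), `exposure`, `index`.
#' @export
add_poisson <- function(expected, seed, exposure = NA_real_, index = NA_integer_) {
  if (any(expected < 0)) stop("expected counts must be >= 0", call. = FALSE)
  counts <- with_preserved_seed(seed, {
    out <- expected
    small <- expected <= 1e7
    out[small] <- stats::rpois(sum(small), expected[small])
    if (any(!small)) {
      mu <- expected[!small]
      out[!small] <- pmax(0, round(stats::rnorm(length(mu), mu, sqrt(mu))))
    }
    out
  })
  diffraction_frame(counts, exposure = exposure, index = index)
}

#' Diffraction frame container
#'
#' @param counts Non-negative counts matrix (centered ordering).
#' @param valid Logical validity mask (default all valid).
#' @param exposure Exposure time in seconds.
#' @param index Frame index.
#' @return A `diffraction_frame` object.
#' @export
diffraction_frame <- function(counts, valid = NULL, exposure = NA_real_,
                              index = NA_integer_) {
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  if (is.null(valid)) valid <- matrix(TRUE, nrow(counts), ncol(counts))
  stopifnot(is.logical(valid), all(dim(valid) == dim(counts)))
  structure(list(counts = counts, valid = valid, exposure = exposure,
                 index = index), class = "diffraction_frame")
}

#' @export
print.diffraction_frame <- function(x, ...) {
  cat(sprintf("<diffraction_frame> %d x %d px, %.4g total counts, %d masked px\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts), sum(!x$valid)))
  invisible(x)
}

#' Invalidate the missing-centre block
#'
#' Marks the central `(2 half_width + 1)^2` block (centred on the
#' zero-frequency pixel, `center_index(N)`) invalid. Counts are unchanged;
#' invalid pixels carry no constraint weight in reconstruction. Idempotent.
#'
#' @param frame A `diffraction_frame`.
#' @param half_width Half-width of the block (2 gives the 5 x 5 centre).
#' @return The frame with an updated validity mask.
#' @export
apply_missing_center <- function(frame, half_width = 2L) {
  n <- nrow(frame$counts)
  if (2 * half_width + 1 > n) stop("missing-centre block exceeds the frame",
                                   call. = FALSE)
  c0 <- center_index(n)
  idx <- (c0 - half_width):(c0 + half_width)
  frame$valid[idx, idx] <- FALSE
  frame
}

#' Integrate sub-frame intensity patterns
#'
#' Pixelwise sum of expected-count patterns: motion blur acts on intensity,
#' not amplitude, because sub-frame exit waves are mutually incoherent in
#' time.
#'
#' @param patterns List of expected-count matrices on a common grid.
#' @return Matrix of summed expected counts.
#' @export
integrate_subframes <- function(patterns) {
  stopifnot(is.list(patterns), length(patterns) >= 1)
  dims <- dim(patterns[[1]])
  for (p in patterns) stopifnot(all(dim(p) == dims))
  Reduce(`+`, patterns)
}

#' Convert counts to Fourier magnitudes
#'
#' Divides out the forward-model scale factor so magnitudes are in the same
#' (electron) units as `|FFT(P O)|`, i.e. object estimates come out in
#' electrons per pixel.
#'
#' @param counts Counts matrix.
#' @param scale The intensity scale factor used by the forward model
#'   (photon counts per squared electron-unit magnitude).
#' @return Magnitude matrix `sqrt(counts / scale)`.
#' @export
counts_to_magnitude <- function(counts, scale) {
  sqrt(pmax(counts, 0) / scale)
}
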