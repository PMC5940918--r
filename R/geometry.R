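#' Photon energy to wavelength
#'
#' @param energy_ev Photon energy in eV (> 0).
#' @return Wavelength in metres, `hc / E` with `hc` = 1239.84 eV nm.
#' @export
energy_to_wavelength <- function(energy_ev) {
  if (any(!is.finite(energy_ev)) || any(energy_ev <= 0)) {
    stop("photon energy must be positive", call. = FALSE)
  }
  cdi_constants$hc_ev_nm / energy_ev * 1e-9
}

#' Experiment geometry for a CDI measurement
#'
#' Bundles the photon energy, propagation distances and detector parameters,
#' and derives the wavelength, reconstruction pixel size, oversampling ratio
#' and detector-edge resolution.
#'
#' @param photon_energy Photon energy in eV.
#' @param sample_to_detector Sample-to-detector distance z in metres.
#' @param detector_pixels Detector side length N in pixels.
#' @param detector_pitch Detector pixel pitch p in metres.
#' @param illuminated_extent Tight extent a of the illuminated area in metres
#'   (for a dual pinhole: hole diameter + centre spacing).
#' @param aperture_to_sample Aperture-to-sample propagation distance in metres
#'   (default 0, i.e. aperture in contact).
#' @return An `experiment_geometry` object (list with the inputs plus
#'   `wavelength`, `pixel_size` = lambda z / (N p), `oversampling`,
#'   `edge_resolution`).
#' @export
experiment_geometry <- function(photon_energy, sample_to_detector,
                                detector_pixels, detector_pitch,
                                illuminated_extent,
                                aperture_to_sample = 0) {
  lens <- c(sample_to_detector = sample_to_detector,
            detector_pitch = detector_pitch,
            illuminated_extent = illuminated_extent)
  if (any(!is.finite(lens)) || any(lens <= 0)) {
    stop("all geometry lengths must be strictly positive", call. = FALSE)
  }
  if (detector_pixels < 2) stop("need at least a 2-pixel detector", call. = FALSE)
  lambda <- energy_to_wavelength(photon_energy)
  g <- structure(list(
    photon_energy = photon_energy,
    wavelength = lambda,
    aperture_to_sample = aperture_to_sample,
    sample_to_detector = sample_to_detector,
    detector_pixels = as.integer(detector_pixels),
    detector_pitch = detector_pitch,
    illuminated_extent = illuminated_extent
  ), class = "experiment_geometry")
  g$pixel_size <- reconstruction_pixel_size(g)
  g$oversampling <- oversampling_ratio(g)
  g$edge_resolution <- detector_edge_resolution(g)
  g
}

#' @export
print.experiment_geometry <- function(x, ...) {
  cat(sprintf(paste0(
    "<experiment_geometry> %g eV (lambda %.4g nm)\n",
    "  detector %d x %d px, pitch %.3g um, z = %.3g cm\n",
    "  reconstruction pixel %.3g nm, edge resolution %.3g nm, sigma1 = %.2f\n"),
    x$photon_energy, x$wavelength * 1e9,
    x$detector_pixels, x$detector_pixels, x$detector_pitch * 1e6,
    x$sample_to_detector * 1e2,
    x$pixel_size * 1e9, x$edge_resolution * 1e9, x$oversampling))
  invisible(x)
}

#' Reconstruction (half-period) pixel size
#'
#' @param geometry An `experiment_geometry`.
#' @return lambda z / (N p) in metres.
#' @export
reconstruction_pixel_size <- function(geometry) {
  with(geometry,
       wavelength * sample_to_detector / (detector_pixels * detector_pitch))
}

#' Full-period resolution at the detector edge
#'
#' Full-period convention: twice the reconstruction pixel size,
#' 2 lambda z / (N p). The half-period value is available as
#' [reconstruction_pixel_size()].
#'
#' @param geometry An `experiment_geometry`.
#' @return Resolution in metres.
#' @export
detector_edge_resolution <- function(geometry) {
  2 * reconstruction_pixel_size(geometry)
}

#' Linear oversampling ratio
#'
#' sigma1 = (lambda z / p) / a: ratio of the reconstruction array extent to
#' the tight extent of the illuminated support. sigma1 > 1 is required for a
#' solvable phase problem.
#'
#' @param geometry An `experiment_geometry`.
#' @return Dimensionless ratio.
#' @export
oversampling_ratio <- function(geometry) {
  with(geometry,
       (wavelength * sample_to_detector / detector_pitch) / illuminated_extent)
}
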