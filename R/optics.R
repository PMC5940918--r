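#' Dual-pinhole aperture transmission
#'
#' Binary aperture with two circular openings centred symmetrically about the
#' grid centre along the row axis. A pixel is open when its centre lies inside
#' a disc (no anti-aliasing, for reproducibility).
#'
#' @param n Grid side length in pixels.
#' @param pixel_size Grid pixel size in metres.
#' @param hole_diameter Pinhole diameter in metres. 0 gives an empty aperture.
#' @param center_spacing Centre-to-centre spacing in metres (>= 0). With
#'   `center_spacing = 0` the two discs coincide (a single pinhole).
#' @return A `complex_field` on the aperture plane with values 0/1.
#' @export
dual_pinhole_aperture <- function(n, pixel_size, hole_diameter,
                                  center_spacing) {
  if (center_spacing < 0) stop("center_spacing must be >= 0", call. = FALSE)
  if (hole_diameter < 0) stop("hole_diameter must be >= 0", call. = FALSE)
  vals <- matrix(0, n, n)
  if (hole_diameter > 0) {
    r_px <- hole_diameter / 2 / pixel_size
    s_px <- center_spacing / pixel_size
    if (center_spacing > 0 && center_spacing < hole_diameter) {
      stop("pinholes overlap: center_spacing < hole_diameter", call. = FALSE)
    }
    c0 <- center_index(n)
    if (c0 - s_px / 2 - r_px < 1 || c0 + s_px / 2 + r_px > n) {
      stop("pinholes clipped by the grid boundary", call. = FALSE)
    }
    d1 <- disc_mask(n, c(c0 - s_px / 2, c0), r_px)
    d2 <- disc_mask(n, c(c0 + s_px / 2, c0), r_px)
    vals[d1 | d2] <- 1
  }
  complex_field(vals, pixel_size, plane = "aperture")
}

#' Free-space propagation (band-limited angular spectrum)
#'
#' Propagates a field by a signed distance using the angular-spectrum method,
#' exact for free space on a periodic grid. Spatial frequencies beyond 1/lambda
#' (evanescent) are attenuated; for the geometries handled here the sampled
#' band is entirely propagating, so total power is conserved to machine
#' precision and `propagate(propagate(f, d), -d)` restores `f`.
#'
#' @param field A `complex_field`.
#' @param distance Signed propagation distance in metres (0 is an identity).
#' @param wavelength Wavelength in metres.
#' @return The propagated `complex_field` (same grid and plane label
#'   "sample").
#' @export
propagate <- function(field, distance, wavelength) {
  vals <- field_values(field)
  px <- field_pixel_size(field)
  if (distance == 0) {
    return(complex_field(vals, px, plane = "sample"))
  }
  n <- nrow(vals)
  f <- c(0:(n - floor(n / 2) - 1), -(floor(n / 2):1)) / (n * px)
  f2 <- outer(f^2, f^2, "+")
  kz2 <- 1 / wavelength^2 - f2
  prop <- kz2 > 0
  # sampling-adequacy check: the kernel phase step between neighbouring
  # frequency samples should stay below pi at the band edge
  h <- matrix(0i, n, n)
  h[prop] <- exp(2i * pi * distance * sqrt(kz2[prop]))
  h[!prop] <- exp(-2 * pi * abs(distance) * sqrt(-kz2[!prop]))
  fmax <- 1 / (2 * px)
  if (fmax < 1 / wavelength) {
    # worst-case phase increment of the transfer function across one
    # frequency sample at the band edge
    dphi <- 2 * pi * abs(distance) * fmax / (n * px) /
      sqrt(max(1 / wavelength^2 - fmax^2, .Machine$double.eps))
    if (dphi > pi) {
      warning("propagation kernel under-sampled; increase the grid or ",
              "reduce the distance", call. = FALSE)
    }
  }
  out <- stats::fft(stats::fft(vals) * h, inverse = TRUE) / length(vals)
  complex_field(out, px, plane = "sample")
}

#' Dual-pinhole illumination and region masks
#'
#' Convenience constructor for the in situ CDI illumination: builds the binary
#' dual-pinhole aperture, propagates it to the sample plane, and derives the
#' disjoint static/dynamic support masks from the ideal (unpropagated) discs
#' dilated by a few pixels to absorb propagation fringes.
#'
#' @inheritParams dual_pinhole_aperture
#' @param propagation_distance Aperture-to-sample distance in metres.
#' @param wavelength Wavelength in metres.
#' @param dilate_px Mask dilation radius in pixels (default 2).
#' @param dynamic_side Which pinhole holds the dynamic specimen: `"first"`
#'   (lower row indices) or `"second"`.
#' @return A list with `illumination` (`complex_field`), `masks`
#'   (a `region_masks` list with logical matrices `static`, `dynamic`) and
#'   the disc geometry (`centers_px`, `radius_px`).
#' @export
make_illumination <- function(n, pixel_size, hole_diameter, center_spacing,
                              propagation_distance, wavelength,
                              dilate_px = 2L, dynamic_side = c("first", "second")) {
  dynamic_side <- match.arg(dynamic_side)
  ap <- dual_pinhole_aperture(n, pixel_size, hole_diameter, center_spacing)
  P <- propagate(ap, propagation_distance, wavelength)
  r_px <- hole_diameter / 2 / pixel_size
  s_px <- center_spacing / pixel_size
  c0 <- center_index(n)
  c1 <- c(c0 - s_px / 2, c0)
  c2 <- c(c0 + s_px / 2, c0)
  d1 <- dilate_mask(disc_mask(n, c1, r_px), dilate_px)
  d2 <- dilate_mask(disc_mask(n, c2, r_px), dilate_px)
  if (any(d1 & d2)) {
    stop("support masks overlap after dilation; reduce dilate_px or ",
         "increase the pinhole spacing", call. = FALSE)
  }
  if (dynamic_side == "first") {
    masks <- region_masks(static = d2, dynamic = d1)
    centers <- list(dynamic = c1, static = c2)
  } else {
    masks <- region_masks(static = d1, dynamic = d2)
    centers <- list(dynamic = c2, static = c1)
  }
  list(illumination = P, masks = masks, centers_px = centers,
       radius_px = r_px)
}

#' Disjoint static/dynamic support masks
#'
#' @param static,dynamic Logical matrices of equal size, pixelwise disjoint
#'   and each non-empty.
#' @return A `region_masks` object.
#' @export
region_masks <- function(static, dynamic) {
  stopifnot(is.logical(static), is.logical(dynamic),
            all(dim(static) == dim(dynamic)))
  if (!any(static) || !any(dynamic)) {
    stop("both region masks must be non-empty", call. = FALSE)
  }
  if (any(static & dynamic)) {
    stop("static and dynamic masks must be disjoint", call. = FALSE)
  }
  structure(list(static = static, dynamic = dynamic), class = "region_masks")
}
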