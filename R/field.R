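#' Complex-valued field on a square grid
#'
#' Container for 2-D complex fields sampled on a regular square grid with a
#' physical pixel size: illumination functions, object (projected electron
#' density) maps, exit waves and Fourier-space fields all use this type.
#'
#' @param values Square complex (or numeric, promoted) matrix.
#' @param pixel_size Pixel size in metres (> 0).
#' @param plane One of `"aperture"`, `"sample"`, `"detector"`.
#' @return An object of class `complex_field`.
#' @export
complex_field <- function(values, pixel_size,
                          plane = c("sample", "aperture", "detector")) {
  plane <- match.arg(plane)
  if (!is.matrix(values) || nrow(values) != ncol(values)) {
    stop("`values` must be a square matrix", call. = FALSE)
  }
  if (!is.complex(values)) storage.mode(values) <- "complex"
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    stop("`pixel_size` must be a single positive number", call. = FALSE)
  }
  structure(list(values = values, pixel_size = pixel_size, plane = plane),
            class = "complex_field")
}

#' @export
print.complex_field <- function(x, ...) {
  cat(sprintf("<complex_field> %d x %d, pixel %.3g nm, plane '%s', power %.4g\n",
              nrow(x$values), ncol(x$values), x$pixel_size * 1e9, x$plane,
              field_power(x)))
  invisible(x)
}

#' @export
dim.complex_field <- function(x) dim(x$values)

# Coerce a complex_field or bare matrix to a complex matrix.
field_values <- function(x) {
  if (inherits(x, "complex_field")) return(x$values)
  if (is.matrix(x)) {
    if (!is.complex(x)) storage.mode(x) <- "complex"
    return(x)
  }
  stop("expected a complex_field or a matrix", call. = FALSE)
}

field_pixel_size <- function(x, default = NULL) {
  if (inherits(x, "complex_field")) return(x$pixel_size)
  if (!is.null(default)) return(default)
  stop("pixel size unavailable; pass a complex_field", call. = FALSE)
}

#' Total integrated power of a field
#'
#' @param x A `complex_field` or complex matrix.
#' @return `sum(|x|^2)` (dimensionless; per-pixel sum).
#' @export
field_power <- function(x) sum(Mod(field_values(x))^2)

#' Centre-origin index of an N-pixel axis
#'
#' The zero-frequency / grid-centre pixel sits at 1-based index `N/2 + 1` for
#' even N (floor(N/2) + 1 generally), matching the centered FFT convention
#' used throughout.
#' @param n Axis length.
#' @return 1-based index of the centre pixel.
#' @export
center_index <- function(n) floor(n / 2) + 1L

#' Quadrant swaps between natural and FFT ordering
#'
#' `fftshift()` moves the origin pixel (1,1) of FFT ordering to the grid
#' centre; `ifftshift()` is its exact inverse (they differ for odd N).
#' @param x A matrix.
#' @return The reordered matrix.
#' @export
fftshift <- function(x) {
  n <- nrow(x); m <- ncol(x)
  x[c((floor(n / 2) + 1L):n, 1:floor(n / 2)),
    c((floor(m / 2) + 1L):m, 1:floor(m / 2)), drop = FALSE]
}

#' @rdname fftshift
#' @export
ifftshift <- function(x) {
  n <- nrow(x); m <- ncol(x)
  x[c((ceiling(n / 2) + 1L):n, 1:ceiling(n / 2)),
    c((ceiling(m / 2) + 1L):m, 1:ceiling(m / 2)), drop = FALSE]
}

#' Centered 2-D Fourier transforms
#'
#' Unnormalized forward transform and matching inverse with the real-space and
#' Fourier-space origins both at the grid centre pixel (`center_index(N)`).
#' `ifft2_centered(fft2_centered(x))` reproduces `x` to machine precision.
#'
#' @param x Complex matrix (natural, centre-origin ordering).
#' @return Complex matrix in the same ordering.
#' @export
fft2_centered <- function(x) fftshift(stats::fft(ifftshift(x)))

#' @rdname fft2_centered
#' @export
ifft2_centered <- function(x) {
  fftshift(stats::fft(ifftshift(x), inverse = TRUE)) / length(x)
}

# Matrices of centered pixel coordinates (in pixels) and squared radius.
radius2_matrix <- function(n) {
  ax <- seq_len(n) - center_index(n)
  outer(ax^2, ax^2, "+")
}

# Binary disc mask: pixel centres strictly inside radius (no anti-aliasing).
disc_mask <- function(n, center_px, radius_px) {
  ax <- seq_len(n)
  dx2 <- (ax - center_px[1])^2
  dy2 <- (ax - center_px[2])^2
  outer(dx2, dy2, "+") <= radius_px^2
}

# Gaussian blur by FFT convolution (periodic boundaries), sigma in pixels.
gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  n <- nrow(x)
  f <- c(0:(n - floor(n / 2) - 1), -(floor(n / 2):1)) / n
  g <- exp(-2 * pi^2 * sigma^2 * outer(f^2, f^2, "+"))
  Re(stats::fft(stats::fft(x) * g, inverse = TRUE)) / length(x)
}

# Binary dilation of a logical mask by a disc of integer radius (pixels).
dilate_mask <- function(mask, radius) {
  if (radius <= 0) return(mask)
  n <- nrow(mask); m <- ncol(mask)
  out <- mask
  offsets <- expand.grid(dx = -radius:radius, dy = -radius:radius)
  offsets <- offsets[offsets$dx^2 + offsets$dy^2 <= radius^2, ]
  for (k in seq_len(nrow(offsets))) {
    dx <- offsets$dx[k]; dy <- offsets$dy[k]
    if (dx == 0 && dy == 0) next
    src_r <- pmin(pmax(seq_len(n) - dx, 1L), n)
    src_c <- pmin(pmax(seq_len(m) - dy, 1L), m)
    out <- out | mask[src_r, src_c]
  }
  out
}
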