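#' Fourier ring correlation between two images
#'
#' Ring-wise normalized cross-correlation of the two images' Fourier
#' transforms:
#' `FRC(k) = Re[ sum_ring A conj(B) ] / sqrt( sum_ring |A|^2 sum_ring |B|^2 )`.
#' Symmetric in its arguments, invariant to a common global phase and to a
#' positive scale on either image.
#'
#' @param image_a,image_b `complex_field`s or matrices on equal grids.
#' @param ring_width Ring width in pixels (default 1).
#' @param pixel_size Pixel size in metres (taken from a `complex_field` input
#'   when available); sets the physical frequency axis.
#' @return A tibble of class `frc_curve` with columns `ring`, `radius_px`
#'   (ring centre radius), `frequency` (cycles per metre), `n_pixels` and
#'   `frc`. Empty rings are dropped.
#' @export
frc <- function(image_a, image_b, ring_width = 1, pixel_size = NULL) {
  a <- field_values(image_a); b <- field_values(image_b)
  stopifnot(all(dim(a) == dim(b)))
  px <- tryCatch(field_pixel_size(image_a), error = function(e) pixel_size)
  if (is.null(px)) px <- NA_real_
  n <- nrow(a)
  A <- fft2_centered(a)
  B <- fft2_centered(b)
  r <- sqrt(radius2_matrix(n))
  ring <- as.integer(floor(r / ring_width))
  max_ring <- as.integer(floor((n / 2) / ring_width))
  keep <- ring <= max_ring
  grp <- ring[keep]
  num <- rowsum(Re(A * Conj(B))[keep], grp)[, 1]
  pa <- rowsum(Mod(A[keep])^2, grp)[, 1]
  pb <- rowsum(Mod(B[keep])^2, grp)[, 1]
  cnt <- rowsum(rep(1, sum(keep)), grp)[, 1]
  rid <- as.integer(names(cnt))
  denom <- sqrt(pa * pb)
  val <- ifelse(denom > 0, num / denom, NA_real_)
  out <- tibble::tibble(
    ring = rid,
    radius_px = (rid + 0.5) * ring_width,
    frequency = if (is.na(px)) NA_real_ else (rid + 0.5) * ring_width / (n * px),
    n_pixels = as.integer(cnt),
    frc = as.numeric(val)
  )
  out$frequency[out$ring == 0] <- 0
  out$radius_px[out$ring == 0] <- 0
  out <- out[!is.na(out$frc), ]
  out <- out[order(out$ring), ]
  class(out) <- c("frc_curve", class(out))
  attr(out, "pixel_size") <- px
  attr(out, "n") <- n
  out
}

#' Resolution at a threshold crossing of an FRC curve
#'
#' The curve is smoothed by a 3-ring running median; the resolution is the
#' full-period value `1 / frequency` at the first ring where the smoothed
#' curve falls below the threshold and stays below it for at least 2 rings.
#' If the curve never crosses, the detector-edge (best-case) resolution
#' `2 * pixel_size` is returned and flagged.
#'
#' @param curve An `frc_curve` from [frc()] (needs a physical frequency
#'   axis).
#' @param threshold Crossing threshold in (0, 1); default `1/e`.
#' @param persistence Number of consecutive rings that must sit below the
#'   threshold (default 2).
#' @return A one-row tibble: `resolution` (metres), `crossed` (logical),
#'   `threshold`.
#' @export
resolution_from_frc <- function(curve, threshold = exp(-1), persistence = 2L) {
  stopifnot(nrow(curve) > 0, threshold > 0, threshold < 1)
  px <- attr(curve, "pixel_size")
  if (is.null(px) || is.na(px)) {
    stop("FRC curve has no physical frequency axis; pass pixel_size to frc()",
         call. = FALSE)
  }
  v <- curve$frc
  sm <- if (length(v) >= 3) stats::runmed(v, 3, endrule = "constant") else v
  below <- sm < threshold
  below[curve$ring == 0] <- FALSE  # never report a DC "crossing"
  hit <- NA_integer_
  for (i in seq_along(below)) {
    j <- min(i + persistence - 1L, length(below))
    if (all(below[i:j]) && (j - i + 1L) >= min(persistence, length(below) - i + 1L)) {
      hit <- i; break
    }
  }
  if (is.na(hit)) {
    return(tibble::tibble(resolution = 2 * px, crossed = FALSE,
                          threshold = threshold))
  }
  tibble::tibble(resolution = 1 / curve$frequency[hit], crossed = TRUE,
                 threshold = threshold)
}

#' Align the global phase of one field to a reference
#'
#' Multiplies `x` by the unit phasor that maximizes `Re sum(x conj(ref))`,
#' removing the global-phase ambiguity of phase retrieval before comparison.
#'
#' @param x,ref Complex matrices or `complex_field`s.
#' @return The phase-aligned complex matrix.
#' @export
align_global_phase <- function(x, ref) {
  xv <- field_values(x); rv <- field_values(ref)
  z <- sum(xv * Conj(rv))
  if (Mod(z) == 0) return(xv)
  xv * Conj(z / Mod(z))
}

#' Register a reconstruction to a reference over the trivial ambiguities
#'
#' Phase retrieval determines an object only up to a global phase, an integer
#' lateral translation, and a conjugate inversion (point reflection plus
#' complex conjugation). This registers `x` to `ref` by testing both
#' inversion candidates over all integer circular shifts (via FFT
#' cross-correlation of magnitudes) and aligning the global phase.
#'
#' @param x,ref Complex matrices or `complex_field`s on one grid.
#' @param max_shift Maximum allowed shift in pixels (default n/4).
#' @return The registered complex matrix.
#' @export
register_to_reference <- function(x, ref, max_shift = NULL) {
  xv <- field_values(x); rv <- field_values(ref)
  n <- nrow(xv)
  if (is.null(max_shift)) max_shift <- floor(n / 4)
  # conjugate-inversion candidate: reverse both axes (about the centre pixel)
  flip <- Conj(xv[c(1L, n:2L), c(1L, n:2L), drop = FALSE])
  best <- NULL; best_score <- -Inf
  R <- stats::fft(rv)
  for (cand in list(xv, flip)) {
    xc <- stats::fft(cand)
    cc <- stats::fft(R * Conj(xc), inverse = TRUE) / length(xc)
    sc <- Mod(cc)
    shifts_ok <- outer(pmin(0:(n - 1), n - (0:(n - 1))) <= max_shift,
                       pmin(0:(n - 1), n - (0:(n - 1))) <= max_shift, "&")
    sc[!shifts_ok] <- -Inf
    k <- arrayInd(which.max(sc), dim(sc))
    if (sc[k] > best_score) {
      best_score <- sc[k]
      dx <- k[1] - 1L; dy <- k[2] - 1L
      shifted <- cand[((seq_len(n) - 1L - dx) %% n) + 1L,
                      ((seq_len(n) - 1L - dy) %% n) + 1L, drop = FALSE]
      best <- shifted
    }
  }
  align_global_phase(best, rv)
}

#' FRC resolution of a reconstruction against a known truth
#'
#' Convenience wrapper: optionally restrict both images to a region mask,
#' register the reconstruction to the truth over the trivial ambiguities,
#' then compute the FRC and its 1/e-threshold resolution.
#'
#' @param recon,truth Complex matrices or `complex_field`s.
#' @param pixel_size Pixel size in metres.
#' @param mask Optional logical region mask applied to both images.
#' @param register Register over translations/inversion first
#'   (default FALSE; the in situ algorithm has no translation ambiguity
#'   because the illumination pins the object).
#' @param threshold FRC threshold (default 1/e).
#' @return A one-row tibble: `resolution`, `crossed`, `threshold`.
#' @export
frc_resolution <- function(recon, truth, pixel_size, mask = NULL,
                           register = FALSE, threshold = exp(-1)) {
  rv <- field_values(recon); tv <- field_values(truth)
  if (!is.null(mask)) {
    rv <- rv * mask; tv <- tv * mask
  }
  if (register) rv <- register_to_reference(rv, tv)
  resolution_from_frc(frc(rv, tv, pixel_size = pixel_size),
                      threshold = threshold)
}

#' Mass absorption coefficient
#'
#' @param mu Linear absorption coefficient in cm^-1.
#' @param rho Density in g cm^-3 (> 0).
#' @return mu / rho in cm^2 g^-1.
#' @export
mass_absorption <- function(mu, rho) {
  if (any(rho <= 0)) stop("density must be > 0", call. = FALSE)
  mu / rho
}

#' Absorbed radiation dose from a photon fluence
#'
#' `D = (P_t / A) (mu E / rho)`: fluence (photons um^-2, converted to cm^-2)
#' times the mass absorption coefficient (cm^2 g^-1) times the photon energy
#' (eV, converted to J), giving J g^-1, converted to Gy (J kg^-1) by a
#' factor of 1000. Linear in fluence and in energy.
#'
#' @param fluence Photon fluence in photons um^-2.
#' @param mu Linear absorption coefficient in cm^-1 (default: average
#'   protein at 530 eV, 1.25e4).
#' @param rho Density in g cm^-3 (default 1.35).
#' @param photon_energy Photon energy in eV (default 530).
#' @return Dose in Gy.
#' @export
dose <- function(fluence, mu = 1.25e4, rho = 1.35, photon_energy = 530) {
  if (any(fluence < 0)) stop("fluence must be >= 0", call. = FALSE)
  fluence_cm2 <- fluence * 1e8
  energy_j <- photon_energy * cdi_constants$ev_joule
  fluence_cm2 * mass_absorption(mu, rho) * energy_j * 1000
}

#' Dose table over a fluence ladder
#'
#' @param fluences Vector of fluences in photons um^-2.
#' @inheritParams dose
#' @return A tibble with `fluence` and `dose_gy`.
#' @export
dose_table <- function(fluences = c(3.5e4, 3.5e5, 3.5e6, 3.5e7),
                       mu = 1.25e4, rho = 1.35, photon_energy = 530) {
  tibble::tibble(fluence = fluences,
                 dose_gy = dose(fluences, mu, rho, photon_energy))
}

#' Fluence reduction factor between two resolution-versus-fluence curves
#'
#' For each (fluence, resolution) point of the assisted arm, finds by
#' log-linear interpolation the fluence the reference arm needs to reach the
#' same resolution, and reports the ratio of the two fluences. Points whose
#' resolution the reference arm never reaches within its ladder are assigned
#' the ratio to the top of the reference ladder (a lower bound).
#'
#' @param assisted,reference Data frames with columns `fluence` and
#'   `resolution` (same units in both).
#' @return A tibble: `fluence`, `resolution`, `reference_fluence_needed`,
#'   `reduction_factor`, `bounded` (TRUE when the factor is a lower bound).
#' @export
fluence_reduction_factor <- function(assisted, reference) {
  ref <- reference[order(reference$fluence), ]
  out <- lapply(seq_len(nrow(assisted)), function(i) {
    res_i <- assisted$resolution[i]
    fl_i <- assisted$fluence[i]
    reach <- ref$resolution <= res_i
    if (!any(reach)) {
      need <- max(ref$fluence); bounded <- TRUE
    } else {
      k <- which(reach)[1]
      if (k == 1) {
        need <- ref$fluence[1]; bounded <- TRUE  # could be even lower
      } else {
        # log-linear interpolation in fluence between the bracketing points
        f1 <- log10(ref$fluence[k - 1]); f2 <- log10(ref$fluence[k])
        r1 <- ref$resolution[k - 1]; r2 <- ref$resolution[k]
        w <- if (r1 == r2) 1 else (r1 - res_i) / (r1 - r2)
        need <- 10^(f1 + w * (f2 - f1)); bounded <- FALSE
      }
    }
    tibble::tibble(fluence = fl_i, resolution = res_i,
                   reference_fluence_needed = need,
                   reduction_factor = need / fl_i,
                   bounded = bounded)
  })
  dplyr::bind_rows(out)
}
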