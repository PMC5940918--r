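#' Algorithm parameters for in situ CDI reconstruction
#'
#' @param gamma Static-function weighting factor between 0 and 1 (default 0.8): the
#'   blend `S' = gamma S_prev + (1 - gamma) S_this` carried along the time
#'   series each iteration.
#' @param eps Regularizer for the object update, as a fraction of
#'   `max|P|^2` (default 1e-6).
#' @param n_iter Number of full sweeps over the time series (default 300).
#' @param seed Integer seed for the random initial phases.
#' @param share_static If `FALSE`, the time-invariant constraint is disabled
#'   and every frame is retrieved independently (control mode).
#' @param alpha `"linear"` uses `alpha = max|P|` in the object update,
#'   `"squared"` uses `max|P|^2` (probe-normalized variant).
#' @param average_window The returned objects are the mean over the final
#'   `average_window` sweeps (default 100, clamped to `n_iter`), suppressing
#'   iteration-to-iteration noise fitting; 1 returns the final iterate.
#' @param density_range Enforce the physical range of a projected electron
#'   density at the support split — non-negative real part (refractive
#'   decrement) and non-positive imaginary part (absorption) — which holds
#'   for every bundled material (default TRUE). Disable for objects in
#'   other units.
#' @return An `algorithm_params` list.
#' @export
algorithm_params <- function(gamma = 0.8, eps = 1e-6, n_iter = 300L,
                             seed = 1L, share_static = TRUE,
                             alpha = c("linear", "squared"),
                             average_window = 100L,
                             density_range = TRUE) {
  if (gamma < 0 || gamma > 1) stop("gamma must lie in [0, 1]", call. = FALSE)
  if (n_iter < 1) stop("n_iter must be >= 1", call. = FALSE)
  structure(list(gamma = gamma, eps = eps, n_iter = as.integer(n_iter),
                 seed = as.integer(seed), share_static = share_static,
                 alpha = match.arg(alpha),
                 average_window = as.integer(average_window),
                 density_range = isTRUE(density_range)),
            class = "algorithm_params")
}

#' Weighted static-function update
#'
#' Pixelwise convex combination `gamma * S_prev + (1 - gamma) * S_this`
#' passing the static estimate along the time series.
#'
#' @param s_prev,s_this Complex matrices (or `complex_field`s) on one grid.
#' @param gamma Weight between 0 and 1.
#' @return Complex matrix.
#' @export
weighted_static_update <- function(s_prev, s_this, gamma) {
  if (gamma < 0 || gamma > 1) stop("gamma must lie in [0, 1]", call. = FALSE)
  a <- field_values(s_prev); b <- field_values(s_this)
  stopifnot(all(dim(a) == dim(b)))
  gamma * a + (1 - gamma) * b
}

#' Fourier magnitude projection
#'
#' Transforms the exit wave, replaces the calculated Fourier magnitude by the
#' measured one on valid pixels (calculated phase retained; calculated value
#' retained unchanged on invalid pixels), and transforms back. Idempotent on
#' valid pixels.
#'
#' @param psi Exit wave (complex matrix or `complex_field`), natural
#'   (centre-origin) ordering.
#' @param magnitude Measured Fourier magnitudes, centered ordering
#'   (zero frequency at `center_index(N)`).
#' @param valid Logical validity mask (default all valid).
#' @return Updated exit wave, complex matrix.
#' @export
fourier_magnitude_projection <- function(psi, magnitude, valid = NULL) {
  p <- field_values(psi)
  stopifnot(all(dim(p) == dim(magnitude)))
  if (is.null(valid)) valid <- matrix(TRUE, nrow(p), ncol(p))
  F <- fft2_centered(p)
  a <- Mod(F)
  Fp <- F
  repl <- valid & a > 0
  Fp[repl] <- F[repl] * (magnitude[repl] / a[repl])
  dead <- valid & a == 0
  Fp[dead] <- magnitude[dead] + 0i
  ifft2_centered(Fp)
}

#' Object update from an exit-wave correction
#'
#' `O' = O + |P| P* / (alpha (|P|^2 + eps)) (psi' - psi)` with
#' `alpha = max|P|` (or `max|P|^2` for the probe-normalized variant); pixels
#' where `P = 0` are left unchanged.
#'
#' @param object Current object estimate (complex matrix).
#' @param psi Exit wave used in the Fourier projection.
#' @param psi_updated Projected exit wave.
#' @param illumination Illumination function P (matrix or `complex_field`).
#' @param eps Regularizer as a fraction of `max|P|^2` (default 1e-6).
#' @param alpha `"linear"` or `"squared"` (see [algorithm_params()]).
#' @return Updated object, complex matrix.
#' @export
object_update <- function(object, psi, psi_updated, illumination,
                          eps = 1e-6, alpha = c("linear", "squared")) {
  alpha <- match.arg(alpha)
  P <- field_values(illumination)
  absP <- Mod(P)
  amax <- max(absP)
  if (amax <= 0) stop("illumination function is identically zero", call. = FALSE)
  a <- if (alpha == "linear") amax else amax^2
  w <- absP * Conj(P) / (a * (absP^2 + eps * amax^2))
  object + w * (psi_updated - psi)
}

#' Split an object into static and dynamic parts
#'
#' Applies the support constraint: `S = O * M_S`, `D = O * M_D`, everything
#' outside both supports set to zero.
#'
#' @param object Complex matrix.
#' @param masks A [region_masks()] object.
#' @return List with complex matrices `static` and `dynamic`.
#' @export
split_object <- function(object, masks) {
  O <- field_values(object)
  list(static = O * masks$static, dynamic = O * masks$dynamic)
}

#' Fourier R-factor
#'
#' Normalized L1 discrepancy between measured and calculated Fourier
#' magnitudes, summed over frames and valid pixels:
#' `R = sum | |m| - |c| | / sum |m|`.
#'
#' @param measured,calculated Magnitude matrices, or lists of them (frames).
#' @param valid Logical mask or list of masks (default all valid).
#' @return Dimensionless R-factor.
#' @export
r_factor <- function(measured, calculated, valid = NULL) {
  if (!is.list(measured)) measured <- list(measured)
  if (!is.list(calculated)) calculated <- list(calculated)
  stopifnot(length(measured) == length(calculated))
  if (!is.null(valid) && !is.list(valid)) valid <- list(valid)
  num <- den <- 0
  for (t in seq_along(measured)) {
    m <- Mod(measured[[t]]); cc <- Mod(calculated[[t]])
    v <- if (is.null(valid)) TRUE else valid[[min(t, length(valid))]]
    num <- num + sum(abs(m - cc)[v])
    den <- den + sum(m[v])
  }
  if (den <= 0) stop("all-zero measured magnitudes", call. = FALSE)
  num / den
}

#' Random-phase initialization for the in situ algorithm
#'
#' For each frame, draws uniform Fourier phases, combines them with the
#' measured magnitudes (zero on invalid pixels), inverse-transforms, divides
#' out the illumination where `|P|` exceeds a threshold, and splits the
#' result onto the two supports. When a known background object (for an
#' immersion experiment, the empty-cell water slab under the pinholes) is
#' supplied, the random component is scaled to the background's rms level
#' and added to it, so the iteration starts inside the convergence basin
#' anchored by the a priori part of the object while remaining
#' seed-stochastic.
#'
#' @param magnitudes List of measured magnitude matrices (centered ordering).
#' @param valid Logical validity mask.
#' @param illumination Illumination `complex_field` or matrix.
#' @param masks A [region_masks()] object.
#' @param seed Integer seed.
#' @param threshold Fraction of `max|P|` below which the division is
#'   suppressed (default 0.1).
#' @param background Optional known complex object component (same grid) to
#'   anchor the initialization.
#' @param background_weight Rms ratio of the random component to the
#'   background (default 1).
#' @return List with per-frame lists `static` and `dynamic`.
#' @export
insitu_initialize <- function(magnitudes, valid, illumination, masks, seed,
                              threshold = 0.1, background = NULL,
                              background_weight = 1) {
  P <- field_values(illumination)
  absP <- Mod(P)
  ok <- absP > threshold * max(absP)
  invP <- matrix(0i, nrow(P), ncol(P))
  invP[ok] <- 1 / P[ok]
  sup <- masks$static | masks$dynamic
  bg <- if (is.null(background)) NULL else field_values(background)
  with_preserved_seed(seed, {
    n <- nrow(P)
    lapply(magnitudes, function(m) {
      phi <- matrix(stats::runif(n * n, 0, 2 * pi), n, n)
      Fi <- m * exp(1i * phi)
      Fi[!valid] <- 0
      O0 <- ifft2_centered(Fi) * invP
      if (!is.null(bg)) {
        bg_rms <- sqrt(mean(Mod(bg[sup])^2))
        rnd_rms <- sqrt(mean(Mod(O0[sup])^2))
        if (rnd_rms > 0 && bg_rms > 0) {
          O0 <- bg + background_weight * (bg_rms / rnd_rms) * O0
        } else {
          O0 <- bg + O0
        }
      }
      split_object(O0, masks)
    })
  })
}

#' In situ CDI reconstruction of a diffraction time series
#'
#' Simultaneously reconstructs the complex exit waves of all frames using the
#' time-invariant static region as a real-space constraint. Each iteration
#' sweeps the frames in order: blend the running static estimate into the
#' frame's static function, add the dynamic function, multiply by the
#' illumination, project onto the measured Fourier magnitudes, update the
#' object, and split it back onto the two supports; the updated static
#' estimate is carried to the next frame (and wraps around to the next
#' sweep). The Fourier R-factor is recorded every sweep.
#'
#' @param frames List of [diffraction_frame()]s (>= 2 for a meaningful
#'   constraint; centered ordering).
#' @param illumination Illumination `complex_field` (sample plane).
#' @param masks A [region_masks()] object consistent with the illumination
#'   support.
#' @param scale Intensity scale factor of the forward model (counts per
#'   squared magnitude unit); used to convert counts to magnitudes so objects
#'   come out in electrons per pixel.
#' @param params An [algorithm_params()] object.
#' @param background Optional known object component (e.g. the empty-cell
#'   water slab) anchoring the initialization; see [insitu_initialize()].
#' @return An `insitu_recon` object: lists `objects`, `statics`, `dynamics`
#'   of per-frame complex matrices, the per-iteration `r_trace`, `params`,
#'   and `pixel_size`.
#' @export
reconstruct_insitu <- function(frames, illumination, masks, scale,
                               params = algorithm_params(),
                               background = NULL) {
  stopifnot(length(frames) >= 1)
  P <- field_values(illumination)
  n <- nrow(P)
  for (f in frames) {
    if (!all(dim(f$counts) == c(n, n))) {
      stop("frame grid does not match the illumination grid", call. = FALSE)
    }
  }
  if (!any(masks$static) || !any(masks$dynamic)) {
    stop("empty region masks", call. = FALSE)
  }
  mags <- lapply(frames, function(f) counts_to_magnitude(f$counts, scale))
  valid <- frames[[1]]$valid
  init <- insitu_initialize(mags, valid, P, masks, params$seed,
                            background = background)

  res <- insitu_core(
    mags = lapply(mags, ifftshift),
    valid = ifftshift(valid),
    P = P,
    MS = masks$static, MD = masks$dynamic,
    S0 = lapply(init, `[[`, "static"),
    D0 = lapply(init, `[[`, "dynamic"),
    gamma = params$gamma, eps_frac = params$eps,
    n_iter = params$n_iter,
    share_static = params$share_static,
    alpha_squared = identical(params$alpha, "squared"),
    avg_window = params$average_window %||% 1L,
    density_range = isTRUE(params$density_range)
  )
  structure(list(objects = res$objects, statics = res$statics,
                 dynamics = res$dynamics,
                 r_trace = as.numeric(res$r_trace),
                 params = params,
                 pixel_size = field_pixel_size(illumination, default = NA_real_)),
            class = "insitu_recon")
}

#' @export
print.insitu_recon <- function(x, ...) {
  cat(sprintf(
    "<insitu_recon> %d frames, %d iterations, final R = %.4g%s\n",
    length(x$objects), length(x$r_trace), x$r_trace[length(x$r_trace)],
    if (isTRUE(x$params$share_static)) "" else " (static constraint off)"))
  invisible(x)
}
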