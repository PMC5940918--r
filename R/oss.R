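#' Parameters for oversampling-smoothness (OSS) phase retrieval
#'
#' @param n_iter Iterations per run (default 500).
#' @param n_runs Independent random starts (default 10); the run with the
#'   lowest Fourier R-factor is returned.
#' @param beta Hybrid input-output feedback parameter (default 0.9).
#' @param n_filters Number of Gaussian filter steps; the filter width steps
#'   down linearly from N to N/10 spatial-frequency pixels (default 10).
#' @param seed Integer seed; run k uses `seed + k - 1` for its random
#'   initial phases.
#' @param range Real-space range constraint applied inside the support each
#'   iteration: `"none"` (default; general complex objects), `"real"`
#'   (non-negative real object: Re >= 0, Im = 0), or `"density"` (projected
#'   electron density: Re >= 0, Im <= 0).
#' @return An `oss_params` list.
#' @export
oss_params <- function(n_iter = 500L, n_runs = 10L, beta = 0.9,
                       n_filters = 10L, seed = 1L,
                       range = c("none", "real", "density")) {
  if (n_iter < 1) stop("n_iter must be >= 1", call. = FALSE)
  if (n_runs < 1) stop("n_runs must be >= 1", call. = FALSE)
  structure(list(n_iter = as.integer(n_iter), n_runs = as.integer(n_runs),
                 beta = beta, n_filters = as.integer(n_filters),
                 seed = as.integer(seed), range = match.arg(range)),
            class = "oss_params")
}

#' Single-frame OSS phase retrieval
#'
#' Reconstructs a complex object from one diffraction pattern with the
#' oversampling-smoothness algorithm: a hybrid input-output update inside the
#' support, with the density outside the support low-pass filtered by a
#' Gaussian `W(k) = exp(-k^2 / (2 alpha^2))` whose width alpha steps down
#' over the iteration schedule. Each stage restarts from the lowest-R iterate
#' so far; the final result is the best of `n_runs` independent random
#' starts, selected by the single-frame Fourier R-factor. Optionally a known
#' static structure is re-imposed on its support every iteration.
#'
#' @param frame A [diffraction_frame()] (centered ordering).
#' @param support Logical support mask (non-empty).
#' @param scale Intensity scale factor of the forward model (counts per
#'   squared magnitude unit).
#' @param params An [oss_params()] object.
#' @param static_values Optional complex matrix of known object values to
#'   enforce where `static_mask` is TRUE (a priori static structure).
#' @param static_mask Logical mask for `static_values`.
#' @return An `oss_recon` object: `object` (complex matrix, supported
#'   region), `r_factor` (best), `run_r_factors` (per run), `best_run`,
#'   `r_trace` of the winning run.
#' @export
oss_reconstruct <- function(frame, support, scale, params = oss_params(),
                            static_values = NULL, static_mask = NULL) {
  if (!any(support)) stop("empty support", call. = FALSE)
  n <- nrow(frame$counts)
  mag <- counts_to_magnitude(frame$counts, scale)
  # Fourier-side arrays go to unshifted (origin-first) ordering for the core;
  # real-space arrays stay in natural centre-origin ordering, which is the
  # ordering the support constraint pins the solution to.
  mag_u <- ifftshift(mag)
  valid_u <- ifftshift(frame$valid)
  has_static <- !is.null(static_values)
  if (has_static) {
    stopifnot(!is.null(static_mask), all(dim(static_mask) == dim(support)))
    st_vals <- field_values(static_values)
    st_mask <- static_mask
  } else {
    st_vals <- matrix(0i, 1, 1)
    st_mask <- matrix(FALSE, 1, 1)
  }

  runs <- vector("list", params$n_runs)
  for (k in seq_len(params$n_runs)) {
    phi <- with_preserved_seed(params$seed + k - 1L, {
      matrix(stats::runif(n * n, 0, 2 * pi), n, n)
    })
    Fi <- mag_u * exp(1i * phi)
    Fi[!valid_u] <- 0
    psi0 <- stats::fft(Fi, inverse = TRUE) / length(Fi)
    psi0 <- psi0 * support
    if (has_static) psi0[st_mask] <- st_vals[st_mask]
    range_mode <- match(params$range %||% "none",
                        c("none", "real", "density")) - 1L
    runs[[k]] <- oss_core(mag_u, valid_u, support, psi0,
                          beta = params$beta, n_iter = params$n_iter,
                          n_filters = params$n_filters,
                          has_static = has_static,
                          static_vals = st_vals, static_mask = st_mask,
                          range_mode = range_mode)
  }
  rs <- vapply(runs, function(r) r$r_factor, numeric(1))
  best <- which.min(rs)
  structure(list(object = runs[[best]]$object,
                 r_factor = rs[best],
                 run_r_factors = rs,
                 best_run = best,
                 r_trace = as.numeric(runs[[best]]$r_trace),
                 energy_outside = as.numeric(runs[[best]]$energy_outside),
                 params = params),
            class = "oss_recon")
}

#' @export
print.oss_recon <- function(x, ...) {
  cat(sprintf("<oss_recon> best of %d runs (run %d), R = %.4g\n",
              length(x$run_r_factors), x$best_run, x$r_factor))
  invisible(x)
}
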