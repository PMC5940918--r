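# Run code under a fixed seed without clobbering the caller's RNG stream.
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Time-evolving dendrite growth phantom
#'
#' Procedural stand-in for an electrodeposition process: a branching,
#' tip-growing metal (Pb) structure anchored at one edge of a circular growth
#' region, immersed in a uniform water layer. Growth is strictly additive, so
#' per-pixel thickness is non-decreasing over the series, and the whole series
#' is a pure function of the seed.
#'
#' @param n Grid side length in pixels.
#' @param pixel_size Pixel size in metres.
#' @param n_steps Number of growth snapshots (e.g. frames x subframes).
#' @param seed Integer RNG seed.
#' @param center_px Centre of the growth region, in pixels
#'   (default grid centre).
#' @param region_radius Radius of the growth region in metres.
#' @param max_thickness Thickness cap in metres (default 500 nm).
#' @param water_thickness Uniform water layer in metres (default 1 um),
#'   reported alongside the metal maps.
#' @param n_seeds Number of initial growth tips.
#' @param branch_prob Per-step branching probability per tip.
#' @param branch_width Dendrite branch width in metres.
#' @param step_length Tip advance per snapshot in metres
#'   (default region_radius / 12).
#' @param smooth_px Gaussian smoothing sigma in pixels applied to each
#'   snapshot (anti-aliasing; linear, so monotonicity is preserved).
#' @param warmup_steps Optional growth steps executed before the first
#'   recorded snapshot (default 0): with a positive value the recorded
#'   series starts from an already developed structure that keeps growing.
#' @return A `dynamic_scene`: list with `frames` (list of n_steps matrices of
#'   Pb thickness in metres), `water_thickness`, `pixel_size`, `material`
#'   ("pb"), `seed`.
#' @export
make_dendrite_series <- function(n, pixel_size, n_steps, seed,
                                 center_px = NULL,
                                 region_radius = 0.25e-6,
                                 max_thickness = 500e-9,
                                 water_thickness = 1e-6,
                                 n_seeds = 3,
                                 branch_prob = 0.25,
                                 branch_width = 40e-9,
                                 step_length = NULL,
                                 smooth_px = 1.2,
                                 warmup_steps = 0L) {
  if (n_steps < 1) stop("n_steps must be >= 1", call. = FALSE)
  total_steps <- n_steps + warmup_steps
  r_px <- region_radius / pixel_size
  if (r_px < 8) stop("growth region too small for the branch scale", call. = FALSE)
  if (is.null(center_px)) center_px <- rep(center_index(n), 2)
  if (is.null(step_length)) step_length <- region_radius / 12
  step_px <- max(step_length / pixel_size, 1)
  w_px <- max(branch_width / 2 / pixel_size, 1)

  arrival <- with_preserved_seed(seed, {
    arrival <- matrix(Inf, n, n)
    stamp <- function(x, y, step) {
      xs <- seq.int(max(1, floor(x - w_px - 1)), min(n, ceiling(x + w_px + 1)))
      ys <- seq.int(max(1, floor(y - w_px - 1)), min(n, ceiling(y + w_px + 1)))
      for (i in xs) for (j in ys) {
        if ((i - x)^2 + (j - y)^2 <= w_px^2 && arrival[i, j] > step) {
          arrival[i, j] <<- step
        }
      }
    }
    # tips start near the lower edge of the growth region, heading inward
    tips_x <- center_px[1] + r_px * 0.9 * rep(1, n_seeds)
    tips_y <- center_px[2] +
      r_px * 0.55 * seq(-1, 1, length.out = max(n_seeds, 2))[seq_len(n_seeds)]
    tips_dir <- stats::runif(n_seeds, pi - 0.3, pi + 0.3)
    for (k in seq_len(n_seeds)) stamp(tips_x[k], tips_y[k], 1)

    for (s in seq_len(total_steps)) {
      keep <- integer(0)
      new_x <- new_y <- new_d <- numeric(0)
      for (k in seq_along(tips_x)) {
        d <- tips_dir[k] + stats::rnorm(1, 0, 0.35)
        x <- tips_x[k] + step_px * cos(d)
        y <- tips_y[k] + step_px * sin(d)
        inside <- (x - center_px[1])^2 + (y - center_px[2])^2 <= (0.95 * r_px)^2
        if (inside) {
          stamp(x, y, s)
          tips_x[k] <- x; tips_y[k] <- y; tips_dir[k] <- d
          keep <- c(keep, k)
          if (stats::runif(1) < branch_prob && length(tips_x) < 60) {
            new_x <- c(new_x, x); new_y <- c(new_y, y)
            new_d <- c(new_d, d + sample(c(-1, 1), 1) * stats::runif(1, 0.5, 1.1))
          }
        }
      }
      tips_x <- c(tips_x[keep], new_x)
      tips_y <- c(tips_y[keep], new_y)
      tips_dir <- c(tips_dir[keep], new_d)
      # growth never goes extinct: when tips die (left the region), new
      # branches nucleate from random already-grown positions
      if (length(tips_x) < n_seeds) {
        occ <- which(is.finite(arrival), arr.ind = TRUE)
        need <- n_seeds - length(tips_x)
        pick <- occ[sample.int(nrow(occ), need, replace = TRUE), , drop = FALSE]
        tips_x <- c(tips_x, pick[, 1])
        tips_y <- c(tips_y, pick[, 2])
        tips_dir <- c(tips_dir, stats::runif(need, 0, 2 * pi))
      }
    }
    arrival
  })

  # thickness ramps with age toward the cap; a linear positive kernel keeps
  # per-pixel monotonicity across snapshots
  ramp <- max(total_steps / 2, 2)
  frames <- lapply(warmup_steps + seq_len(n_steps), function(s) {
    age <- s - arrival
    h <- matrix(0, n, n)
    grown <- is.finite(age) & age >= 0
    h[grown] <- max_thickness * pmin(1, (age[grown] + ramp / 4) / ramp)
    h <- gaussian_blur(h, smooth_px)
    h[h < 0] <- 0
    h
  })
  structure(list(frames = frames, water_thickness = water_thickness,
                 pixel_size = pixel_size, material = "pb", seed = seed),
            class = "dynamic_scene")
}

#' @export
print.dynamic_scene <- function(x, ...) {
  cat(sprintf("<dynamic_scene> %d frames, %d x %d px, material %s, seed %d\n",
              length(x$frames), nrow(x$frames[[1]]), ncol(x$frames[[1]]),
              x$material, x$seed))
  invisible(x)
}

#' Lacey gold static-structure phantom
#'
#' Binary web-like pattern (ridges of a smoothed random field near its median
#' level set) multiplied by a uniform thickness, resembling lacey-carbon
#' morphology. The fill fraction is imposed exactly via a quantile threshold.
#'
#' @param n Grid side in pixels.
#' @param pixel_size Pixel size in metres.
#' @param thickness Uniform thickness in metres (> 0; default 20 nm).
#' @param seed Integer RNG seed.
#' @param fill Target fill fraction between 0.2 and 0.6 (default 0.35).
#' @param feature_scale Correlation length of the web in metres
#'   (default 30 pixels).
#' @return Thickness matrix (metres) with attributes `pixel_size`,
#'   `material = "au"`.
#' @export
make_lacey_gold <- function(n, pixel_size, thickness = 20e-9, seed = 1,
                            fill = 0.35, feature_scale = NULL) {
  if (thickness <= 0) stop("thickness must be > 0", call. = FALSE)
  if (fill < 0.2 || fill > 0.6) stop("fill must lie in [0.2, 0.6]", call. = FALSE)
  if (is.null(feature_scale)) feature_scale <- 30 * pixel_size
  g <- with_preserved_seed(seed, {
    gaussian_blur(matrix(stats::rnorm(n * n), n, n),
                  feature_scale / pixel_size / 2)
  })
  dev <- abs(g - stats::median(g))
  web <- dev <= stats::quantile(dev, fill)
  out <- matrix(0, n, n)
  out[web] <- thickness
  attr(out, "pixel_size") <- pixel_size
  attr(out, "material") <- "au"
  out
}

#' Model-cell phantom (vesicle plus protein aggregates)
#'
#' One elongated organelle (about 2 um long) with a dome thickness profile
#' plus scattered protein aggregates, total thickness capped at
#' `max_thickness` and confined to a central square region.
#'
#' @param n Grid side in pixels.
#' @param pixel_size Pixel size in metres.
#' @param seed Integer RNG seed.
#' @param region_extent Side of the confining square in metres (default 3 um).
#' @param max_thickness Thickness cap in metres (default 1 um).
#' @param center_px Centre of the confining region in pixels
#'   (default grid centre).
#' @param n_aggregates Number of aggregate discs (default 25).
#' @return Thickness matrix (metres) with attributes `pixel_size`,
#'   `material = "protein"`.
#' @export
make_cell_phantom <- function(n, pixel_size, seed = 1,
                              region_extent = 3e-6,
                              max_thickness = 1e-6,
                              center_px = NULL,
                              n_aggregates = 25) {
  half_px <- region_extent / 2 / pixel_size
  if (2 * half_px > n) stop("grid smaller than the cell region", call. = FALSE)
  if (is.null(center_px)) center_px <- rep(center_index(n), 2)
  ax <- seq_len(n)
  X <- outer(ax - center_px[1], rep(1, n))
  Y <- outer(rep(1, n), ax - center_px[2])

  h <- with_preserved_seed(seed, {
    h <- matrix(0, n, n)
    # elongated organelle ~2 um x 0.7 um, random orientation, dome profile
    th <- stats::runif(1, 0, pi)
    a_px <- 1.0e-6 / pixel_size
    b_px <- 0.35e-6 / pixel_size
    U <- (cos(th) * X + sin(th) * Y) / a_px
    V <- (-sin(th) * X + cos(th) * Y) / b_px
    q <- 1 - U^2 - V^2
    dome <- q > 0
    h[dome] <- 0.8 * max_thickness * sqrt(q[dome])
    # scattered aggregates (dome-profiled discs)
    for (k in seq_len(n_aggregates)) {
      cx <- stats::runif(1, -0.85, 0.85) * half_px
      cy <- stats::runif(1, -0.85, 0.85) * half_px
      r <- stats::runif(1, 40e-9, 150e-9) / pixel_size
      t0 <- stats::runif(1, 0.2, 0.6) * max_thickness
      d2 <- (X - cx)^2 + (Y - cy)^2
      inside <- d2 < r^2
      h[inside] <- h[inside] + t0 * sqrt(1 - d2[inside] / r^2)
    }
    h
  })
  h <- pmin(h, max_thickness)
  h <- gaussian_blur(h, 1)
  h[h < 0] <- 0
  h <- pmin(h, max_thickness)
  # confinement is exact: mask after smoothing
  box <- abs(X) <= half_px & abs(Y) <= half_px
  h[!box] <- 0
  attr(h, "pixel_size") <- pixel_size
  attr(h, "material") <- "protein"
  h
}

#' Thickness maps to complex transmission
#'
#' Multiplicative projection (thin-object) approximation:
#' `t(r) = exp(i (2 pi / lambda) sum_m (-delta_m + i beta_m) h_m(r))`,
#' so `|t| <= 1` everywhere for beta >= 0.
#'
#' @param thickness Named list of thickness matrices in metres; names are
#'   material labels present in [optical_constants()].
#' @param photon_energy Photon energy in eV (530 or 8000).
#' @return Complex transmission matrix.
#' @export
thickness_to_transmission <- function(thickness, photon_energy) {
  stopifnot(is.list(thickness), length(thickness) >= 1,
            !is.null(names(thickness)))
  lambda <- energy_to_wavelength(photon_energy)
  acc <- 0
  for (m in names(thickness)) {
    oc <- optical_constants(m, photon_energy)
    acc <- acc + (-oc$delta + 1i * oc$beta) * thickness[[m]]
  }
  exp(2i * pi / lambda * acc)
}

#' Thickness maps to projected complex electron density
#'
#' Converts thickness maps to the projected complex electron count per pixel,
#' `O(r) = (2 pi / (r_e lambda^2)) sum_m (delta_m - i beta_m) h_m(r) px^2`,
#' which equals `(i / (r_e lambda)) log t(r) px^2` for the transmission
#' returned by [thickness_to_transmission()]. This is the object-function
#' representation whose squared Fourier magnitude, scaled by the Thomson
#' factor in [diffraction_intensity()], gives expected photon counts.
#'
#' @inheritParams thickness_to_transmission
#' @param pixel_size Grid pixel size in metres.
#' @return Complex matrix, electrons per pixel (negative imaginary part
#'   carries absorption).
#' @export
thickness_to_density <- function(thickness, photon_energy, pixel_size) {
  stopifnot(is.list(thickness), length(thickness) >= 1,
            !is.null(names(thickness)))
  lambda <- energy_to_wavelength(photon_energy)
  acc <- 0
  for (m in names(thickness)) {
    oc <- optical_constants(m, photon_energy)
    acc <- acc + (oc$delta - 1i * oc$beta) * thickness[[m]]
  }
  2 * pi / (cdi_constants$r_e * lambda^2) * acc * pixel_size^2
}
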