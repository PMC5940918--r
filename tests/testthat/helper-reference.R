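# Shared fixtures and a pure-R reference implementation of the in situ sweep,
# built from the exported per-step operations. The reference is deliberately
# slow and simple; it serves as the independent oracle for the compiled core.

# Pure-R sweep mirroring the algorithm definition step by step.
insitu_sweep_reference <- function(mags, valid, P, masks, S0, D0,
                                   gamma = 0.8, eps = 1e-6, n_iter = 10,
                                   share_static = TRUE) {
  n_frames <- length(mags)
  S <- S0; D <- D0
  S_run <- S[[1]]
  r_trace <- numeric(n_iter)
  den <- sum(unlist(lapply(mags, function(m) sum(m[valid]))))
  for (j in seq_len(n_iter)) {
    num <- 0
    for (t in seq_len(n_frames)) {
      Sp <- if (share_static) weighted_static_update(S_run, S[[t]], gamma)
            else S[[t]]
      O <- Sp + D[[t]]
      psi <- O * P
      Fc <- fft2_centered(psi)
      num <- num + sum(abs(Mod(Fc) - mags[[t]])[valid])
      psip <- fourier_magnitude_projection(psi, mags[[t]], valid)
      Op <- object_update(O, psi, psip, P, eps = eps)
      sp <- split_object(Op, masks)
      S[[t]] <- sp$static
      D[[t]] <- sp$dynamic
      S_run <- sp$static
    }
    r_trace[j] <- num / den
  }
  list(objects = lapply(seq_len(n_frames), function(t) S[[t]] + D[[t]]),
       statics = S, dynamics = D, r_trace = r_trace)
}

# Small dual-pinhole scene used by several test files: two lacey objects in
# the two regions plus a uniform water slab, noiseless expected counts.
mini_scene <- function(n = 96, n_frames = 3, seed = 7) {
  px <- 10e-9
  lam <- energy_to_wavelength(8000)
  il <- make_illumination(n, px, 0.2e-6, 0.26e-6, 10e-6, lam, dilate_px = 2)
  disc_dyn <- insituCDI:::disc_mask(n, il$centers_px$dynamic, il$radius_px)
  disc_sta <- insituCDI:::disc_mask(n, il$centers_px$static, il$radius_px)
  static_h <- make_lacey_gold(n, px, thickness = 300e-9, seed = seed + 1,
                              fill = 0.4, feature_scale = 6 * px) * disc_sta
  water <- 1e-6 * (disc_dyn | disc_sta)
  scale <- insituCDI:::intensity_scale(1e11 * 0.01, 0.8, lam, n, px)
  frames <- list(); truth <- list(); mags <- list()
  for (t in seq_len(n_frames)) {
    dyn_h <- make_lacey_gold(n, px, thickness = 400e-9, seed = seed + 10 + t,
                             fill = 0.35, feature_scale = 5 * px) * disc_dyn
    O <- thickness_to_density(list(pb = dyn_h + static_h, h2o = water),
                              8000, px)
    expc <- scale * Mod(fft2_centered(il$illumination$values * O))^2
    frames[[t]] <- diffraction_frame(expc, index = t)
    truth[[t]] <- O
    mags[[t]] <- sqrt(expc / scale)
  }
  background <- thickness_to_density(list(h2o = water), 8000, px)
  list(n = n, px = px, lambda = lam, illumination = il$illumination,
       masks = il$masks, frames = frames, truth = truth, mags = mags,
       scale = scale, background = background)
}

# Cached copy so several test files can share one scene build.
.mini_env <- new.env(parent = emptyenv())
mini_scene_cached <- function() {
  if (is.null(.mini_env$scene)) .mini_env$scene <- mini_scene()
  .mini_env$scene
}
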