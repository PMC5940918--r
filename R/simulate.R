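#' Simulation presets
#'
#' Two ready-made experiment configurations:
#'
#' * `dendrite_preset()` — hard X-ray (8 keV) imaging of a dendrite growth
#'   process through a dual pinhole, 100 Hz frames integrated from 10 x 1 ms
#'   sub-frames, Poisson noise, 5 x 5 missing centre. The full-scale variant
#'   uses a 1024^2 detector with a ~5.9 nm reconstruction pixel and 1 um
#'   pinholes spaced 1.25 um; the desk variant halves the array and the
#'   aperture/phantom scale together (512^2, 0.5 um pinholes, 5 nm pixel),
#'   preserving the oversampling ratio and the nm-scale resolution target at
#'   a fraction of the cost.
#' * `dose_preset()` — soft X-ray (530 eV) dose-reduction study: a model cell
#'   behind one 3 um pinhole and a lacey-gold static structure behind the
#'   other (4 um centre spacing), 10 um detector pitch at 5 cm. Full scale is
#'   an 1100^2 detector (21.2 nm detector-edge resolution); the desk variant
#'   halves the array (550^2), doubling the reconstruction pixel while
#'   keeping the field of view.
#'
#' @param desk Use the desk-scale variant (default TRUE).
#' @return A `cdi_config` list.
#' @export
dendrite_preset <- function(desk = TRUE) {
  n <- if (desk) 512L else 1024L
  pixel_size <- if (desk) 5e-9 else 6e-6 / 1024
  # Desk variant shrinks the aperture/phantom with the array so that both the
  # reconstruction pixel (~5-6 nm) and the oversampling ratio (~2.7-2.8, i.e.
  # the padding fraction of the array) match the full-scale geometry.
  scale_f <- if (desk) 0.4 else 1
  lambda <- energy_to_wavelength(8000)
  pitch <- 10e-6
  cfg <- list(
    experiment = "dendrite",
    photon_energy = 8000,
    n = n,
    pixel_size = pixel_size,
    detector_pitch = pitch,
    sample_to_detector = pixel_size * n * pitch / lambda,
    hole_diameter = 1e-6 * scale_f,
    center_spacing = 1.25e-6 * scale_f,
    propagation_distance = 10e-6,
    dilate_px = 2L,
    incident_flux = 1e11,
    efficiency = 0.8,
    subframe_exposure = 1e-3,
    subframes = 10L,
    n_frames = 5L,
    missing_half_width = 2L,
    water_thickness = 1e-6,
    dendrite = list(max_thickness = 500e-9, n_seeds = 3, branch_prob = 0.25,
                    branch_width = 40e-9 * scale_f, smooth_px = 0.7),
    static_structure = list(material = "pb", thickness = 300e-9, fill = 0.35,
                            feature_scale_px = 12),
    algorithm = list(gamma = 0.8, eps = 1e-6, n_iter = 500L)
  )
  structure(cfg, class = "cdi_config")
}

#' @rdname dendrite_preset
#' @export
dose_preset <- function(desk = TRUE) {
  n <- if (desk) 550L else 1100L
  cfg <- list(
    experiment = "dose",
    photon_energy = 530,
    n = n,
    detector_pitch = 10e-6,
    sample_to_detector = 0.05,
    hole_diameter = 3e-6,
    center_spacing = 4e-6,
    dilate_px = 2L,
    efficiency = 0.8,
    exposure = 1,
    fluence_ladder = c(3.5e4, 3.5e5, 3.5e6, 3.5e7),
    fluence_static = 1.4e10,
    missing_half_width = 2L,
    water_thickness = 1e-6,
    cell = list(region_extent = 3e-6, max_thickness = 1e-6),
    static_structure = list(thickness = 20e-9, fill = 0.35,
                            feature_scale_px = 18),
    oss = list(n_iter = 300L, n_runs = 5L, beta = 0.9, n_filters = 10L)
  )
  lambda <- energy_to_wavelength(cfg$photon_energy)
  cfg$pixel_size <- lambda * cfg$sample_to_detector / (n * cfg$detector_pitch)
  structure(cfg, class = "cdi_config")
}

#' Geometry object for a configuration
#'
#' @param config A `cdi_config`.
#' @return An [experiment_geometry()].
#' @export
config_geometry <- function(config) {
  experiment_geometry(
    photon_energy = config$photon_energy,
    sample_to_detector = config$sample_to_detector,
    detector_pixels = config$n,
    detector_pitch = config$detector_pitch,
    illuminated_extent = config$hole_diameter + config$center_spacing,
    aperture_to_sample = config$propagation_distance %||% 0
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a dendrite-growth diffraction time series
#'
#' Builds the dual-pinhole illumination, grows the dendrite phantom in the
#' dynamic pinhole (with a lacey static structure in the other and a uniform
#' water layer under both), computes each frame's expected diffraction
#' intensity as the sum of sub-frame patterns (motion blur in intensity),
#' adds Poisson noise and masks the missing centre.
#'
#' @param config A [dendrite_preset()]-style configuration.
#' @param seed Integer seed controlling phantom growth and noise.
#' @return A `cdi_stack`: list with `frames` (list of
#'   [diffraction_frame()]s), `illumination`, `masks`, `scale` (counts per
#'   squared-magnitude unit at the full frame exposure), `truth` (per-frame
#'   time-averaged complex object, electrons per pixel), `geometry`,
#'   `config`, `seed`.
#' @export
simulate_dendrite_experiment <- function(config = dendrite_preset(), seed = 1L) {
  n <- config$n
  px <- config$pixel_size
  lambda <- energy_to_wavelength(config$photon_energy)
  geom <- config_geometry(config)

  illum <- make_illumination(
    n, px, config$hole_diameter, config$center_spacing,
    config$propagation_distance, lambda,
    dilate_px = config$dilate_px, dynamic_side = "first")
  P <- illum$illumination
  r_px <- illum$radius_px
  disc_dyn <- disc_mask(n, illum$centers_px$dynamic, r_px)
  disc_sta <- disc_mask(n, illum$centers_px$static, r_px)

  n_sub <- config$subframes
  scene <- make_dendrite_series(
    n, px, n_steps = config$n_frames * n_sub, seed = seed,
    center_px = illum$centers_px$dynamic,
    region_radius = 0.85 * config$hole_diameter / 2,
    max_thickness = config$dendrite$max_thickness,
    water_thickness = config$water_thickness,
    n_seeds = config$dendrite$n_seeds,
    branch_prob = config$dendrite$branch_prob,
    branch_width = config$dendrite$branch_width,
    smooth_px = config$dendrite$smooth_px)

  st <- config$static_structure
  static_h <- make_lacey_gold(n, px, thickness = st$thickness,
                              seed = seed + 1000L, fill = st$fill,
                              feature_scale = st$feature_scale_px * px)
  static_h <- static_h * disc_sta
  water <- config$water_thickness * (disc_dyn | disc_sta)

  flux_sub <- flux_settings(incident_flux = config$incident_flux,
                            efficiency = config$efficiency,
                            exposure = config$subframe_exposure)
  density_of <- function(pb_map) {
    thickness_to_density(
      list(pb = pb_map * disc_dyn + static_h, h2o = water),
      config$photon_energy, px)
  }

  frames <- vector("list", config$n_frames)
  truth <- vector("list", config$n_frames)
  for (f in seq_len(config$n_frames)) {
    subs <- vector("list", n_sub)
    dens_sum <- 0
    for (s in seq_len(n_sub)) {
      O <- density_of(scene$frames[[(f - 1L) * n_sub + s]])
      dens_sum <- dens_sum + O
      psi <- field_values(P) * O
      subs[[s]] <- diffraction_intensity(psi, flux_sub, lambda, px)
    }
    expected <- integrate_subframes(subs)
    fr <- add_poisson(expected, seed = seed + 100L + f,
                      exposure = n_sub * config$subframe_exposure, index = f)
    frames[[f]] <- apply_missing_center(fr, config$missing_half_width)
    truth[[f]] <- dens_sum / n_sub
  }

  scale <- intensity_scale(
    config$incident_flux * n_sub * config$subframe_exposure,
    config$efficiency, lambda, n, px)

  # known empty-cell component (water slab under both pinholes): recorded as
  # the reconstruction's initialization anchor
  background <- thickness_to_density(list(h2o = water),
                                     config$photon_energy, px)

  structure(list(frames = frames, illumination = P, masks = illum$masks,
                 scale = scale, truth = truth, background = background,
                 geometry = geom, config = config, seed = seed),
            class = "cdi_stack")
}

#' @export
print.cdi_stack <- function(x, ...) {
  cat(sprintf("<cdi_stack> '%s': %d frames of %d x %d px, seed %d\n",
              x$config$experiment, length(x$frames),
              nrow(x$frames[[1]]$counts), ncol(x$frames[[1]]$counts), x$seed))
  invisible(x)
}

#' Reconstruct a simulated stack with the in situ algorithm
#'
#' @param stack A `cdi_stack` from [simulate_dendrite_experiment()].
#' @param params [algorithm_params()]; defaults come from the stack's
#'   configuration.
#' @return An `insitu_recon`.
#' @export
reconstruct_stack <- function(stack, params = NULL) {
  if (is.null(params)) {
    a <- stack$config$algorithm
    params <- algorithm_params(gamma = a$gamma, eps = a$eps,
                               n_iter = a$n_iter, seed = stack$seed + 1L)
  }
  reconstruct_insitu(stack$frames, stack$illumination, stack$masks,
                     stack$scale, params, background = stack$background)
}

#' Evaluate an in situ reconstruction against the stack's ground truth
#'
#' Per frame: FRC between the reconstructed object and the known phantom,
#' restricted to the dynamic region, and its 1/e-threshold full-period
#' resolution.
#'
#' @param recon An `insitu_recon`.
#' @param stack The `cdi_stack` it was reconstructed from.
#' @param threshold FRC threshold (default 1/e).
#' @return A tibble: `frame`, `resolution`, `crossed`, `final_r_factor`.
#' @export
evaluate_insitu <- function(recon, stack, threshold = exp(-1)) {
  px <- stack$config$pixel_size
  rows <- lapply(seq_along(recon$objects), function(f) {
    res <- frc_resolution(recon$objects[[f]], stack$truth[[f]],
                          pixel_size = px, mask = stack$masks$dynamic,
                          register = FALSE, threshold = threshold)
    tibble::tibble(frame = f, resolution = res$resolution,
                   crossed = res$crossed)
  })
  out <- dplyr::bind_rows(rows)
  out$final_r_factor <- recon$r_trace[length(recon$r_trace)]
  out
}

#' Average FRC resolution of a reconstructed time series
#'
#' Computes the per-frame FRC curves between the reconstruction and the known
#' phantom over the dynamic region, averages them ring-wise, and extracts the
#' threshold resolution from the mean curve — the study's summary resolution
#' for a time series.
#'
#' @inheritParams evaluate_insitu
#' @return A list: `curve` (the mean `frc_curve`) and `resolution`
#'   (one-row tibble from [resolution_from_frc()]).
#' @export
average_frc_resolution <- function(recon, stack, threshold = exp(-1)) {
  px <- stack$config$pixel_size
  curves <- lapply(seq_along(recon$objects), function(f) {
    frc(recon$objects[[f]] * stack$masks$dynamic,
        stack$truth[[f]] * stack$masks$dynamic, pixel_size = px)
  })
  avg <- curves[[1]]
  frc_mat <- vapply(curves, function(cc) cc$frc, numeric(nrow(avg)))
  avg$frc <- rowMeans(frc_mat)
  list(curve = avg, resolution = resolution_from_frc(avg, threshold))
}

#' Simulate one dose-study diffraction pattern
#'
#' Soft X-ray differential-flux measurement of the model cell, optionally
#' interfering with the lacey-gold static structure at its own (much higher)
#' fluence.
#'
#' @param config A [dose_preset()] configuration.
#' @param fluence_dynamic Fluence on the cell in photons um^-2.
#' @param with_static Include the static structure (at
#'   `config$fluence_static`)?
#' @param seed Integer seed (phantoms and noise).
#' @return List: `frame` ([diffraction_frame()]), `support` (logical),
#'   `scale`, `truth` (cell-region object, electrons per pixel),
#'   `dynamic_mask`, `static_values`, `static_mask` (NULL without static),
#'   `config`, `fluence_dynamic`, `with_static`.
#' @export
simulate_dose_experiment <- function(config = dose_preset(),
                                     fluence_dynamic = 3.5e7,
                                     with_static = TRUE, seed = 1L) {
  n <- config$n
  px <- config$pixel_size
  lambda <- energy_to_wavelength(config$photon_energy)
  r_px <- config$hole_diameter / 2 / px
  s_px <- config$center_spacing / px
  c0 <- center_index(n)
  c_dyn <- c(c0 - s_px / 2, c0)
  c_sta <- c(c0 + s_px / 2, c0)
  disc_dyn <- disc_mask(n, c_dyn, r_px)
  disc_sta <- disc_mask(n, c_sta, r_px)
  sup_dyn <- dilate_mask(disc_dyn, config$dilate_px)
  sup_sta <- dilate_mask(disc_sta, config$dilate_px)

  cell <- make_cell_phantom(n, px, seed = seed,
                            region_extent = config$cell$region_extent,
                            max_thickness = config$cell$max_thickness,
                            center_px = c_dyn)
  O_dyn <- thickness_to_density(
    list(protein = cell * disc_dyn,
         h2o = config$water_thickness * disc_dyn),
    config$photon_energy, px)

  st <- config$static_structure
  lacey <- make_lacey_gold(n, px, thickness = st$thickness,
                           seed = seed + 1000L, fill = st$fill,
                           feature_scale = st$feature_scale_px * px)
  O_sta <- thickness_to_density(
    list(au = lacey * disc_sta,
         h2o = config$water_thickness * disc_sta),
    config$photon_energy, px)

  f_sta <- if (with_static) config$fluence_static else 0
  fx <- flux_settings(efficiency = config$efficiency,
                      exposure = config$exposure,
                      fluence_dynamic = fluence_dynamic,
                      fluence_static = f_sta)
  expected <- dual_flux_intensity(O_dyn, O_sta, fx, lambda, px)
  fr <- add_poisson(expected, seed = seed + 7L,
                    exposure = config$exposure, index = 1L)
  fr <- apply_missing_center(fr, config$missing_half_width)

  # magnitudes are normalized by the dynamic-region amplitude, so the
  # reconstructed object is O_dyn + sqrt(I_S/I_D) O_sta
  scale <- intensity_scale(fluence_dynamic, config$efficiency, lambda, n, px)
  if (with_static) {
    support <- sup_dyn | sup_sta
    static_values <- sqrt(f_sta / fluence_dynamic) * O_sta
    static_mask <- sup_sta
  } else {
    support <- sup_dyn
    static_values <- NULL
    static_mask <- NULL
  }
  list(frame = fr, support = support, scale = scale, truth = O_dyn,
       dynamic_mask = sup_dyn, static_values = static_values,
       static_mask = static_mask, config = config,
       fluence_dynamic = fluence_dynamic, with_static = with_static)
}

#' Run the dose-reduction study
#'
#' For each fluence of the ladder and each arm (with / without the static
#' structure), simulates the diffraction pattern, reconstructs with OSS
#' (best of `n_runs` by Fourier R-factor; the known static structure is
#' enforced as an a priori constraint in the assisted arm), and measures the
#' FRC 1/e resolution of the cell region against the phantom.
#'
#' @param config A [dose_preset()] configuration.
#' @param seed Integer seed.
#' @param fluences Fluence ladder (defaults to the configuration's).
#' @param arms Character vector among `"with_static"`, `"without_static"`.
#' @return A tibble: `arm`, `fluence`, `resolution`, `crossed`, `r_factor`,
#'   `dose_gy`.
#' @export
run_dose_study <- function(config = dose_preset(), seed = 1L,
                           fluences = NULL,
                           arms = c("without_static", "with_static")) {
  if (is.null(fluences)) fluences <- config$fluence_ladder
  o <- config$oss
  rows <- list()
  for (arm in arms) {
    with_static <- identical(arm, "with_static")
    for (fl in fluences) {
      sim <- simulate_dose_experiment(config, fluence_dynamic = fl,
                                      with_static = with_static, seed = seed)
      pars <- oss_params(n_iter = o$n_iter, n_runs = o$n_runs, beta = o$beta,
                         n_filters = o$n_filters,
                         seed = seed + round(log10(fl)) * 10L)
      rec <- oss_reconstruct(sim$frame, sim$support, sim$scale, pars,
                             static_values = sim$static_values,
                             static_mask = sim$static_mask)
      res <- frc_resolution(rec$object, sim$truth,
                            pixel_size = config$pixel_size,
                            mask = sim$dynamic_mask, register = TRUE)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        arm = arm, fluence = fl, resolution = res$resolution,
        crossed = res$crossed, r_factor = rec$r_factor,
        dose_gy = dose(fl, photon_energy = config$photon_energy))
    }
  }
  dplyr::bind_rows(rows)
}

#' Run the dendrite experiment end to end
#'
#' Simulate, reconstruct with the in situ algorithm, and evaluate per-frame
#' FRC resolutions.
#'
#' @param config A [dendrite_preset()] configuration.
#' @param seed Integer seed.
#' @param params Optional [algorithm_params()] override.
#' @return List: `stack`, `recon`, `evaluation` (tibble).
#' @export
run_dendrite_study <- function(config = dendrite_preset(), seed = 1L,
                               params = NULL) {
  stack <- simulate_dendrite_experiment(config, seed = seed)
  recon <- reconstruct_stack(stack, params)
  list(stack = stack, recon = recon,
       evaluation = evaluate_insitu(recon, stack))
}
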