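#' Write / read a diffraction stack
#'
#' The canonical on-disk form is a single RDS file holding the full stack
#' (counts, masks, illumination, truth, configuration, seed), which
#' round-trips exactly. [export_stack_tiff()] additionally writes the counts
#' as a multi-page 32-bit float TIFF with a JSON metadata sidecar for
#' inspection in external viewers.
#'
#' @param stack A `cdi_stack`.
#' @param path Output file path (`.rds`).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "cdi_stack"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(stack, path)
  invisible(path)
}

#' @rdname write_stack
#' @return For `read_stack`, the `cdi_stack`.
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("stack file not found: ", path, call. = FALSE)
  x <- readRDS(path)
  if (!inherits(x, "cdi_stack")) {
    stop("not a cdi_stack file: ", path, call. = FALSE)
  }
  x
}

#' Export stack counts as multi-page TIFF plus JSON metadata
#'
#' @param stack A `cdi_stack`.
#' @param basename Output basename; writes `<basename>.tif` (counts, 32-bit
#'   float, one page per frame), `<basename>_valid.tif` (validity mask) and
#'   `<basename>.json` (geometry, flux and seed metadata).
#' @return The TIFF path, invisibly.
#' @export
export_stack_tiff <- function(stack, basename) {
  stopifnot(inherits(stack, "cdi_stack"))
  dir.create(dirname(basename), recursive = TRUE, showWarnings = FALSE)
  counts <- lapply(stack$frames, function(f) {
    m <- f$counts
    m / max(m, 1)  # TIFF float pages normalized to [0, 1] for viewers
  })
  tiff::writeTIFF(counts, paste0(basename, ".tif"),
                  bits.per.sample = 32L, reduce = FALSE)
  valid <- lapply(stack$frames, function(f) 1 * f$valid)
  tiff::writeTIFF(valid, paste0(basename, "_valid.tif"),
                  bits.per.sample = 32L, reduce = FALSE)
  meta <- list(experiment = stack$config$experiment,
               n = stack$config$n,
               pixel_size = stack$config$pixel_size,
               photon_energy = stack$config$photon_energy,
               n_frames = length(stack$frames),
               count_max = vapply(stack$frames, function(f) max(f$counts),
                                  numeric(1)),
               seed = stack$seed)
  jsonlite::write_json(meta, paste0(basename, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(paste0(basename, ".tif"))
}

#' Write / read a run configuration
#'
#' Configurations are flat YAML documents; a run is reproducible from its
#' configuration and seed alone.
#'
#' @param config A `cdi_config`.
#' @param path Output path (`.yaml`).
#' @return `path` invisibly; for `read_config`, the `cdi_config`.
#' @export
write_config <- function(config, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "cdi_config")
}

#' Write a reconstruction result
#'
#' RDS with the per-frame complex objects, the R-factor trace and the
#' parameters; [export_recon_tiff()] writes magnitude images as a multi-page
#' 32-bit float TIFF.
#'
#' @param recon An `insitu_recon` or `oss_recon`.
#' @param path Output `.rds` path.
#' @return `path`, invisibly.
#' @export
write_recon <- function(recon, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(recon, path)
  invisible(path)
}

#' @rdname write_recon
#' @export
read_recon <- function(path) {
  if (!file.exists(path)) stop("reconstruction file not found: ", path,
                               call. = FALSE)
  readRDS(path)
}

#' @rdname write_recon
#' @param basename Output basename for `export_recon_tiff`.
#' @export
export_recon_tiff <- function(recon, basename) {
  objs <- if (inherits(recon, "oss_recon")) list(recon$object) else recon$objects
  mags <- lapply(objs, function(o) {
    m <- Mod(o)
    m / max(m, .Machine$double.eps)
  })
  dir.create(dirname(basename), recursive = TRUE, showWarnings = FALSE)
  tiff::writeTIFF(mags, paste0(basename, "_magnitude.tif"),
                  bits.per.sample = 32L, reduce = FALSE)
  invisible(paste0(basename, "_magnitude.tif"))
}

#' Export an FRC curve as CSV
#'
#' @param curve An `frc_curve`.
#' @param path Output `.csv` path.
#' @return `path`, invisibly.
#' @export
export_frc_csv <- function(curve, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
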