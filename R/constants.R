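#' Physical constants used throughout
#'
#' @format A named list: `hc_ev_nm` (1239.84 eV nm), `r_e` (classical electron
#'   radius, m), `ev_joule` (J per eV).
#' @export
cdi_constants <- list(
  hc_ev_nm = 1239.84,
  r_e      = 2.8179403262e-15,
  ev_joule = 1.602176634e-19
)

# Tabulated refractive-index decrements delta and absorption indices beta,
# Henke/CXRO-style values at the two photon energies used by the simulations.
# delta/beta were derived from f1/f2 scattering factors and bulk densities
# (Pb 11.35, H2O 1.00, Au 19.32, protein H50C30N9O10S1 at 1.35 g cm^-3);
# beta(protein, 530 eV) corresponds to mu = 1.25e4 cm^-1, the value the dose
# model is anchored to. Accuracy ~10% is sufficient for contrast modelling;
# dose arithmetic never reads this table.
.optical_constants_table <- local({
  rows <- rbind(
    # material, energy_eV, delta,    beta
    c("pb",      8000, 2.74e-05, 3.25e-06),
    c("h2o",     8000, 3.62e-06, 1.28e-08),
    c("au",      8000, 4.71e-05, 4.96e-06),
    c("protein", 8000, 4.68e-06, 1.64e-08),
    c("pb",       530, 2.40e-03, 1.10e-03),
    c("h2o",      530, 4.68e-04, 9.31e-05),
    c("au",       530, 4.40e-03, 1.70e-03),
    c("protein",  530, 9.90e-04, 2.327e-04)
  )
  data.frame(material = rows[, 1],
             photon_energy = as.numeric(rows[, 2]),
             delta = as.numeric(rows[, 3]),
             beta = as.numeric(rows[, 4]),
             stringsAsFactors = FALSE)
})

#' X-ray optical constants for the bundled materials
#'
#' Returns the complex-refractive-index components n = 1 - delta + i beta for
#' lead, water, gold and average protein (H50C30N9O10S1) at 530 eV and 8 keV.
#'
#' @param material One or more of `"pb"`, `"h2o"`, `"au"`, `"protein"`
#'   (case-insensitive). `NULL` returns the full table.
#' @param photon_energy Photon energy in eV (530 or 8000).
#' @return A tibble with columns `material`, `photon_energy`, `delta`, `beta`.
#' @export
optical_constants <- function(material = NULL, photon_energy = NULL) {
  tab <- .optical_constants_table
  if (!is.null(photon_energy)) {
    if (!photon_energy %in% tab$photon_energy) {
      stop("no tabulated constants at ", photon_energy,
           " eV (available: 530, 8000)", call. = FALSE)
    }
    tab <- tab[tab$photon_energy == photon_energy, ]
  }
  if (!is.null(material)) {
    material <- tolower(material)
    missing <- setdiff(material, tab$material)
    if (length(missing) > 0) {
      stop("no tabulated constants for material(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    tab <- tab[match(material, tab$material), ]
  }
  tibble::as_tibble(tab)
}
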