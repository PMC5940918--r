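test_that("energy-to-wavelength conversion matches hc/E", {
  expect_equal(energy_to_wavelength(1239.84), 1e-9, tolerance = 1e-12)
  expect_equal(energy_to_wavelength(530), 2.339e-9, tolerance = 1e-3)
  expect_equal(energy_to_wavelength(8000), 0.15498e-9, tolerance = 1e-4)
  expect_error(energy_to_wavelength(0), "positive")
  expect_error(energy_to_wavelength(-5), "positive")
})

test_that("geometry derivations: pixel size, edge resolution, oversampling", {
  g <- experiment_geometry(530, 0.05, 1100, 10e-6, 7e-6)
  expect_equal(g$wavelength, 2.3393e-9, tolerance = 1e-4)
  # full-period detector-edge resolution, soft X-ray dose geometry
  expect_equal(detector_edge_resolution(g), 21.2e-9, tolerance = 0.01)
  expect_equal(detector_edge_resolution(g), 2 * reconstruction_pixel_size(g))
  # doubling z doubles the edge resolution
  g2 <- experiment_geometry(530, 0.10, 1100, 10e-6, 7e-6)
  expect_equal(detector_edge_resolution(g2), 2 * detector_edge_resolution(g))
  # oversampling for the dual- and single-pinhole extents
  expect_equal(oversampling_ratio(g), 1.7, tolerance = 0.02)
  gs <- experiment_geometry(530, 0.05, 1100, 10e-6, 3e-6)
  expect_equal(oversampling_ratio(gs), 3.9, tolerance = 0.01)
  # halving the extent doubles sigma1
  gh <- experiment_geometry(530, 0.05, 1100, 10e-6, 3.5e-6)
  expect_equal(oversampling_ratio(gh), 2 * oversampling_ratio(g))
  # derived 8 keV case: sigma1 = 2 at a = 3 um, N = 1024 -> 2 a sigma1 / N
  lam <- energy_to_wavelength(8000)
  z <- 2 * 3e-6 * 10e-6 / lam  # z such that (lam z / p) = a sigma1
  g8 <- experiment_geometry(8000, z, 1024, 10e-6, 3e-6)
  expect_equal(oversampling_ratio(g8), 2, tolerance = 1e-6)
  expect_equal(detector_edge_resolution(g8), 2 * 6e-6 / 1024, tolerance = 1e-6)
  expect_error(experiment_geometry(530, -0.05, 1100, 10e-6, 7e-6), "positive")
})

test_that("dual-pinhole aperture rasterization matches disc areas", {
  ap <- dual_pinhole_aperture(512, 10e-9, 1e-6, 1.25e-6)
  # two discs of radius 50 px
  expect_equal(sum(Mod(ap$values)), 2 * pi * 50^2, tolerance = 0.02)
  expect_true(all(ap$values %in% c(0 + 0i, 1 + 0i)))
  # zero diameter -> empty aperture
  expect_equal(field_power(dual_pinhole_aperture(64, 10e-9, 0, 1e-6)), 0)
  # the dose-study aperture: 3 um discs spaced 4 um
  px5 <- 21.2e-9 / 2
  ap5 <- dual_pinhole_aperture(1100, px5, 3e-6, 4e-6)
  expect_equal(sum(Mod(ap5$values)) * px5^2, 2 * pi * (1.5e-6)^2,
               tolerance = 0.02)
  # overlap and clipping errors
  expect_error(dual_pinhole_aperture(128, 10e-9, 1e-6, 0.5e-6), "overlap")
  expect_error(dual_pinhole_aperture(64, 10e-9, 1e-6, 1.25e-6), "clipped")
})

test_that("angular-spectrum propagation is unitary and invertible", {
  set.seed(11)
  n <- 96
  lam <- energy_to_wavelength(8000)
  f <- complex_field(matrix(complex(real = rnorm(n^2), imaginary = rnorm(n^2)),
                            n), 5e-9)
  expect_identical(propagate(f, 0, lam)$values, f$values)
  for (d in c(1e-6, 10e-6, -3e-6)) {
    p <- propagate(f, d, lam)
    expect_equal(field_power(p), field_power(f), tolerance = 1e-6)
    back <- propagate(p, -d, lam)
    expect_lt(max(Mod(back$values - f$values)), 1e-6 * max(Mod(f$values)))
  }
})

test_that("propagated Gaussian beam matches the closed-form waist", {
  n <- 512
  px <- 1e-6
  lam <- 500e-9
  ax <- (seq_len(n) - center_index(n)) * px
  w0 <- 10e-6
  g <- exp(-outer(ax^2, ax^2, "+") / w0^2)  # amplitude waist w0
  f <- complex_field(g + 0i, px)
  zr <- pi * w0^2 / lam
  d <- zr  # one Rayleigh range: waist grows by sqrt(2)
  p <- propagate(f, d, lam)
  w_theory <- w0 * sqrt(1 + (d / zr)^2)
  # measure the waist from the second moment of |u|^2
  inten <- Mod(p$values)^2
  r2 <- outer(ax^2, ax^2, "+")
  w_meas <- sqrt(2 * sum(r2 * inten) / sum(inten))
  expect_equal(w_meas, w_theory, tolerance = 0.01)
})

test_that("region masks from the illumination helper are disjoint and non-empty", {
  lam <- energy_to_wavelength(8000)
  il <- make_illumination(128, 10e-9, 0.3e-6, 0.4e-6, 10e-6, lam)
  expect_false(any(il$masks$static & il$masks$dynamic))
  expect_gt(sum(il$masks$static), 0)
  expect_gt(sum(il$masks$dynamic), 0)
  expect_error(region_masks(il$masks$static, il$masks$static), "disjoint")
  empty <- matrix(FALSE, 4, 4)
  expect_error(region_masks(empty, empty), "non-empty")
})

test_that("optical constants table covers the bundled materials", {
  tab <- optical_constants()
  expect_setequal(unique(tab$material), c("pb", "h2o", "au", "protein"))
  expect_setequal(unique(tab$photon_energy), c(530, 8000))
  expect_true(all(tab$beta >= 0))
  # beta(protein, 530 eV) corresponds to mu = 1.25e4 cm^-1 via beta = mu lambda / 4 pi
  oc <- optical_constants("protein", 530)
  mu <- oc$beta * 4 * pi / energy_to_wavelength(530) / 100  # cm^-1
  expect_equal(mu, 1.25e4, tolerance = 0.01)
  expect_error(optical_constants("kryptonite", 530), "kryptonite")
})
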