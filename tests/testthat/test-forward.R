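test_that("diffraction intensity scales and obeys Parseval", {
  set.seed(4)
  n <- 64; px <- 5e-9
  lam <- energy_to_wavelength(8000)
  psi <- matrix(complex(real = rnorm(n^2), imaginary = rnorm(n^2)), n)
  fx <- flux_settings(incident_flux = 1e11, efficiency = 0.8,
                      exposure = 1e-3)
  I1 <- diffraction_intensity(psi, fx, lam, px)
  expect_true(all(I1 >= 0))
  # zero wave -> zero counts
  expect_equal(sum(diffraction_intensity(matrix(0i, n, n), fx, lam, px)), 0)
  # linear in exposure
  fx2 <- flux_settings(incident_flux = 1e11, efficiency = 0.8,
                       exposure = 2e-3)
  expect_equal(diffraction_intensity(psi, fx2, lam, px), 2 * I1,
               tolerance = 1e-12)
  # Parseval with the unnormalized transform: sum I = scale * N^2 * sum|psi|^2
  scale <- insituCDI:::intensity_scale(1e11 * 1e-3, 0.8, lam, n, px)
  expect_equal(sum(I1), scale * n^2 * sum(Mod(psi)^2), tolerance = 1e-10)
  # invariant to a global phase of the exit wave
  expect_equal(diffraction_intensity(psi * exp(1.3i), fx, lam, px), I1,
               tolerance = 1e-10)
})

test_that("differential flux reduces to the uniform model when I_D = I_S", {
  set.seed(5)
  n <- 64; px <- 21.2e-9 / 2
  lam <- energy_to_wavelength(530)
  pd <- matrix(complex(real = rnorm(n^2), imaginary = rnorm(n^2)), n)
  ps <- matrix(complex(real = rnorm(n^2), imaginary = rnorm(n^2)), n)
  f_eq <- 1e8  # common fluence = I0 * Dt
  fx_dual <- flux_settings(efficiency = 0.8, exposure = 1,
                           fluence_dynamic = f_eq, fluence_static = f_eq)
  fx_uni <- flux_settings(incident_flux = f_eq, efficiency = 0.8,
                          exposure = 1)
  I_dual <- dual_flux_intensity(pd, ps, fx_dual, lam, px)
  I_uni <- diffraction_intensity(pd + ps, fx_uni, lam, px)
  expect_equal(I_dual, I_uni, tolerance = 1e-10)
  # I_S = 0 -> pure dynamic pattern
  fx0 <- flux_settings(efficiency = 0.8, exposure = 1,
                       fluence_dynamic = f_eq, fluence_static = 0)
  expect_equal(dual_flux_intensity(pd, ps, fx0, lam, px),
               diffraction_intensity(pd, fx_uni, lam, px), tolerance = 1e-10)
  expect_error(
    dual_flux_intensity(pd, ps,
                        flux_settings(efficiency = 0.8,
                                      fluence_dynamic = NA_real_), lam, px),
    "fluence")
  # expansion identity: the three-term form equals the amplitude form
  FD <- fft2_centered(pd); FS <- fft2_centered(ps)
  f_d <- 3.5e7; f_s <- 1.4e10
  three_term <- (f_d * Mod(FD)^2 + f_s * Mod(FS)^2 +
                   sqrt(f_d * f_s) * 2 * Re(FD * Conj(FS)))
  fx_df <- flux_settings(efficiency = 0.8, exposure = 1,
                         fluence_dynamic = f_d, fluence_static = f_s)
  scale <- insituCDI:::intensity_scale(1, 0.8, lam, n, px)
  expect_equal(dual_flux_intensity(pd, ps, fx_df, lam, px),
               pmax(scale * three_term, 0), tolerance = 1e-8)
})

test_that("strong static flux boosts high-frequency counts on the dose phantoms", {
  cfg <- dose_preset(desk = TRUE)
  cfg$n <- 256L  # small replica of the geometry for speed
  cfg$pixel_size <- energy_to_wavelength(530) * cfg$sample_to_detector /
    (cfg$n * cfg$detector_pitch)
  sim_with <- simulate_dose_experiment(cfg, fluence_dynamic = 3.5e7,
                                       with_static = TRUE, seed = 3)
  sim_wo <- simulate_dose_experiment(cfg, fluence_dynamic = 3.5e7,
                                     with_static = FALSE, seed = 3)
  n <- cfg$n; c0 <- center_index(n)
  inner <- matrix(FALSE, n, n)
  qtr <- round(n / 8)
  inner[(c0 - qtr):(c0 + qtr), (c0 - qtr):(c0 + qtr)] <- TRUE
  hi_with <- sum(sim_with$frame$counts[!inner])
  hi_wo <- sum(sim_wo$frame$counts[!inner])
  expect_gt(hi_with, hi_wo)
})

test_that("Poisson sampling has the right moments and is seeded", {
  expected <- matrix(100, 100, 100)
  fr <- add_poisson(expected, seed = 9)
  expect_equal(mean(fr$counts), 100, tolerance = 3 * 10 / 100)  # 3 sigma
  expect_equal(var(as.numeric(fr$counts)), 100, tolerance = 0.1 * 100)
  expect_identical(add_poisson(expected, seed = 9)$counts, fr$counts)
  expect_false(identical(add_poisson(expected, seed = 10)$counts, fr$counts))
  # zero expectation -> zero counts
  expect_equal(sum(add_poisson(matrix(0, 8, 8), seed = 1)$counts), 0)
  # large means use the normal branch with matching relative moments
  big <- matrix(4e9, 20, 20)
  frb <- add_poisson(big, seed = 2)
  expect_equal(mean(frb$counts), 4e9, tolerance = 1e-4)
  expect_identical(add_poisson(big, seed = 2)$counts, frb$counts)
  expect_error(add_poisson(matrix(-1, 2, 2), seed = 1), ">= 0")
})

test_that("missing-centre mask invalidates exactly the central block", {
  fr <- diffraction_frame(matrix(7, 64, 64))
  f2 <- apply_missing_center(fr, 2L)
  expect_equal(sum(!f2$valid), 25)
  expect_equal(f2$counts, fr$counts)  # counts unchanged
  c0 <- center_index(64)
  expect_false(f2$valid[c0, c0])
  expect_true(f2$valid[c0 + 3, c0])
  # half width 0 -> single pixel; idempotence
  expect_equal(sum(!apply_missing_center(fr, 0L)$valid), 1)
  expect_identical(apply_missing_center(f2, 2L)$valid, f2$valid)
})

test_that("sub-frame integration is a pixelwise sum", {
  set.seed(6)
  pats <- lapply(1:10, function(i) matrix(rpois(64, 20), 8, 8))
  expect_equal(integrate_subframes(pats), Reduce(`+`, pats))
  expect_equal(integrate_subframes(pats[1]), pats[[1]])
  same <- lapply(1:10, function(i) pats[[1]])
  expect_equal(integrate_subframes(same), 10 * pats[[1]])
})
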