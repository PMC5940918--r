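test_that("FRC self-correlation, scale and phase invariance, symmetry", {
  set.seed(12)
  n <- 64; px <- 10e-9
  a <- matrix(complex(real = rnorm(n^2), imaginary = rnorm(n^2)), n)
  b <- matrix(complex(real = rnorm(n^2), imaginary = rnorm(n^2)), n)
  ca <- frc(a, a, pixel_size = px)
  expect_true(all(abs(ca$frc - 1) < 1e-10))
  # positive scale on either image
  expect_equal(frc(a, 3.7 * a, pixel_size = px)$frc, ca$frc,
               tolerance = 1e-10)
  # common global phase
  expect_equal(frc(a * exp(0.7i), b * exp(0.7i), pixel_size = px)$frc,
               frc(a, b, pixel_size = px)$frc, tolerance = 1e-10)
  # symmetry
  expect_equal(frc(a, b, pixel_size = px)$frc, frc(b, a, pixel_size = px)$frc,
               tolerance = 1e-10)
  expect_true(all(frc(a, b, pixel_size = px)$frc >= -1 - 1e-12))
  expect_true(all(frc(a, b, pixel_size = px)$frc <= 1 + 1e-12))
})

test_that("FRC of independent noise is near zero on well-populated rings", {
  set.seed(13)
  n <- 256
  a <- matrix(rnorm(n^2), n)
  b <- matrix(rnorm(n^2), n)
  cur <- frc(a, b, pixel_size = 1e-9)
  busy <- cur[cur$n_pixels >= 100, ]
  # bounds calibrated on a 10-seed null simulation of this exact setup
  expect_gt(mean(abs(busy$frc) < 0.1), 0.85)
  expect_gt(mean(abs(busy$frc) < 0.15), 0.95)
  expect_lt(max(abs(busy$frc)), 0.35)
})

test_that("resolution extraction finds the threshold crossing", {
  n <- 128; px <- 5e-9
  # synthetic curve: build images whose FRC steps from 1 to 0 at a known ring
  # via a hard low-pass: beyond the cut, image b has independent content
  set.seed(14)
  a <- matrix(rnorm(n^2), n)
  cut <- 32
  r <- sqrt(insituCDI:::radius2_matrix(n))
  Fa <- fft2_centered(a)
  Fb <- Fa
  noise_f <- fft2_centered(matrix(rnorm(n^2), n))
  Fb[r > cut] <- noise_f[r > cut]
  b <- Re(ifft2_centered(Fb))
  cur <- frc(a, b, pixel_size = px)
  res <- resolution_from_frc(cur)
  expect_true(res$crossed)
  # crossing at ring ~cut: resolution = (n px) / cut within 2 rings
  expect_equal(1 / res$resolution, cut / (n * px),
               tolerance = 2 / cut)
  # identical images never cross: detector-edge value, flagged
  res_id <- resolution_from_frc(frc(a, a, pixel_size = px))
  expect_false(res_id$crossed)
  expect_equal(res_id$resolution, 2 * px)
  expect_error(resolution_from_frc(frc(a, a)), "pixel_size")
})

test_that("added noise never improves the reported resolution", {
  set.seed(15)
  n <- 96; px <- 5e-9
  base <- insituCDI:::gaussian_blur(matrix(rnorm(n^2), n), 2)
  ref <- resolution_from_frc(frc(base, base + 0.05 * matrix(rnorm(n^2), n),
                                 pixel_size = px))$resolution
  worse <- 0
  for (k in 1:20) {
    noisy <- base + 0.6 * matrix(rnorm(n^2), n)
    res <- resolution_from_frc(frc(base, noisy, pixel_size = px))$resolution
    expect_gte(res, ref * 0.999)
    worse <- worse + (res > ref)
  }
  expect_gt(worse, 10)  # noise degrades resolution most of the time
})

test_that("registration removes the trivial ambiguities before FRC", {
  set.seed(16)
  n <- 64
  obj <- matrix(0i, n, n)
  obj[20:40, 25:35] <- complex(real = runif(21 * 11), imaginary = runif(21 * 11))
  # shifted + global phase
  sh <- obj[c(4:n, 1:3), c(n, 1:(n - 1))] * exp(1.1i)
  reg <- register_to_reference(sh, obj)
  expect_lt(max(Mod(reg - obj)), 1e-8)
  # conjugate inversion about the centre pixel
  flip <- Conj(obj[c(1, n:2), c(1, n:2)])
  reg2 <- register_to_reference(flip, obj)
  expect_lt(max(Mod(reg2 - obj)), 1e-8)
})

test_that("dose arithmetic reproduces the protein reference values", {
  expect_equal(mass_absorption(1.25e4, 1.35), 9.26e3, tolerance = 1e-3)
  expect_equal(mass_absorption(0, 1.35), 0)
  expect_equal(mass_absorption(1.25e4, 2.7), 9.26e3 / 2, tolerance = 1e-3)
  expect_equal(dose(3.5e7), 2.75e6, tolerance = 0.01)
  expect_equal(dose(3.5e4), 2.75e3, tolerance = 0.01)
  expect_equal(dose(0), 0)
  # linear in fluence and energy
  expect_equal(dose(7e4), 2 * dose(3.5e4))
  expect_equal(dose(3.5e4, photon_energy = 1060), 2 * dose(3.5e4))
  tab <- dose_table()
  expect_equal(nrow(tab), 4)
  expect_equal(tab$dose_gy, dose(tab$fluence))
})

test_that("fluence reduction factor interpolates on the reference ladder", {
  assisted <- tibble::tibble(fluence = c(1e5, 1e6),
                             resolution = c(40e-9, 25e-9))
  reference <- tibble::tibble(fluence = c(1e5, 1e6, 1e7, 1e8),
                              resolution = c(200e-9, 80e-9, 40e-9, 25e-9))
  out <- fluence_reduction_factor(assisted, reference)
  expect_equal(out$reference_fluence_needed[1], 1e7)  # exact ladder match
  expect_equal(out$reduction_factor[1], 100)
  expect_equal(out$reduction_factor[2], 100)
  # resolution unreachable by the reference -> bounded at ladder top
  out2 <- fluence_reduction_factor(
    tibble::tibble(fluence = 1e5, resolution = 10e-9), reference)
  expect_true(out2$bounded)
  expect_equal(out2$reference_fluence_needed, 1e8)
})
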