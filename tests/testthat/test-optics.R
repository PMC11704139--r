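test_that("Zernike polynomials match the closed-form Noll table", {
  expect_equal(zernike_eval(1, 0.37, 1.2), 1)          # piston is constant
  expect_equal(zernike_eval(4, 1, 0), sqrt(3) * (2 * 1 - 1))
  expect_equal(zernike_eval(4, 0, 0), -sqrt(3))
  expect_equal(zernike_eval(11, 0, 0), sqrt(5) * 1)    # 6r^4 - 6r^2 + 1 at 0
  expect_equal(zernike_eval(11, 1, 0), sqrt(5) * 1)
  # astigmatism and coma angular structure
  expect_equal(zernike_eval(6, 0.5, 0), sqrt(6) * 0.25)        # cos(2*0)
  expect_equal(zernike_eval(5, 0.5, pi / 4), sqrt(6) * 0.25)   # sin(pi/2)
  expect_equal(zernike_eval(8, 1, 0), sqrt(8) * (3 - 2))       # cos coma
  expect_error(zernike_eval(0, 0.5), "noll_index")
  expect_error(zernike_eval(4, 1.5), "rho")
})

test_that("Zernike modes are orthonormal over the unit disc", {
  # Monte-Carlo quadrature over the disc; Noll normalization gives
  # <Z_i, Z_j> = delta_ij under the normalized area measure.
  set.seed(11)
  n <- 2e5
  r <- sqrt(runif(n)); th <- runif(n, 0, 2 * pi)
  js <- c(4, 5, 7, 9, 11)
  Z <- sapply(js, function(j) zernike_eval(j, r, th))
  g <- crossprod(Z) / n
  expect_lt(max(abs(g - diag(length(js)))), 0.02)
})

test_that("optical_config validates its physical invariants", {
  cfg <- optical_config()
  expect_equal(cfg$cutoff, 1.49 / 0.5)
  expect_error(optical_config(numerical_aperture = 1.6, immersion_index = 1.5),
               "immersion_index")
  expect_error(optical_config(psf_grid_size = 30), "odd")
  expect_error(optical_config(pixel_pitch = 0.4), "Nyquist")
  expect_error(zernike_coeffs(c(0.1), 3), "excluded")
  expect_error(zernike_coeffs(c(0.1, 0.2), c(5, 5)), "unique")
})

test_that("the pupil is a unit-modulus phase disc with the stated phase", {
  cfg <- tiny_optics(grid = 15)
  p0 <- build_pupil(cfg)
  expect_true(all(p0$field[!p0$mask] == 0))
  expect_equal(Mod(p0$field[p0$mask]), rep(1, sum(p0$mask)))
  expect_true(all(Im(p0$field[p0$mask]) == 0))  # empty phase -> real indicator
  p1 <- build_pupil(cfg, zernike_coeffs(0.15, 4))
  expect_equal(Mod(p1$field[p1$mask]), rep(1, sum(p1$mask)))
  # phase at the grid center (rho = 0): 2*pi*0.15*Z4(0) = -2*pi*0.15*sqrt(3)
  want <- 2 * pi * 0.15 * (-sqrt(3))
  expect_equal(Arg(p1$field[1, 1]), want, tolerance = 1e-12)
})

test_that("aberration-free PSF is centered, symmetric, unit-sum, band-limited", {
  cfg <- optical_config()
  k <- zernike_psf(cfg)
  expect_equal(sum(k), 1, tolerance = 1e-12)
  expect_true(all(k >= 0))
  ctr <- (cfg$psf_grid_size + 1L) %/% 2L
  expect_equal(which.max(k), (ctr - 1L) * cfg$psf_grid_size + ctr)
  rot90 <- t(apply(k, 2, rev))
  expect_lt(max(abs(k - rot90)) / max(k), 1e-6)
  # direct recomputation: |IFFT(disc indicator)|^2, cropped and normalized
  g <- varblur:::pupil_freq_grid(cfg)
  disc <- (g$fr <= cfg$cutoff) * 1
  amp <- stats::fft(disc, inverse = TRUE) / length(disc)
  ref <- varblur:::fftshift2(Re(amp * Conj(amp)))
  n <- cfg$fft_size; c2 <- (n + 1L) %/% 2L; half <- 15L
  ref <- ref[(c2 - half):(c2 + half), (c2 - half):(c2 + half)]
  ref <- ref / sum(ref)
  expect_lt(max(abs(k - ref)) / max(ref), 1e-12)
  # band limit: OTF of the uncropped kernel vanishes outside 2 f_c
  kf <- zernike_psf(cfg, crop = FALSE)
  Fm <- Mod(stats::fft(kf))
  f1 <- c(0:((n - 1) %/% 2), -((n - 1) %/% 2):-1) / (n * cfg$pixel_pitch)
  fr <- sqrt(outer(f1^2, f1^2, "+"))
  expect_lt(max(Fm[fr > 2 * cfg$cutoff + 1e-9]) / max(Fm), 1e-10)
})

test_that("defocus is an even function of z for the aberration-free pupil", {
  kp <- zernike_psf(optical_config(defocus_z = 0.4))
  km <- zernike_psf(optical_config(defocus_z = -0.4))
  expect_equal(kp, km, tolerance = 1e-12)
  # and defocus actually spreads the PSF
  k0 <- zernike_psf(optical_config())
  expect_gt(max(k0), max(kp))
})

test_that("PSF generation is deterministic and errors on degenerate pupils", {
  cfg <- tiny_optics(grid = 9)
  set.seed(42); c1 <- sample_random_coeffs(4:10, 0.15)
  set.seed(42); c2 <- sample_random_coeffs(4:10, 0.15)
  expect_identical(c1, c2)
  expect_identical(zernike_psf(cfg, c1), zernike_psf(cfg, c2))
  bad <- build_pupil(cfg)
  bad$field[] <- 0
  expect_error(psf_from_pupil(bad, cfg), "degenerate")
})

test_that("random coefficient sampling has uniform moments and bounds", {
  set.seed(7)
  expect_true(all(abs(sample_random_coeffs(4:10, 0.15)$values) <= 0.15))
  expect_identical(sample_random_coeffs(4:8, 0)$values, rep(0, 5))
  n <- 1e5
  set.seed(123)
  pk <- t(replicate(n, sample_random_coeffs(4:5, 0.15)$values))
  se_mean <- 0.15 / sqrt(3 * n)
  expect_lt(max(abs(colMeans(pk))), 3 * se_mean)
  v <- 0.15^2 / 3
  se_var <- v * sqrt(2 / n) * 1.5   # conservative
  expect_lt(max(abs(apply(pk, 2, var) - v)), 3 * se_var)
})
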