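test_that("phantoms stay in [0,1], are reproducible, and non-degenerate", {
  for (kind in c("beads", "filaments", "blobs", "texture", "mixture")) {
    u <- generate_phantom(phantom_spec(kind, size = 48, seed = 7))
    expect_true(min(u) >= 0 && max(u) <= 1)
    expect_gt(stats::sd(u), 0.01)       # usable content for identification
    u2 <- generate_phantom(phantom_spec(kind, size = 48, seed = 7))
    expect_identical(unclass(u), unclass(u2))
  }
  # a spec seed does not disturb the surrounding RNG stream
  set.seed(90); a <- runif(1)
  set.seed(90); invisible(generate_phantom(phantom_spec("blobs", seed = 3)))
  b <- runif(1)
  expect_identical(a, b)
})

test_that("bead counts follow the Poisson density parameter", {
  set.seed(91)
  lambda <- 25
  counts <- replicate(400, {
    u <- generate_phantom(phantom_spec("beads", size = 32, density = lambda))
    attr(u, "count")
  })
  se <- sqrt(lambda / 400)
  expect_lt(abs(mean(counts) - lambda), 3 * se)
})

test_that("synthetic product-convolution families satisfy the contracts", {
  set.seed(92)
  fam <- generate_synthetic_family(p = 4, img_size = 24,
                                   config = tiny_optics(9), n_cloud = 30)
  expect_s3_class(fam, "operator_family")
  V <- matrix(fam$basis$kernels, 81, 4)
  expect_lt(max(abs(crossprod(V) - diag(4))), 1e-10)
  W <- matrix(fam$sv_basis$maps, 24 * 24, 4)
  expect_lt(max(abs(crossprod(W) - diag(4))), 1e-10)
  # PCA residual equals the SVD tail (cloud regenerated with the same seed)
  set.seed(92)
  cloud <- lapply(1:30, function(i)
    zernike_psf(tiny_optics(9), sample_random_coeffs(c_max = 0.15)))
  X <- sapply(cloud, as.vector)
  sv <- svd(X)
  resid <- sum((X - V %*% crossprod(V, X))^2)
  expect_equal(resid, sum(sv$d[5:length(sv$d)]^2), tolerance = 1e-8)
  # p = 1: leading map is constant in sign => family acts like a convolution
  fam1 <- generate_synthetic_family(p = 1, img_size = 16,
                                    config = tiny_optics(7), n_cloud = 10)
  v1 <- fam1$sv_basis$maps[, , 1]
  expect_lt(stats::sd(v1) / abs(mean(v1)), 1e-8)
  op <- family_operator(fam1, 1)
  u <- matrix(runif(256), 16, 16)
  conv_ref <- mean(v1) * varblur:::fft_conv(u, fam1$basis$kernels[, , 1])
  expect_equal(apply_operator(op, u), conv_ref, tolerance = 1e-12)
})

test_that("datasets are written completely and reproducibly", {
  fam <- zernike_family(p = 2, config = tiny_optics(5))
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  man1 <- make_dataset(10, phantom_spec("beads", size = 24), fam,
                       noise_ranges(), margin = 2L, seed = 5, out_dir = d1)
  man2 <- make_dataset(10, phantom_spec("beads", size = 24), fam,
                       noise_ranges(), margin = 2L, seed = 5, out_dir = d2)
  expect_equal(nrow(man1), 10L)
  expect_true(all(file.exists(file.path(d1, man1$clean))))
  expect_true(all(file.exists(file.path(d1, man1$degraded))))
  expect_identical(readLines(file.path(d1, "manifest.jsonl")),
                   readLines(file.path(d2, "manifest.jsonl")))
  # labels within family and noise ranges
  recs <- lapply(readLines(file.path(d1, "manifest.jsonl")),
                 jsonlite::fromJSON)
  for (r in recs) {
    expect_true(all(abs(r$gamma) <= 0.15))
    expect_true(r$eta1 >= 0 && r$eta1 <= 0.01)
    expect_true(r$eta2 >= 0 && r$eta2 <= 0.05)
    expect_equal(r$margin, 2L)
  }
  # degraded images have the cropped size
  b <- read_image_tiff(file.path(d1, recs[[1]]$degraded))
  expect_equal(dim(b), c(20L, 20L))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("label marginals are uniform over the family ranges", {
  set.seed(93)
  fam <- zernike_family(p = 2, config = tiny_optics(5))
  draws <- t(replicate(1e4, sample_operator(fam)$gamma))
  for (j in 1:2) {
    ks <- suppressWarnings(stats::ks.test(draws[, j], "punif", -0.15, 0.15))
    expect_gt(ks$p.value, 0.001)
  }
})
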