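make_test_ops <- function() {
  set.seed(21)
  cfg <- tiny_optics(grid = 5)
  op_z <- blur_operator("zernike_conv", c(0.1, -0.08, 0.05), config = cfg,
                        noll_indices = c(7, 8, 9))
  basis <- random_orthonormal_kernels(5, 3)
  op_e <- blur_operator("eigenpsf_conv", c(0.7, -0.2, 0.4), basis = basis)
  sv <- random_orthonormal_maps(8, 8, 3)
  op_p <- blur_operator("product_conv", c(0.9, 0.3, -0.5), basis = basis,
                        sv_basis = sv)
  list(zernike = op_z, eigen = op_e, product = op_p)
}

test_that("PCA basis is orthonormal and its residual equals the SVD tail", {
  set.seed(22)
  g <- 9; nsamp <- 14; M <- 5
  samples <- array(abs(rnorm(g * g * nsamp)), c(g, g, nsamp))
  basis <- build_basis_pca(samples, M)
  V <- matrix(basis$kernels, g * g, M)
  expect_lt(max(abs(crossprod(V) - diag(M))), 1e-10)
  # oracle: full SVD of the sample matrix
  X <- matrix(samples, g * g, nsamp)
  sv <- svd(X)
  resid <- sum((X - V %*% crossprod(V, X))^2)
  tail <- sum(sv$d[(M + 1):length(sv$d)]^2)
  expect_equal(resid, tail, tolerance = 1e-8)
  expect_equal(attr(basis, "singular_values"), sv$d, tolerance = 1e-10)
  # lossless case: orthonormal samples, M = sample count
  ob <- random_orthonormal_kernels(5, 4)
  b2 <- build_basis_pca(ob$kernels, 4)
  V2 <- matrix(b2$kernels, 25, 4)
  for (m in 1:4) {
    s <- as.vector(ob$kernels[, , m])
    expect_lt(sqrt(sum((s - V2 %*% crossprod(V2, s))^2)), 1e-10)
  }
  expect_error(build_basis_pca(samples, nsamp + 1), "exceeds")
})

test_that("kernel_from_params is the stated linear combination", {
  set.seed(23)
  basis <- random_orthonormal_kernels(7, 4)
  e1 <- basis$kernels[, , 1]
  expect_equal(kernel_from_params(basis, c(1, 0, 0, 0)), e1)
  expect_equal(kernel_from_params(basis, rep(0, 4)), matrix(0, 7, 7))
  g <- rnorm(4)
  k <- kernel_from_params(basis, g)
  expect_equal(sum(k^2), sum(g^2), tolerance = 1e-10)  # Parseval
  expect_error(kernel_from_params(basis, 1:3), "length")
})

test_that("apply/adjoint/normal match dense-matrix oracles on small grids", {
  ops <- make_test_ops()
  dims <- c(8L, 8L)
  for (nm in names(ops)) {
    op <- ops[[nm]]
    A <- dense_matrix(function(d) apply_operator(op, d), dims)
    At <- dense_matrix(function(d) adjoint_operator(op, d), dims)
    expect_lt(max(abs(At - t(A))) / max(abs(A)), 1e-10)
    set.seed(24)
    u <- matrix(runif(64), 8, 8)
    expect_lt(max(abs(apply_operator(op, u) - matrix(A %*% as.vector(u), 8))) /
                max(abs(A %*% as.vector(u))), 1e-10)
    # normal operator
    ntu <- adjoint_operator(op, apply_operator(op, u))
    expect_lt(max(abs(as.vector(ntu) - crossprod(A, A %*% as.vector(u)))) /
                max(abs(ntu)), 1e-10)
  }
})

test_that("circular FFT convolution agrees with direct summation", {
  set.seed(25)
  u <- matrix(runif(100), 10, 10)
  k <- matrix(runif(25), 5, 5)
  expect_equal(varblur:::fft_conv(u, k), direct_circ_conv(u, k),
               tolerance = 1e-12)
})

test_that("duality <Hu, w> = <u, H^T w> holds across variants", {
  ops <- make_test_ops()
  set.seed(26)
  for (i in 1:100) {
    op <- ops[[(i %% 3) + 1]]
    n <- if (op$variant == "product_conv") 8 else 16
    u <- matrix(rnorm(n * n), n, n)
    w <- matrix(rnorm(n * n), n, n)
    lhs <- sum(apply_operator(op, u) * w)
    rhs <- sum(u * adjoint_operator(op, w))
    expect_lt(abs(lhs - rhs) / (sqrt(sum(u^2)) * sqrt(sum(w^2))), 1e-10)
  }
})

test_that("subspace operators are linear in gamma and in the image", {
  set.seed(27)
  basis <- random_orthonormal_kernels(5, 3)
  sv <- random_orthonormal_maps(8, 8, 3)
  g1 <- rnorm(3); g2 <- rnorm(3)
  u <- matrix(runif(64), 8, 8)
  w <- matrix(runif(64), 8, 8)
  for (variant in c("eigenpsf_conv", "product_conv")) {
    mk <- function(g) blur_operator(variant, g, basis = basis,
                                    sv_basis = if (variant == "product_conv") sv)
    expect_equal(apply_operator(mk(g1 + g2), u),
                 apply_operator(mk(g1), u) + apply_operator(mk(g2), u),
                 tolerance = 1e-12)
    op <- mk(g1)
    expect_equal(apply_operator(op, 2 * u - 3 * w),
                 2 * apply_operator(op, u) - 3 * apply_operator(op, w),
                 tolerance = 1e-12)
  }
})

test_that("identity kernel and unit-sum kernels behave as expected", {
  d <- matrix(0, 5, 5); d[3, 3] <- 1
  basis <- eigen_psf_basis(array(d, c(5, 5, 1)))
  op <- blur_operator("eigenpsf_conv", 1, basis = basis)
  set.seed(28)
  u <- matrix(runif(144), 12, 12)
  expect_equal(apply_operator(op, u), u, tolerance = 1e-14)
  # flux preservation for a unit-sum kernel
  opz <- blur_operator("zernike_conv", c(0.1, 0.05), config = tiny_optics(5),
                       noll_indices = c(7, 9))
  expect_equal(mean(apply_operator(opz, u)), mean(u), tolerance = 1e-12)
  # centrally symmetric kernel => self-adjoint convolution
  ksym <- gaussian_like(5)
  bs <- eigen_psf_basis(array(ksym / sqrt(sum(ksym^2)), c(5, 5, 1)))
  ops <- blur_operator("eigenpsf_conv", 1, basis = bs)
  expect_equal(apply_operator(ops, u), adjoint_operator(ops, u),
               tolerance = 1e-12)
})

test_that("local_psf returns the impulse response at a location", {
  ops <- make_test_ops()
  # convolution variants: independent of location
  expect_identical(local_psf(ops$eigen, c(1, 1)), ops$eigen$kernel)
  # product-convolution: H(delta at x) equals local_psf translated to x
  op <- ops$product
  x <- c(5L, 3L)
  resp <- apply_operator(op, delta_image(c(8, 8), x[1], x[2]))
  k <- local_psf(op, x)
  # translate kernel (5x5, centered) to x circularly
  want <- matrix(0, 8, 8)
  for (a in 1:5) for (b in 1:5) {
    i <- ((x[1] + a - 3 - 1) %% 8) + 1
    j <- ((x[2] + b - 3 - 1) %% 8) + 1
    want[i, j] <- k[a, b]
  }
  expect_lt(max(abs(resp - want)), 1e-12)
  expect_error(local_psf(op, c(0, 3)), "outside")
  # gamma = 0 -> zero kernel everywhere
  op0 <- blur_operator("product_conv", rep(0, 3), basis = op$basis,
                       sv_basis = op$sv_basis)
  expect_equal(local_psf(op0, c(2, 2)), matrix(0, 5, 5))
})

test_that("product-convolution with constant maps reduces to convolution", {
  set.seed(29)
  basis <- random_orthonormal_kernels(5, 2)
  const <- 1 / sqrt(64)
  sv <- space_variation_basis(array(c(rep(const, 64), rep(const, 64)),
                                    c(8, 8, 2)), orthonormal = FALSE)
  g <- c(0.8, -0.3)
  opp <- blur_operator("product_conv", g, basis = basis, sv_basis = sv)
  ope <- blur_operator("eigenpsf_conv", g * const, basis = basis)
  u <- matrix(runif(64), 8, 8)
  expect_lt(max(abs(apply_operator(opp, u) - apply_operator(ope, u))), 1e-12)
})

test_that("sample_operator draws within ranges, reproducibly, covering them", {
  fam <- zernike_family(p = 3, c_max = 0.15, config = tiny_optics(5))
  set.seed(30); g1 <- sample_operator(fam)$gamma
  set.seed(30); g2 <- sample_operator(fam)$gamma
  expect_identical(g1, g2)
  expect_true(all(abs(g1) <= 0.15))
  set.seed(31)
  draws <- t(replicate(1e4, stats::runif(fam$p, fam$ranges[, 1],
                                         fam$ranges[, 2])))
  cover <- apply(draws, 2, function(v) diff(range(v))) / 0.30
  expect_true(all(cover >= 0.95))
  expect_true(all(abs(draws) <= 0.15))
})

test_that("basis constructors enforce orthonormality checks", {
  bad <- array(runif(50), c(5, 5, 2))
  expect_error(eigen_psf_basis(bad), "orthonormal")
  expect_silent(eigen_psf_basis(bad, check = FALSE))
  expect_error(space_variation_basis(array(runif(32), c(4, 4, 2))),
               "orthonormal")
})
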