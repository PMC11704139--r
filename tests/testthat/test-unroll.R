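test_that("regularized inverse has its closed-form limits", {
  set.seed(71)
  b <- matrix(runif(64), 8, 8)
  z <- matrix(runif(64), 8, 8)
  H <- identity_op()
  # H = I, sigma = 1: x = (b + z)/2
  expect_equal(regularized_inverse(H, 1, z, b), (b + z) / 2,
               tolerance = 1e-12)
  # dominant regularizer: x -> z
  op <- make_conv_op(invertible_kernel())
  x <- regularized_inverse(op, 1e8, z, b)
  expect_lt(max(abs(x - z)) / max(abs(z)), 1e-6)
})

test_that("CG solution matches the Fourier closed form on convolutions", {
  set.seed(72)
  op <- make_conv_op(invertible_kernel())
  b <- matrix(runif(256), 16, 16)
  z <- matrix(runif(256), 16, 16)
  xf <- regularized_inverse(op, 0.05, z, b, exact_fourier = TRUE)
  xc <- regularized_inverse(op, 0.05, z, b, exact_fourier = FALSE,
                            cg_iters = 200L)
  expect_lt(sqrt(sum((xf - xc)^2)) / sqrt(sum(xf^2)), 1e-6)
})

test_that("init_guess solves the Tikhonov problem within its budget", {
  set.seed(73)
  b <- matrix(runif(64), 8, 8)
  expect_equal(init_guess(identity_op(), b, 0.5, cg_iters = 10),
               b / 1.5, tolerance = 1e-8)
  expect_equal(init_guess(identity_op(), matrix(0, 8, 8), 0.5), matrix(0, 8, 8))
  op <- make_conv_op(invertible_kernel())
  b2 <- matrix(runif(64 * 64), 64, 64)
  x20 <- init_guess(op, b2, 1e-2, cg_iters = 20)
  otf <- varblur:::kernel_otf(op$kernel, dim(b2))
  xf <- Re(varblur:::ifft2(Conj(otf) * varblur:::fft2(b2) /
                           (Mod(otf)^2 + 1e-2)))
  expect_lt(sqrt(sum((x20 - xf)^2)) / sqrt(sum(xf^2)), 1e-3)
})

test_that("identity-prox recursion converges to the least-squares solution", {
  set.seed(74)
  op <- make_conv_op(invertible_kernel(5, 0.3))
  u <- matrix(runif(64), 8, 8)
  b <- apply_operator(op, u)
  A <- dense_matrix(function(d) apply_operator(op, d), c(8L, 8L))
  xls <- matrix(solve(crossprod(A), crossprod(A, as.vector(b))), 8, 8)
  cfg <- solver_config(K = 200L, sigma = 0.5, cg_iters = 30)
  xk <- douglas_rachford_unrolled(b, op, init_prox_network("identity"), cfg)
  expect_lt(sqrt(sum((xk - xls)^2)) / sqrt(sum(xls^2)), 1e-4)
  # H = identity, tiny sigma: exact data fit
  cfg2 <- solver_config(K = 5L, sigma = 1e-10, cg_iters = 30)
  xb <- douglas_rachford_unrolled(b, identity_op(), init_prox_network("identity"),
                                  cfg2)
  expect_lt(max(abs(xb - b)), 1e-8)
})

test_that("the unrolled recursion replicates a dense re-implementation", {
  set.seed(75)
  op <- make_conv_op(invertible_kernel())
  u <- matrix(runif(64), 8, 8)
  b <- apply_operator(op, u) + 0.01 * matrix(rnorm(64), 8, 8)
  sigma <- 0.05; K <- 4L
  # classical Gaussian-smoothing prox: a linear map, dense-replicable
  px <- init_prox_network("classical_denoiser", denoise_sigma = 1)
  A <- dense_matrix(function(d) apply_operator(op, d), c(8L, 8L))
  G <- dense_matrix(function(d) varblur:::fft_conv(d, gaussian_like(7, 1)),
                    c(8L, 8L))
  M <- solve(crossprod(A) + sigma * diag(64))
  # dense replication of init guess (CG converges on this small instance)
  xk <- douglas_rachford_unrolled(b, op, rep(list(px), K),
                                  solver_config(K = K, sigma = sigma,
                                                cg_iters = 100))
  x <- init_guess(op, b, sigma, cg_iters = 100)
  z <- as.vector(x)
  bv <- as.vector(b)
  for (k in seq_len(K)) {
    xv <- M %*% (crossprod(A, bv) + sigma * z)
    if (k < K) z <- z + G %*% (2 * xv - z) - xv
  }
  expect_lt(max(abs(as.vector(xk) - xv)), 1e-10)
})

test_that("quadratic-prox limit recovers the ridge solution", {
  # Prox of g(x) = (lambda*sigma/2)||x||^2 at v is v/(1 + lambda); the
  # K -> infinity limit then solves min 1/2||Hx-b||^2 + (sigma*lambda/2)||x||^2.
  set.seed(76)
  op <- make_conv_op(invertible_kernel())
  b <- apply_operator(op, matrix(runif(64), 8, 8))
  sigma <- 0.2; lambda <- 0.3
  shrink <- function(v) v / (1 + lambda)
  xk <- douglas_rachford_unrolled(b, op, rep(list(shrink), 300),
                                  solver_config(K = 300L, sigma = sigma,
                                                cg_iters = 50))
  otf <- varblur:::kernel_otf(op$kernel, dim(b))
  ridge <- Re(varblur:::ifft2(Conj(otf) * varblur:::fft2(b) /
                              (Mod(otf)^2 + sigma * lambda)))
  expect_lt(sqrt(sum((xk - ridge)^2)) / sqrt(sum(ridge^2)), 1e-6)
})

test_that("prox networks are grid-preserving with finite outputs", {
  set.seed(77)
  x <- matrix(runif(21 * 21), 21, 21)   # odd size exercises the pad path
  for (preset in c("tiny_unet", "drunet_like", "identity",
                   "classical_denoiser")) {
    px <- init_prox_network(preset, seed = 2)
    y <- prox_apply(px, x)
    expect_equal(dim(y), dim(x))
    expect_true(all(is.finite(y)))
  }
  # near-zero-initialized head keeps the untrained prox close to identity
  px <- init_prox_network("tiny_unet", seed = 2)
  expect_lt(max(abs(prox_apply(px, x) - x)), 0.5)
})

test_that("deblurring training runs with true and estimated parameters", {
  set.seed(78)
  fam <- zernike_family(p = 2, config = tiny_optics(7))
  imgs <- lapply(1:4, function(i)
    generate_phantom(phantom_spec("beads", size = 32, density = 10)))
  sc <- solver_config(K = 2L, sigma = 1e-3, cg_iters = 10)
  tc <- train_config(epochs = 1L, batch_size = 2L, seed = 1, margin = 3L)
  pl <- lapply(1:2, function(k) init_prox_network("tiny_unet", seed = k))
  # estimated-parameter route requires an identification model
  expect_error(train_deblurring(pl, NULL, imgs, fam, NULL, tc, sc),
               "identification model")
  m <- init_identification_model(2, "tiny", seed = 1)
  fit_est <- train_deblurring(pl, m, imgs, fam, NULL, tc, sc)
  expect_equal(nrow(fit_est$history), 1L)
  expect_true(is.finite(fit_est$history$loss))
  fit_true <- train_deblurring(pl, NULL, imgs, fam, NULL, tc, sc,
                               use_true_gamma = TRUE)
  expect_true(is.finite(fit_true$history$loss))
  # identity proxes have nothing to train but the loop still reports losses
  plid <- rep(list(init_prox_network("identity")), 2)
  fit_id <- train_deblurring(plid, NULL, imgs, fam, NULL, tc, sc,
                             use_true_gamma = TRUE)
  expect_true(fit_id$history$baseline > 0)
})
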