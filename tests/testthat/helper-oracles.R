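# Shared oracles and fixtures, all built in code.

# A small optical configuration for fast kernels.
tiny_optics <- function(grid = 7L, oversampling = 4L)
  optical_config(psf_grid_size = grid, oversampling = oversampling)

# Assemble the dense matrix of a linear image operator column by column from
# delta inputs.  Independent of the FFT path only in the sense of exercising
# it on the canonical basis; used to check linear-algebra identities
# (adjoint = transpose, normal operator) that the FFT path must satisfy.
dense_matrix <- function(fun, dims) {
  n <- prod(dims)
  A <- matrix(0, n, n)
  for (j in seq_len(n)) {
    d <- matrix(0, dims[1], dims[2])
    d[j] <- 1
    A[, j] <- as.vector(fun(d))
  }
  A
}

# Direct circular convolution by summation (no FFT): independent oracle for
# the Fourier convolution path.
direct_circ_conv <- function(u, k) {
  H <- nrow(u); W <- ncol(u)
  kh <- nrow(k); kw <- ncol(k)
  ci <- kh %/% 2L + 1L; cj <- kw %/% 2L + 1L
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- 0
    for (a in seq_len(kh)) for (b in seq_len(kw)) {
      ii <- ((i - (a - ci) - 1) %% H) + 1
      jj <- ((j - (b - cj) - 1) %% W) + 1
      acc <- acc + k[a, b] * u[ii, jj]
    }
    out[i, j] <- acc
  }
  out
}

# Independent SSIM reference: direct summation over Gaussian windows,
# written without the package's correlation kernel.
reference_ssim <- function(x, y, data_range = 1, sigma = 1.5,
                           win_size = 11L) {
  r <- (win_size - 1L) %/% 2L
  g1 <- exp(-((-r):r)^2 / (2 * sigma^2))
  w <- outer(g1, g1); w <- w / sum(w)
  c1 <- (0.01 * data_range)^2; c2 <- (0.03 * data_range)^2
  H <- nrow(x); W <- ncol(x)
  vals <- c()
  for (i in seq_len(H - win_size + 1L)) for (j in seq_len(W - win_size + 1L)) {
    px <- x[i:(i + win_size - 1L), j:(j + win_size - 1L)]
    py <- y[i:(i + win_size - 1L), j:(j + win_size - 1L)]
    mx <- sum(w * px); my <- sum(w * py)
    vx <- sum(w * px^2) - mx^2; vy <- sum(w * py^2) - my^2
    cxy <- sum(w * px * py) - mx * my
    vals <- c(vals, ((2 * mx * my + c1) * (2 * cxy + c2)) /
                    ((mx^2 + my^2 + c1) * (vx + vy + c2)))
  }
  mean(vals)
}

# A deliberately well-conditioned small convolution kernel (delta plus mild
# smoothing): its OTF is bounded away from zero, so H is invertible.
invertible_kernel <- function(size = 5L, mix = 0.35) {
  g <- gaussian_like(size)
  d <- matrix(0, size, size)
  d[size %/% 2L + 1L, size %/% 2L + 1L] <- 1
  k <- (1 - mix) * d + mix * g
  k / sum(k)
}

gaussian_like <- function(size, sigma = 1) {
  r <- (size - 1L) %/% 2L
  g1 <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- outer(g1, g1)
  k / sum(k)
}

# Orthonormal kernel family on a g x g grid (QR of random matrices).
random_orthonormal_kernels <- function(g, M) {
  q <- qr.Q(qr(matrix(stats::rnorm(g * g * M), g * g, M)))
  eigen_psf_basis(array(q, c(g, g, M)))
}

# Wrap a single kernel as a space-invariant blur operator.
make_conv_op <- function(kernel) {
  k <- kernel / sqrt(sum(kernel^2))
  blur_operator("eigenpsf_conv", sqrt(sum(kernel^2)),
                basis = eigen_psf_basis(array(k, c(dim(kernel), 1))))
}

identity_op <- function(size = 3L) {
  d <- matrix(0, size, size); d[size %/% 2L + 1L, size %/% 2L + 1L] <- 1
  make_conv_op(d)
}

delta_image <- function(dims, i, j) {
  d <- matrix(0, dims[1], dims[2]); d[i, j] <- 1; d
}

random_orthonormal_maps <- function(h, w, M) {
  q <- qr.Q(qr(matrix(stats::rnorm(h * w * M), h * w, M)))
  space_variation_basis(array(q, c(h, w, M)))
}
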