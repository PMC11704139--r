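# Internal FFT helpers: circular 2D convolution with a centered kernel.
# Kernel center convention: index floor(size/2) + 1 (1-based) in each axis,
# i.e. the middle pixel for odd sizes.

kernel_center <- function(n) as.integer(n) %/% 2L + 1L

# Embed a centered kernel into an H x W zero matrix so that its center pixel
# lands on [1,1] (circularly); the FFT of the result is the transfer function.
pad_kernel <- function(k, dims) {
  kh <- nrow(k); kw <- ncol(k)
  if (kh > dims[1] || kw > dims[2])
    stop("kernel larger than the image grid")
  p <- matrix(0, dims[1], dims[2])
  ci <- kernel_center(kh); cj <- kernel_center(kw)
  ri <- ((seq_len(kh) - ci) %% dims[1]) + 1L
  rj <- ((seq_len(kw) - cj) %% dims[2]) + 1L
  p[ri, rj] <- k
  p
}

# Transfer function (OTF) of a centered kernel on an H x W grid.
kernel_otf <- function(k, dims) stats::fft(pad_kernel(k, dims))

fft2 <- function(x) stats::fft(x)
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# Circular convolution u * k (kernel centered).
fft_conv <- function(u, k, otf = NULL) {
  if (is.null(otf)) otf <- kernel_otf(k, dim(u))
  Re(ifft2(fft2(u) * otf))
}

# Adjoint of circular convolution: correlation, i.e. convolution with the
# coordinate-reversed kernel; conj(OTF) in Fourier.
fft_corr <- function(u, k, otf = NULL) {
  if (is.null(otf)) otf <- kernel_otf(k, dim(u))
  Re(ifft2(fft2(u) * Conj(otf)))
}

# Discrete delta image with a 1 at (i, j).
delta_image <- function(dims, i, j) {
  d <- matrix(0, dims[1], dims[2]); d[i, j] <- 1; d
}
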