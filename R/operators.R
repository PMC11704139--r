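#' Orthonormal eigen-PSF basis
#'
#' A family of M convolution kernels, pairwise orthonormal under the
#' Euclidean inner product, spanning a low-dimensional subspace of point
#' spread functions.  Typically obtained with \code{\link{build_basis_pca}}.
#'
#' @param kernels A (kh, kw, M) array, or a list of equally sized matrices.
#' @param check If \code{TRUE}, verify orthonormality (Gram matrix equal to
#'   the identity within 1e-10).
#' @return Object of class \code{eigen_psf_basis}.
#' @export
eigen_psf_basis <- function(kernels, check = TRUE) {
  if (is.list(kernels)) {
    d <- dim(kernels[[1]])
    kernels <- array(unlist(kernels), c(d, length(kernels)))
  }
  stopifnot(length(dim(kernels)) == 3)
  if (check) {
    v <- matrix(kernels, prod(dim(kernels)[1:2]), dim(kernels)[3])
    g <- crossprod(v)
    if (max(abs(g - diag(ncol(v)))) > 1e-10)
      stop("kernels are not orthonormal (Gram deviation > 1e-10)")
  }
  structure(list(kernels = kernels, M = dim(kernels)[3]),
            class = "eigen_psf_basis")
}

#' Eigen space-variation basis
#'
#' M weight maps on the image grid describing how the impulse response varies
#' across the field of view in a product-convolution expansion.
#'
#' @param maps A (H, W, M) array or list of matrices.
#' @param orthonormal If \code{TRUE} (default), verify pairwise orthonormality
#'   of the maps; set to \code{FALSE} to flag a deliberately
#'   non-orthogonalized family (e.g. a constant map plus modulations).
#' @return Object of class \code{space_variation_basis}.
#' @export
space_variation_basis <- function(maps, orthonormal = TRUE) {
  if (is.list(maps)) {
    d <- dim(maps[[1]])
    maps <- array(unlist(maps), c(d, length(maps)))
  }
  stopifnot(length(dim(maps)) == 3)
  if (orthonormal) {
    v <- matrix(maps, prod(dim(maps)[1:2]), dim(maps)[3])
    g <- crossprod(v)
    if (max(abs(g - diag(ncol(v)))) > 1e-10)
      stop("maps are not orthonormal; pass orthonormal = FALSE to flag this")
  }
  structure(list(maps = maps, M = dim(maps)[3], orthonormal = orthonormal),
            class = "space_variation_basis")
}

#' Principal-component basis of a PSF family
#'
#' Computes the top-M principal directions of a family of observed or
#' theoretical PSFs by singular value decomposition, yielding an orthonormal
#' eigen-PSF basis ordered by decreasing singular value.  By default the
#' samples are not centered: PSFs are nonnegative and their mean carries the
#' dominant diffraction pattern, which belongs in the basis.
#'
#' @param psf_samples List of kernels, or a (kh, kw, n) array.
#' @param M Number of basis elements to keep (<= number of samples).
#' @param center If \code{TRUE}, subtract the sample mean first (returned as
#'   attribute \code{"mean"}).
#' @return An \code{\link{eigen_psf_basis}} with attribute
#'   \code{"singular_values"} (all of them, for residual bookkeeping).
#' @export
build_basis_pca <- function(psf_samples, M, center = FALSE) {
  if (is.list(psf_samples)) {
    d <- dim(psf_samples[[1]])
    psf_samples <- array(unlist(psf_samples), c(d, length(psf_samples)))
  }
  d <- dim(psf_samples)
  n <- d[3]
  if (M > n) stop("M exceeds the number of PSF samples")
  x <- matrix(psf_samples, d[1] * d[2], n)   # columns = samples
  mu <- NULL
  if (center) {
    mu <- rowMeans(x)
    x <- x - mu
  }
  sv <- svd(x, nu = M, nv = 0)
  basis <- eigen_psf_basis(array(sv$u, c(d[1], d[2], M)), check = FALSE)
  attr(basis, "singular_values") <- sv$d
  if (center) attr(basis, "mean") <- matrix(mu, d[1], d[2])
  basis
}

#' Kernel from subspace coordinates
#'
#' Linear combination \eqn{k = \sum_m \gamma_m e_m} of the eigen-PSF basis.
#'
#' @param basis An \code{\link{eigen_psf_basis}}.
#' @param gamma Numeric vector of length \code{basis$M}.
#' @return A kernel matrix.
#' @export
kernel_from_params <- function(basis, gamma) {
  stopifnot(inherits(basis, "eigen_psf_basis"))
  if (length(gamma) != basis$M)
    stop("gamma must have length ", basis$M)
  d <- dim(basis$kernels)
  matrix(matrix(basis$kernels, d[1] * d[2], d[3]) %*% gamma, d[1], d[2])
}

#' Parameterized blur operator
#'
#' A linear operator \eqn{H(\gamma)} acting on images, from one of three
#' low-dimensional families:
#' \describe{
#'   \item{\code{zernike_conv}}{space-invariant convolution whose kernel is
#'     the diffraction PSF generated by Zernike pupil coefficients
#'     \eqn{\gamma} (see \code{\link{zernike_psf}});}
#'   \item{\code{eigenpsf_conv}}{space-invariant convolution with kernel
#'     \eqn{\sum_m \gamma_m e_m} in an eigen-PSF basis;}
#'   \item{\code{product_conv}}{space-varying product-convolution operator
#'     \eqn{H(\gamma) u = \sum_m \gamma_m\, e_m \star (v_m \odot u)} with
#'     eigen-PSF kernels \eqn{e_m} and space-variation maps \eqn{v_m}.}
#' }
#' All convolutions are circular, so that operators diagonalize exactly in
#' Fourier space and adjoints are exact.
#'
#' @param variant One of \code{"zernike_conv"}, \code{"eigenpsf_conv"},
#'   \code{"product_conv"}.
#' @param gamma Parameter vector.
#' @param config \code{\link{optical_config}} (zernike_conv only).
#' @param noll_indices Noll indices paired with \code{gamma}
#'   (zernike_conv only; default 4, 5, 6, ...).
#' @param basis \code{\link{eigen_psf_basis}} (eigenpsf_conv, product_conv).
#' @param sv_basis \code{\link{space_variation_basis}} (product_conv only).
#' @return Object of class \code{blur_operator}.
#' @export
blur_operator <- function(variant = c("zernike_conv", "eigenpsf_conv",
                                      "product_conv"),
                          gamma, config = NULL, noll_indices = NULL,
                          basis = NULL, sv_basis = NULL) {
  variant <- match.arg(variant)
  gamma <- as.numeric(gamma)
  if (any(!is.finite(gamma))) stop("gamma must be finite")
  op <- list(variant = variant, gamma = gamma, boundary = "circular")
  if (variant == "zernike_conv") {
    stopifnot(inherits(config, "optical_config"))
    if (is.null(noll_indices)) noll_indices <- seq(4L, length.out = length(gamma))
    op$config <- config
    op$noll_indices <- as.integer(noll_indices)
    op$kernel <- zernike_psf(config, zernike_coeffs(gamma, op$noll_indices))
  } else if (variant == "eigenpsf_conv") {
    stopifnot(inherits(basis, "eigen_psf_basis"))
    op$basis <- basis
    op$kernel <- kernel_from_params(basis, gamma)
  } else {
    stopifnot(inherits(basis, "eigen_psf_basis"),
              inherits(sv_basis, "space_variation_basis"))
    if (basis$M != sv_basis$M)
      stop("eigen-PSF and space-variation bases must have the same size M")
    if (length(gamma) != basis$M)
      stop("gamma must have length ", basis$M)
    op$basis <- basis
    op$sv_basis <- sv_basis
    op$img_dim <- dim(sv_basis$maps)[1:2]
  }
  structure(op, class = "blur_operator")
}

#' @export
print.blur_operator <- function(x, ...) {
  cat(sprintf("<blur_operator: %s, p = %d>\n", x$variant, length(x$gamma)))
  invisible(x)
}

is_conv_variant <- function(op) op$variant %in% c("zernike_conv", "eigenpsf_conv")

#' Apply a blur operator to an image
#'
#' Convolution variants compute the circular convolution \eqn{k \star u};
#' the product-convolution variant computes
#' \eqn{\sum_m \gamma_m\, e_m \star (v_m \odot u)} where \eqn{\odot} is the
#' pointwise (Hadamard) product.
#'
#' @param op A \code{\link{blur_operator}}.
#' @param u Image matrix on the operator's grid.
#' @return Blurred image, same size as \code{u}.
#' @export
apply_operator <- function(op, u) {
  stopifnot(inherits(op, "blur_operator"), is.matrix(u))
  if (is_conv_variant(op)) {
    return(fft_conv(u, op$kernel))
  }
  if (!identical(dim(u), as.integer(op$img_dim)) &&
      !identical(as.integer(dim(u)), as.integer(op$img_dim)))
    stop("image grid does not match the operator's space-variation maps")
  out <- matrix(0, nrow(u), ncol(u))
  for (m in seq_len(op$basis$M)) {
    if (op$gamma[m] == 0) next
    out <- out + op$gamma[m] *
      fft_conv(op$sv_basis$maps[, , m] * u, op$basis$kernels[, , m])
  }
  out
}

#' Apply the adjoint of a blur operator
#'
#' Exact adjoint of \code{\link{apply_operator}} under the Euclidean inner
#' product: convolution variants correlate with the kernel (coordinate
#' reversal), and the product-convolution adjoint is
#' \eqn{H^T w = \sum_m \gamma_m\, v_m \odot (\tilde e_m \star w)}.
#'
#' @param op A \code{\link{blur_operator}}.
#' @param w Image matrix on the operator's grid.
#' @return Image matrix, same size as \code{w}.
#' @export
adjoint_operator <- function(op, w) {
  stopifnot(inherits(op, "blur_operator"), is.matrix(w))
  if (is_conv_variant(op)) {
    return(fft_corr(w, op$kernel))
  }
  if (!identical(as.integer(dim(w)), as.integer(op$img_dim)))
    stop("image grid does not match the operator's space-variation maps")
  out <- matrix(0, nrow(w), ncol(w))
  for (m in seq_len(op$basis$M)) {
    if (op$gamma[m] == 0) next
    out <- out + op$gamma[m] *
      op$sv_basis$maps[, , m] * fft_corr(w, op$basis$kernels[, , m])
  }
  out
}

#' Local impulse response of a blur operator
#'
#' Returns the PSF at image location \code{x}: for convolution variants it is
#' the (space-invariant) kernel; for product-convolution it is
#' \eqn{\sum_m \gamma_m v_m(x)\, e_m}.
#'
#' @param op A \code{\link{blur_operator}}.
#' @param x Integer location \code{c(row, col)}, 1-based, inside the grid.
#' @return Kernel matrix.
#' @export
local_psf <- function(op, x) {
  stopifnot(inherits(op, "blur_operator"))
  if (is_conv_variant(op)) return(op$kernel)
  x <- as.integer(x)
  if (length(x) != 2 || any(x < 1L) || any(x > op$img_dim))
    stop("location x is outside the image grid")
  w <- op$gamma * op$sv_basis$maps[x[1], x[2], ]
  kernel_from_params(op$basis, w)
}

#' Operator family definition
#'
#' Describes a distribution over blur operators: the variant, the supporting
#' data (optics configuration or bases) and per-coordinate uniform ranges for
#' the parameter vector \eqn{\gamma}.
#'
#' @param variant Operator variant (see \code{\link{blur_operator}}).
#' @param ranges A p x 2 matrix of per-coordinate lower/upper bounds, or a
#'   single \code{c(lo, hi)} recycled to all coordinates of dimension
#'   \code{p}.
#' @param p Parameter dimension (required when \code{ranges} is length 2).
#' @param config,noll_indices,basis,sv_basis Family data, as in
#'   \code{\link{blur_operator}}.
#' @return Object of class \code{operator_family}.
#' @export
operator_family <- function(variant = c("zernike_conv", "eigenpsf_conv",
                                        "product_conv"),
                            ranges, p = NULL, config = NULL,
                            noll_indices = NULL, basis = NULL,
                            sv_basis = NULL) {
  variant <- match.arg(variant)
  if (is.null(dim(ranges))) {
    stopifnot(length(ranges) == 2, !is.null(p))
    ranges <- matrix(rep(as.numeric(ranges), each = p), p, 2)
  }
  ranges <- as.matrix(ranges)
  if (ncol(ranges) != 2 || any(ranges[, 2] < ranges[, 1]))
    stop("ranges must be a p x 2 matrix with lower <= upper")
  p <- nrow(ranges)
  if (variant == "zernike_conv") {
    stopifnot(inherits(config, "optical_config"))
    if (is.null(noll_indices)) noll_indices <- seq(4L, length.out = p)
  } else {
    stopifnot(inherits(basis, "eigen_psf_basis"), basis$M == p)
    if (variant == "product_conv")
      stopifnot(inherits(sv_basis, "space_variation_basis"))
  }
  structure(list(variant = variant, ranges = ranges, p = p, config = config,
                 noll_indices = noll_indices, basis = basis,
                 sv_basis = sv_basis),
            class = "operator_family")
}

#' Instantiate an operator from a family at given parameters
#'
#' @param family An \code{\link{operator_family}}.
#' @param gamma Parameter vector of length \code{family$p}.
#' @return A \code{\link{blur_operator}}.
#' @export
family_operator <- function(family, gamma) {
  stopifnot(inherits(family, "operator_family"))
  blur_operator(family$variant, gamma, config = family$config,
                noll_indices = family$noll_indices, basis = family$basis,
                sv_basis = family$sv_basis)
}

#' Draw a random operator from a family
#'
#' Samples \eqn{\gamma} from the product-uniform distribution over the
#' family's per-coordinate ranges and instantiates the operator.  Uses the
#' current R random number generator state.
#'
#' @param family An \code{\link{operator_family}}.
#' @return A \code{\link{blur_operator}}.
#' @export
sample_operator <- function(family) {
  stopifnot(inherits(family, "operator_family"))
  gamma <- stats::runif(family$p, family$ranges[, 1], family$ranges[, 2])
  family_operator(family, gamma)
}
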