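#' Optical configuration of the imaging model
#'
#' Collects the physical constants of the scalar-diffraction imaging model:
#' emission wavelength, numerical aperture, refractive index of the immersion
#' medium, camera pixel pitch, the size of the kernel grid on which point
#' spread functions (PSFs) are returned, and the axial position of the
#' observed slice.  The defaults are representative of a high-NA oil
#' immersion objective (x100 / NA 1.49).
#'
#' The cutoff frequency of the incoherent system is \eqn{f_c = NA/\lambda};
#' the configuration is only valid when the pupil disc fits inside the
#' discrete frequency plane, i.e. \eqn{1/(2\,\mathrm{pitch}) \ge f_c}.
#'
#' @param wavelength Emission wavelength, in micrometers.
#' @param numerical_aperture Numerical aperture (dimensionless, > 0).
#' @param immersion_index Refractive index of the immersion medium
#'   (>= 1, and >= \code{numerical_aperture}).
#' @param pixel_pitch Object-space pixel size, in micrometers per pixel.
#' @param psf_grid_size Odd integer; side length (pixels) of returned PSF
#'   kernels, so that the kernel has an unambiguous center pixel.
#' @param defocus_z Axial coordinate of the observed slice, in micrometers.
#' @param oversampling Integer >= 1; the pupil is sampled on a frequency grid
#'   of side \code{oversampling * psf_grid_size + 1} (odd, hence symmetric)
#'   before the PSF is cropped to \code{psf_grid_size}.
#' @return An object of class \code{optical_config}.
#' @examples
#' cfg <- optical_config()
#' cfg$cutoff   # NA / lambda, cycles per micrometer
#' @export
optical_config <- function(wavelength = 0.5, numerical_aperture = 1.49,
                           immersion_index = 1.515, pixel_pitch = 0.065,
                           psf_grid_size = 31L, defocus_z = 0,
                           oversampling = 4L) {
  stopifnot(wavelength > 0, numerical_aperture > 0, immersion_index >= 1)
  if (numerical_aperture > immersion_index)
    stop("numerical_aperture must not exceed immersion_index")
  psf_grid_size <- as.integer(psf_grid_size)
  if (psf_grid_size < 3L || psf_grid_size %% 2L == 0L)
    stop("psf_grid_size must be an odd integer >= 3")
  oversampling <- as.integer(oversampling)
  stopifnot(oversampling >= 1L)
  fc <- numerical_aperture / wavelength
  if (1 / (2 * pixel_pitch) < fc)
    stop("Nyquist violation: 1/(2*pixel_pitch) < cutoff frequency NA/lambda; ",
         "decrease pixel_pitch or the aperture")
  structure(list(
    wavelength = wavelength,
    numerical_aperture = numerical_aperture,
    immersion_index = immersion_index,
    pixel_pitch = pixel_pitch,
    psf_grid_size = psf_grid_size,
    defocus_z = defocus_z,
    oversampling = oversampling,
    fft_size = {
      n <- oversampling * psf_grid_size
      if (n %% 2L == 0L) n + 1L else n  # odd: every frequency has a negative twin
    },
    cutoff = fc
  ), class = "optical_config")
}

#' @export
print.optical_config <- function(x, ...) {
  cat("<optical_config>\n")
  cat(sprintf("  lambda = %g um, NA = %g, n_i = %g (f_c = %.3f /um)\n",
              x$wavelength, x$numerical_aperture, x$immersion_index, x$cutoff))
  cat(sprintf("  pixel pitch = %g um, PSF grid %dx%d (pupil grid %d), z = %g um\n",
              x$pixel_pitch, x$psf_grid_size, x$psf_grid_size,
              x$fft_size, x$defocus_z))
  invisible(x)
}

# Noll index -> (n, m) with Noll's sign/ordering convention.
noll_to_nm <- function(j) {
  stopifnot(j >= 1)
  n <- 0L
  while ((n + 1L) * (n + 2L) / 2L < j) n <- n + 1L
  s <- j - n * (n + 1L) / 2L            # 1-based position inside the order
  m_abs <- if (n %% 2L == 0L) 2L * (s %/% 2L) else 2L * ((s - 1L) %/% 2L) + 1L
  m <- if (m_abs == 0L) 0L else if (j %% 2L == 0L) m_abs else -m_abs
  c(n = n, m = m)
}

#' Evaluate a Noll-normalized Zernike polynomial
#'
#' Zernike polynomials form an orthogonal basis on the unit disc and are the
#' standard expansion of pupil-phase aberrations.  Noll's single-index scheme
#' is used (4 = defocus, 5--6 = primary astigmatism, 7--8 = coma,
#' 9--10 = trefoil, 11 = primary spherical), with Noll normalization
#' (\eqn{\sqrt{n+1}} for m = 0, \eqn{\sqrt{2(n+1)}} otherwise) and the usual
#' convention that even indices carry \eqn{\cos(m\theta)} and odd indices
#' \eqn{\sin(m\theta)}.
#'
#' @param noll_index Integer >= 1 (single index per mode).
#' @param rho Radial coordinate(s) in [0, 1].
#' @param theta Azimuthal angle(s), radians.  Recycled against \code{rho}.
#' @return Numeric vector of polynomial values.
#' @examples
#' zernike_eval(4, 1, 0)        # sqrt(3) * (2*1 - 1)
#' zernike_eval(11, 0, 0)       # sqrt(5)
#' @export
zernike_eval <- function(noll_index, rho, theta = 0) {
  if (length(noll_index) != 1L || noll_index < 1)
    stop("noll_index must be a single integer >= 1")
  if (any(rho < -1e-12 | rho > 1 + 1e-12))
    stop("rho must lie in [0, 1]")
  rho <- pmin(pmax(rho, 0), 1)
  nm <- noll_to_nm(as.integer(noll_index))
  n <- nm[["n"]]; m <- nm[["m"]]; ma <- abs(m)
  radial <- numeric(length(rho))
  for (k in 0:((n - ma) %/% 2)) {
    coef <- (-1)^k * factorial(n - k) /
      (factorial(k) * factorial((n + ma) / 2 - k) * factorial((n - ma) / 2 - k))
    radial <- radial + coef * rho^(n - 2 * k)
  }
  norm <- if (ma == 0L) sqrt(n + 1) else sqrt(2 * (n + 1))
  ang <- if (m > 0L) cos(ma * theta) else if (m < 0L) sin(ma * theta) else 1
  norm * radial * ang
}

#' Zernike phase coefficients
#'
#' A set of pupil-phase coefficients expressed in waves (one wave of a mode
#' adds a phase excursion of \eqn{2\pi} times that polynomial across the
#' pupil).  Piston, tip and tilt (Noll 1--3) are excluded because they do not
#' change the shape of the PSF.
#'
#' @param values Numeric coefficients, in waves.
#' @param noll_indices Integer Noll indices, all >= 4, unique, same length as
#'   \code{values}.  Defaults to 4:10 (defocus, astigmatisms, comas,
#'   trefoils).
#' @return Object of class \code{zernike_coeffs}.
#' @export
zernike_coeffs <- function(values, noll_indices = seq(4L, length.out = length(values))) {
  noll_indices <- as.integer(noll_indices)
  if (length(values) != length(noll_indices))
    stop("values and noll_indices must have the same length")
  if (any(noll_indices < 4L))
    stop("piston, tip and tilt (Noll 1-3) are excluded: indices must be >= 4")
  if (anyDuplicated(noll_indices))
    stop("noll_indices must be unique")
  structure(list(values = as.numeric(values), noll_indices = noll_indices),
            class = "zernike_coeffs")
}

#' Draw random Zernike coefficients
#'
#' Each coefficient is drawn independently and uniformly on
#' \eqn{[-c_{max}, c_{max}]} (waves), the sampling distribution used to
#' generate training operators.  Uses the current R random number generator
#' state; call \code{set.seed()} beforehand for reproducibility.
#'
#' @param noll_indices Integer Noll indices (>= 4).
#' @param c_max Amplitude bound (>= 0); the default 0.15 gives a rich but
#'   physically plausible variety of aberrated PSFs.
#' @return A \code{zernike_coeffs} object.
#' @export
sample_random_coeffs <- function(noll_indices = 4:10, c_max = 0.15) {
  stopifnot(c_max >= 0)
  zernike_coeffs(stats::runif(length(noll_indices), -c_max, c_max),
                 noll_indices)
}

# Frequency grids for the pupil plane (cycles per micrometer), FFT layout
# (zero frequency in the [1,1] corner).  N is odd so every frequency has its
# negative counterpart on the grid.
pupil_freq_grid <- function(config) {
  n <- config$fft_size
  f1 <- c(0:((n - 1) %/% 2), -((n - 1) %/% 2):-1) / (n * config$pixel_pitch)
  fx <- matrix(f1, n, n, byrow = TRUE)   # frequency along image columns
  fy <- matrix(f1, n, n)                 # frequency along image rows
  list(fx = fx, fy = fy, fr = sqrt(fx^2 + fy^2))
}

# Zernike polynomial values on a pupil grid depend only on the grid geometry
# and the mode index, not on the coefficients; they are evaluated once per
# (configuration, index) pair and cached, which makes repeated PSF sampling
# from a family cheap.
.zernike_grid_cache <- new.env(parent = emptyenv())

zernike_grid_stack <- function(config, noll_indices) {
  key <- paste(config$fft_size, config$pixel_pitch, config$cutoff,
               paste(noll_indices, collapse = ","), sep = "|")
  hit <- .zernike_grid_cache[[key]]
  if (!is.null(hit)) return(hit)
  g <- pupil_freq_grid(config)
  rho <- pmin(g$fr / config$cutoff, 1)
  theta <- atan2(g$fy, g$fx)
  stack <- vapply(noll_indices, function(j)
    zernike_eval(j, rho, theta), matrix(0, nrow(rho), ncol(rho)))
  .zernike_grid_cache[[key]] <- stack
  stack
}

#' Build the complex pupil function
#'
#' Constructs the pure-phase pupil
#' \deqn{\rho(f) = 1_{\{\|f\| \le f_c\}} \exp\left(2\pi i \sum_j c_j
#'   Z_j(\|f\|/f_c, \angle f)\right)}
#' on the discrete frequency grid of \code{config}.  Real coefficients give a
#' unit-modulus pupil on its support and zero outside.
#'
#' @param config An \code{\link{optical_config}}.
#' @param coeffs A \code{\link{zernike_coeffs}} object (or \code{NULL} for an
#'   aberration-free pupil).
#' @return Object of class \code{pupil_function}: list with the complex
#'   \code{field} (FFT layout, zero frequency at [1,1]), the logical support
#'   \code{mask}, and the generating \code{config}.
#' @export
build_pupil <- function(config, coeffs = NULL) {
  stopifnot(inherits(config, "optical_config"))
  g <- pupil_freq_grid(config)
  mask <- g$fr <= config$cutoff
  phase <- matrix(0, nrow(mask), ncol(mask))
  if (!is.null(coeffs)) {
    stopifnot(inherits(coeffs, "zernike_coeffs"))
    Z <- zernike_grid_stack(config, coeffs$noll_indices)
    n <- config$fft_size
    phase <- matrix(matrix(Z, n * n, length(coeffs$values)) %*%
                      coeffs$values, n, n)
  }
  field <- matrix(0i, nrow(mask), ncol(mask))
  field[mask] <- exp(2i * pi * phase[mask])
  structure(list(field = field, mask = mask, config = config),
            class = "pupil_function")
}

#' Point spread function from a pupil function
#'
#' Scalar (Fresnel/Fraunhofer) diffraction model of the incoherent PSF: the
#' kernel is the squared modulus of the inverse Fourier transform of the
#' pupil, multiplied by the axial propagation factor
#' \eqn{\exp(2\pi i z \sqrt{(n_i/\lambda)^2 - \|f\|^2})} evaluated at
#' \code{config$defocus_z}.  The result is centered (zero frequency at the
#' central pixel), optionally cropped to \code{psf_grid_size}, and normalized
#' to unit sum so that blurring preserves total flux.
#'
#' @param pupil A \code{\link{build_pupil}} result.
#' @param config Optical configuration; defaults to the one stored in
#'   \code{pupil}.
#' @param crop If \code{TRUE} (default) crop the kernel to
#'   \code{psf_grid_size}; if \code{FALSE} return the full oversampled grid
#'   (useful to inspect the exact band limit of the optical transfer
#'   function).
#' @return A numeric matrix (nonnegative, unit sum) of class \code{psf_kernel}.
#' @export
psf_from_pupil <- function(pupil, config = pupil$config, crop = TRUE) {
  stopifnot(inherits(pupil, "pupil_function"))
  if (!identical(dim(pupil$field), c(config$fft_size, config$fft_size)))
    stop("pupil grid does not match the configuration")
  if (all(pupil$field == 0))
    stop("degenerate PSF: the pupil function is identically zero")
  field <- pupil$field
  if (config$defocus_z != 0) {
    g <- pupil_freq_grid(config)
    kz <- sqrt(pmax((config$immersion_index / config$wavelength)^2 - g$fr^2, 0))
    field <- field * exp(2i * pi * config$defocus_z * kz)
  }
  amp <- stats::fft(field, inverse = TRUE) / length(field)
  psf <- Re(amp * Conj(amp))
  psf <- fftshift2(psf)
  if (crop) {
    n <- config$fft_size
    ctr <- if (n %% 2L == 1L) (n + 1L) %/% 2L else n %/% 2L + 1L
    half <- (config$psf_grid_size - 1L) %/% 2L
    idx <- (ctr - half):(ctr + half)
    psf <- psf[idx, idx]
  }
  psf <- psf / sum(psf)
  class(psf) <- c("psf_kernel", class(psf))
  psf
}

#' Generate a Zernike-aberrated PSF in one call
#'
#' Convenience wrapper chaining \code{\link{build_pupil}} and
#' \code{\link{psf_from_pupil}}.
#'
#' @inheritParams build_pupil
#' @inheritParams psf_from_pupil
#' @return A \code{psf_kernel} matrix.
#' @examples
#' cfg <- optical_config(psf_grid_size = 15)
#' k <- zernike_psf(cfg, zernike_coeffs(c(0.1, 0, 0.05)))
#' sum(k)  # 1
#' @export
zernike_psf <- function(config, coeffs = NULL, crop = TRUE) {
  psf_from_pupil(build_pupil(config, coeffs), config, crop = crop)
}

# Exact reflection symmetries of Zernike-generated kernels: reflecting the
# kernel about the vertical or horizontal image axis multiplies each pupil
# coefficient by a sign determined by the mode's azimuthal structure
# (cos(m.) modes pick up (-1)^m under theta -> pi - theta, sin(m.) modes
# -(-1)^m; under theta -> -theta, cos modes are invariant and sin modes
# negate).  Together with the conjugation symmetry (full sign flip = 180
# degree rotation) these give a 4-element group of label-equivariant image
# transforms, used for training augmentation and test-time averaging.
zernike_flip_signs <- function(noll_indices, axis = c("h", "v")) {
  axis <- match.arg(axis)
  vapply(noll_indices, function(j) {
    nm <- noll_to_nm(j)
    m <- nm[["m"]]
    if (axis == "v") {                  # theta -> -theta (rows reversed)
      if (m < 0) -1 else 1
    } else {                            # theta -> pi - theta (cols reversed)
      if (m > 0) (-1)^m else if (m < 0) -(-1)^(-m) else 1
    }
  }, numeric(1))
}

# Shift zero-frequency (index [1,1]) to the central pixel.
fftshift2 <- function(x) {
  n1 <- nrow(x); n2 <- ncol(x)
  s1 <- n1 %/% 2L; s2 <- n2 %/% 2L
  x[c((n1 - s1 + 1L):n1, 1L:(n1 - s1)), c((n2 - s2 + 1L):n2, 1L:(n2 - s2))]
}
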