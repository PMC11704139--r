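#' Phantom specification
#'
#' Describes a synthetic grayscale test image.  The phantom classes span the
#' content regimes relevant for blur identification: sparse point sources
#' (beads), elongated curvilinear structures (filaments), piecewise-smooth
#' regions (blobs) and band-limited textures, plus a mixture class.
#'
#' @param kind One of \code{"beads"}, \code{"filaments"}, \code{"blobs"},
#'   \code{"texture"}, \code{"mixture"}.
#' @param size Image side length (pixels).
#' @param density Expected bead count per image (beads/mixture).
#' @param bead_sigma Length-2 range of bead Gaussian radii in pixels.
#'   Calibration beads are manufactured monodisperse and sub-resolution, so
#'   the default is a tight range around one pixel; widen it to emulate
#'   heterogeneous particles.
#' @param n_filaments Number of random-walk filaments.
#' @param blob_sigma Smoothing scale (pixels) of the blob field.
#' @param texture_cutoff Band limit of the texture, as a fraction of Nyquist.
#' @param intensity Length-2 range to which the phantom is rescaled.
#' @param seed Optional integer; when set, generation is reproducible
#'   independently of the surrounding RNG state.
#' @return Object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(kind = c("beads", "filaments", "blobs", "texture",
                                  "mixture"),
                         size = 64L, density = 30, bead_sigma = c(0.9, 1.1),
                         n_filaments = 4,
                         blob_sigma = 5, texture_cutoff = 0.25,
                         intensity = c(0, 1), seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(size >= 8, density > 0, n_filaments >= 1, blob_sigma > 0,
            length(bead_sigma) == 2, all(bead_sigma > 0),
            bead_sigma[2] >= bead_sigma[1],
            texture_cutoff > 0, texture_cutoff <= 1,
            length(intensity) == 2, intensity[1] >= 0, intensity[2] <= 1,
            intensity[2] > intensity[1])
  structure(list(kind = kind, size = as.integer(size), density = density,
                 bead_sigma = as.numeric(bead_sigma),
                 n_filaments = n_filaments, blob_sigma = blob_sigma,
                 texture_cutoff = texture_cutoff, intensity = intensity,
                 seed = seed),
            class = "phantom_spec")
}

gaussian_kernel2 <- function(sigma, radius = ceiling(3 * sigma)) {
  x <- (-radius):radius
  g <- exp(-x^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

rescale01 <- function(x, lo = 0, hi = 1) {
  r <- range(x)
  if (r[2] - r[1] < .Machine$double.eps) return(matrix(lo, nrow(x), ncol(x)))
  lo + (hi - lo) * (x - r[1]) / (r[2] - r[1])
}

phantom_beads <- function(n, density, bead_sigma = c(0.9, 1.1)) {
  img <- matrix(0, n, n)
  count <- stats::rpois(1, density)
  if (count == 0) count <- 1
  cx <- stats::runif(count, 1, n)
  cy <- stats::runif(count, 1, n)
  amp <- stats::runif(count, 0.4, 1)
  sig <- stats::runif(count, bead_sigma[1], bead_sigma[2])
  xs <- seq_len(n)
  for (i in seq_len(count)) {
    gx <- exp(-(xs - cy[i])^2 / (2 * sig[i]^2))
    gy <- exp(-(xs - cx[i])^2 / (2 * sig[i]^2))
    img <- img + amp[i] * outer(gx, gy)
  }
  attr(img, "count") <- count
  img
}

phantom_filaments <- function(n, n_filaments) {
  img <- matrix(0, n, n)
  steps <- 4L * n
  for (f in seq_len(n_filaments)) {
    pos <- stats::runif(2, 1, n)
    ang <- stats::runif(1, 0, 2 * pi)
    amp <- stats::runif(1, 0.5, 1)
    for (s in seq_len(steps)) {
      ang <- ang + stats::rnorm(1, 0, 0.15)
      pos <- pos + c(cos(ang), sin(ang)) * 0.5
      pos <- ((pos - 1) %% n) + 1
      ij <- ((round(pos) - 1L) %% n) + 1L
      img[ij[1], ij[2]] <- amp
    }
  }
  fft_conv(img, gaussian_kernel2(0.8))
}

phantom_blobs <- function(n, sigma) {
  noise <- matrix(stats::rnorm(n * n), n, n)
  sm <- fft_conv(noise, gaussian_kernel2(sigma))
  thr <- stats::quantile(sm, 0.7)
  mask <- (sm > thr) * sm
  fft_conv(mask, gaussian_kernel2(1))
}

phantom_texture <- function(n, cutoff) {
  noise <- matrix(stats::rnorm(n * n), n, n)
  f1 <- c(0:((n - 1) %/% 2), -(n %/% 2):-1) / n
  fr <- sqrt(outer(f1^2, f1^2, "+"))
  filt <- exp(-(fr / (0.5 * cutoff))^2)
  Re(ifft2(fft2(noise) * filt))
}

#' Generate a synthetic phantom image
#'
#' Beads are Gaussian spots at uniformly scattered locations with a
#' Poisson-distributed count; filaments are smoothed random-walk curves;
#' blobs are thresholded smoothed noise; textures are band-limited Gaussian
#' random fields; the mixture class superimposes a random pair of the above.
#' All phantoms are affinely rescaled to the spec's intensity range (within
#' [0, 1]).
#'
#' @param spec A \code{\link{phantom_spec}} (or a kind name, with defaults).
#' @return Image matrix in [0, 1].  For beads the realized spot count is
#'   attached as attribute \code{"count"}.
#' @examples
#' u <- generate_phantom(phantom_spec("beads", size = 32, seed = 1))
#' range(u)
#' @export
generate_phantom <- function(spec) {
  if (is.character(spec)) spec <- phantom_spec(spec)
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.null(spec$seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(spec$seed)
  }
  n <- spec$size
  kind <- spec$kind
  if (kind == "mixture") {
    pair <- sample(c("beads", "filaments", "blobs", "texture"), 2)
    w <- stats::runif(1, 0.3, 0.7)
    sub <- function(k) generate_phantom(
      phantom_spec(k, size = n, density = spec$density,
                   bead_sigma = spec$bead_sigma,
                   n_filaments = spec$n_filaments,
                   blob_sigma = spec$blob_sigma,
                   texture_cutoff = spec$texture_cutoff))
    img <- w * sub(pair[1]) + (1 - w) * sub(pair[2])
    return(rescale01(img, spec$intensity[1], spec$intensity[2]))
  }
  img <- switch(kind,
    beads = phantom_beads(n, spec$density, spec$bead_sigma),
    filaments = phantom_filaments(n, spec$n_filaments),
    blobs = phantom_blobs(n, spec$blob_sigma),
    texture = phantom_texture(n, spec$texture_cutoff))
  cnt <- attr(img, "count")
  img <- rescale01(img, spec$intensity[1], spec$intensity[2])
  if (!is.null(cnt)) attr(img, "count") <- cnt
  img
}

# Orthonormal smooth low-order 2D fields (tensor products of Legendre-flavor
# polynomials and low harmonics), used as space-variation maps.
smooth_field_basis <- function(dims, M) {
  h <- dims[1]; w <- dims[2]
  x <- seq(-1, 1, length.out = w)
  y <- seq(-1, 1, length.out = h)
  gens <- list(
    function(Y, X) 1 + 0 * X, function(Y, X) X, function(Y, X) Y,
    function(Y, X) X * Y, function(Y, X) X^2 - 1 / 3,
    function(Y, X) Y^2 - 1 / 3, function(Y, X) cos(pi * X),
    function(Y, X) cos(pi * Y), function(Y, X) sin(pi * X) * sin(pi * Y),
    function(Y, X) X^2 * Y, function(Y, X) X * Y^2,
    function(Y, X) cos(2 * pi * X), function(Y, X) cos(2 * pi * Y),
    function(Y, X) X^3, function(Y, X) Y^3
  )
  if (M > length(gens))
    stop("at most ", length(gens), " space-variation maps are supported")
  X <- matrix(x, h, w, byrow = TRUE)
  Y <- matrix(y, h, w)
  raw <- vapply(gens[seq_len(M)], function(f) as.vector(f(Y, X)),
                numeric(h * w))
  q <- qr.Q(qr(raw))
  # fix signs so the leading map is positive (near-constant)
  for (m in seq_len(M)) if (sum(q[, m]) < 0) q[, m] <- -q[, m]
  array(q, c(h, w, M))
}

#' Generate a synthetic product-convolution operator family
#'
#' Builds an eigen-PSF basis by PCA of a cloud of Zernike-generated
#' diffraction PSFs (the "theoretical PSF family" route) and pairs it with
#' orthonormalized smooth low-order polynomial/harmonic space-variation
#' maps, yielding a space-varying product-convolution family.  The leading
#' space-variation map is constant up to normalization, so the first
#' component carries the space-invariant part of the blur.
#'
#' @param p Subspace dimension (number of eigen-PSFs and variation maps).
#' @param img_size Image side length the family operates on.
#' @param config Optical configuration for the PSF cloud.
#' @param n_cloud Number of random PSFs in the PCA cloud.
#' @param c_max Zernike amplitude bound for the cloud.
#' @param gamma_ranges p x 2 matrix of parameter ranges; default: the leading
#'   coefficient in [0.5, 1.5] (dominant mean PSF) and the rest in
#'   [-0.5, 0.5].
#' @return An \code{\link{operator_family}} of variant \code{product_conv},
#'   with the bases accessible as \code{$basis} and \code{$sv_basis}.
#' @export
generate_synthetic_family <- function(p = 10L, img_size = 64L,
                                      config = optical_config(),
                                      n_cloud = 200L, c_max = 0.15,
                                      gamma_ranges = NULL) {
  stopifnot(p >= 1)
  cloud <- lapply(seq_len(n_cloud), function(i)
    zernike_psf(config, sample_random_coeffs(c_max = c_max)))
  basis <- build_basis_pca(cloud, M = p)
  sv <- space_variation_basis(smooth_field_basis(c(img_size, img_size), p))
  if (is.null(gamma_ranges)) {
    gamma_ranges <- cbind(rep(-0.5, p), rep(0.5, p))
    gamma_ranges[1, ] <- c(0.5, 1.5)
  }
  operator_family("product_conv", ranges = gamma_ranges, basis = basis,
                  sv_basis = sv)
}

#' Zernike convolution family with the default study conditions
#'
#' Space-invariant family whose parameters are Zernike pupil coefficients
#' drawn uniformly in \eqn{[-c_{max}, c_{max}]}.
#'
#' For a family to be identifiable from a single image it must contain
#' odd-parity aberrations: with even-parity modes only (defocus,
#' astigmatism, spherical), the pupil phase is even, every PSF is centrally
#' symmetric, and \eqn{\gamma} and \eqn{-\gamma} generate exactly the same
#' observation, so no estimator can recover the sign.  Low-dimensional
#' families therefore default to coma/trefoil modes (Noll 7-10) before the
#' even ones.
#'
#' @param p Number of coefficients.
#' @param c_max Amplitude bound (waves), default 0.15.
#' @param config Optical configuration.
#' @param noll_indices Noll indices paired with the coefficients; default:
#'   the first \code{p} of (7, 8, 9, 10, 4, 5, 6) for p <= 4 (odd-parity
#'   first, see above), else 4:(3+p).
#' @return An \code{\link{operator_family}}.
#' @export
zernike_family <- function(p = 7L, c_max = 0.15, config = optical_config(),
                           noll_indices = NULL) {
  if (is.null(noll_indices)) {
    noll_indices <- if (p <= 4L) c(7L, 8L, 9L, 10L)[seq_len(p)]
                    else seq(4L, length.out = p)
  }
  operator_family("zernike_conv", ranges = c(-c_max, c_max), p = p,
                  config = config, noll_indices = noll_indices)
}

#' Write a synthetic training dataset to disk
#'
#' Draws \code{n} (clean image, operator, noise) triples, simulates the
#' degraded observations, writes clean/degraded images as TIFF and a
#' self-describing JSON-lines manifest (per-record seeds, gamma and noise
#' labels), so any dataset is reproducible from its manifest alone.
#'
#' @param n Number of records.
#' @param phantom_specs A \code{\link{phantom_spec}} or list of specs cycled
#'   over records.
#' @param family An \code{\link{operator_family}}.
#' @param ranges Noise ranges (\code{\link{noise_ranges}}).
#' @param margin Boundary crop applied to the degraded image.
#' @param seed Master seed.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the manifest as a data frame; files are written under
#'   \code{out_dir}.
#' @export
make_dataset <- function(n, phantom_specs, family, ranges = noise_ranges(),
                         margin = 0L, seed = 1L, out_dir) {
  stopifnot(n >= 1)
  if (inherits(phantom_specs, "phantom_spec")) phantom_specs <- list(phantom_specs)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  rec_seeds <- sample.int(.Machine$integer.max - 1L, n)
  manifest_path <- file.path(out_dir, "manifest.jsonl")
  con <- file(manifest_path, "w")
  on.exit(close(con))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(rec_seeds[i])
    spec <- phantom_specs[[(i - 1L) %% length(phantom_specs) + 1L]]
    u <- generate_phantom(spec)
    op <- sample_operator(family)
    eta <- sample_noise_params(ranges)
    obs <- degrade(u, op, eta, margin = margin)
    clean_file <- sprintf("clean_%05d.tif", i)
    deg_file <- sprintf("degraded_%05d.tif", i)
    write_image_tiff(u, file.path(out_dir, clean_file))
    write_image_tiff(obs$b, file.path(out_dir, deg_file))
    rec <- list(index = i, seed = rec_seeds[i], kind = spec$kind,
                clean = clean_file, degraded = deg_file,
                gamma = op$gamma, eta1 = eta$eta1, eta2 = eta$eta2,
                margin = margin)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
    rows[[i]] <- data.frame(index = i, seed = rec_seeds[i], kind = spec$kind,
                            clean = clean_file, degraded = deg_file,
                            eta1 = eta$eta1, eta2 = eta$eta2)
  }
  invisible(do.call(rbind, rows))
}
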