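#' Poisson-Gaussian noise parameters
#'
#' Heteroscedastic Gaussian approximation of shot + read noise: a pixel with
#' clean intensity \eqn{z} receives independent Gaussian noise of variance
#' \eqn{\eta_1 \max(z, 0) + \eta_2^2}.  \eqn{\eta_1} is the signal-dependent
#' variance gain (dimensionless for intensities in [0,1]) and \eqn{\eta_2}
#' the additive noise standard deviation (intensity units).
#'
#' @param eta1,eta2 Nonnegative noise parameters.
#' @return Object of class \code{noise_params}.
#' @export
noise_params <- function(eta1 = 0, eta2 = 0) {
  if (eta1 < 0 || eta2 < 0) stop("noise parameters must be nonnegative")
  structure(list(eta1 = eta1, eta2 = eta2), class = "noise_params")
}

#' Default noise parameter ranges
#'
#' Uniform sampling ranges for \eqn{(\eta_1, \eta_2)} used during training,
#' for images in [0, 1]: \eqn{\eta_1 \in [0, 0.01]},
#' \eqn{\eta_2 \in [0, 0.05]}.
#'
#' @param eta1,eta2 Length-2 numeric ranges.
#' @return A list with elements \code{eta1}, \code{eta2}.
#' @export
noise_ranges <- function(eta1 = c(0, 0.01), eta2 = c(0, 0.05)) {
  stopifnot(length(eta1) == 2, length(eta2) == 2,
            all(eta1 >= 0), all(eta2 >= 0),
            eta1[2] >= eta1[1], eta2[2] >= eta2[1])
  list(eta1 = as.numeric(eta1), eta2 = as.numeric(eta2))
}

#' Draw noise parameters uniformly from ranges
#'
#' @param ranges A list as returned by \code{\link{noise_ranges}}.
#' @return A \code{\link{noise_params}} object.
#' @export
sample_noise_params <- function(ranges = noise_ranges()) {
  noise_params(stats::runif(1, ranges$eta1[1], ranges$eta1[2]),
               stats::runif(1, ranges$eta2[1], ranges$eta2[2]))
}

#' Add Poisson-Gaussian approximate noise to a clean image
#'
#' Returns \eqn{z + w} with \eqn{w_i \sim N(0, \eta_1 \max(z_i,0) +
#' \eta_2^2)} independently per pixel.  Negative intensities only affect the
#' variance through the clamp; the observation itself is not clipped.
#'
#' @param z Clean image (finite; intensities expected in [0, 1]).
#' @param params A \code{\link{noise_params}} object.
#' @return Noisy image, same dimensions.
#' @export
apply_noise <- function(z, params) {
  stopifnot(inherits(params, "noise_params"), all(is.finite(z)))
  if (params$eta1 == 0 && params$eta2 == 0) return(z)
  sd <- sqrt(params$eta1 * pmax(z, 0) + params$eta2^2)
  z + stats::rnorm(length(z)) * sd
}

#' Simulate a degraded observation
#'
#' The forward model \eqn{b = N(H(\gamma) u)}: blur the clean image with the
#' operator, add Poisson-Gaussian approximate noise, optionally discard a
#' boundary margin (circular-convolution wrap-around carries information that
#' is absent from real acquisitions).  The generating parameters are recorded
#' as training labels.
#'
#' @param u Clean image in [0, 1].
#' @param op A \code{\link{blur_operator}}.
#' @param params A \code{\link{noise_params}} object.
#' @param margin Nonnegative crop margin (pixels per side) applied to the
#'   observation.
#' @return Object of class \code{degraded_observation}: list with the
#'   observed image \code{b}, the clean blurred image \code{blurred} (before
#'   noise and crop), labels \code{gamma} and \code{noise}, and the
#'   \code{margin}.
#' @export
degrade <- function(u, op, params = noise_params(), margin = 0L) {
  stopifnot(is.matrix(u))
  z <- apply_operator(op, u)
  b <- apply_noise(z, params)
  if (margin > 0) b <- crop_margins(b, margin)
  structure(list(b = b, blurred = z, gamma = op$gamma, noise = params,
                 margin = as.integer(margin)),
            class = "degraded_observation")
}

#' Remove boundary margins from an image
#'
#' @param b Image matrix.
#' @param margin Pixels removed on every side; \code{2 * margin} must be
#'   smaller than each image dimension.
#' @return Central sub-image.
#' @export
crop_margins <- function(b, margin) {
  margin <- as.integer(margin)
  if (margin < 0) stop("margin must be nonnegative")
  if (margin == 0L) return(b)
  if (2L * margin >= nrow(b) || 2L * margin >= ncol(b))
    stop("margin too large for the image size")
  b[(margin + 1L):(nrow(b) - margin), (margin + 1L):(ncol(b) - margin)]
}
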