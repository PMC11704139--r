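#' Signal-to-noise ratio of an estimated kernel
#'
#' The relative-error SNR in decibels,
#' \deqn{\mathrm{SNR} = -20 \log_{10}\left(\|\hat k - k\|_2 / \|k\|_2\right),}
#' so a 10\% relative error maps to 20 dB and \eqn{\hat k = 2k} to 0 dB.
#' A zero error returns \code{Inf}.
#'
#' @param k_hat Estimated kernel.
#' @param k Reference kernel (nonzero), same grid.
#' @return SNR in dB (possibly \code{Inf}).
#' @export
psf_snr <- function(k_hat, k) {
  if (!all(dim(k_hat) == dim(k))) stop("kernels must share the same grid")
  nk <- sqrt(sum(k^2))
  if (nk == 0) stop("reference kernel is identically zero")
  err <- sqrt(sum((k_hat - k)^2))
  if (err == 0) return(Inf)
  -20 * log10(err / nk)
}

#' Relative l2 error of an estimated kernel or parameter vector
#'
#' @param k_hat,k Estimate and reference (same shape; reference nonzero).
#' @return \eqn{\|\hat k - k\|_2 / \|k\|_2}.
#' @export
relative_error <- function(k_hat, k) {
  nk <- sqrt(sum(k^2))
  if (nk == 0) stop("reference is identically zero")
  sqrt(sum((k_hat - k)^2)) / nk
}

#' Structural similarity index (SSIM)
#'
#' Standard SSIM with the canonical constants (K1 = 0.01, K2 = 0.03) and an
#' 11 x 11 Gaussian window of standard deviation 1.5; local statistics use
#' valid-region windowing and the map is averaged into a scalar score in
#' [-1, 1].
#'
#' @param x,y Images on the same grid, larger than the window.
#' @param data_range Dynamic range L of the data (1 for images in [0, 1]).
#' @param sigma Gaussian window standard deviation.
#' @param win_size Odd window side length.
#' @return Mean SSIM value.
#' @export
ssim <- function(x, y, data_range = 1, sigma = 1.5, win_size = 11L) {
  if (!all(dim(x) == dim(y))) stop("images must share the same grid")
  if (any(dim(x) < win_size)) stop("images smaller than the SSIM window")
  w <- gaussian_kernel2(sigma, radius = (win_size - 1L) %/% 2L)
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  mx <- nn_xcorr_valid(x, w)
  my <- nn_xcorr_valid(y, w)
  sxx <- nn_xcorr_valid(x * x, w) - mx^2
  syy <- nn_xcorr_valid(y * y, w) - my^2
  sxy <- nn_xcorr_valid(x * y, w) - mx * my
  num <- (2 * mx * my + c1) * (2 * sxy + c2)
  den <- (mx^2 + my^2 + c1) * (sxx + syy + c2)
  mean(num / den)
}

#' Image signal-to-noise ratio in dB
#'
#' \eqn{-20\log_{10}(\|\hat u - u\|_2/\|u\|_2)} for a restored image against
#' the reference.
#'
#' @param u_hat,u Restored and reference images.
#' @return SNR in dB.
#' @export
image_snr <- function(u_hat, u) psf_snr(u_hat, u)

#' Robustness sweep of the identification network
#'
#' Evaluation protocol for a trained identification model: for each level of
#' the swept axis (test-time additive noise \eqn{\eta_2}, or Zernike
#' amplitude bound \eqn{c}), degrade \code{n} fresh phantoms with \code{n}
#' freshly sampled operators, identify the parameters, and record the
#' quartiles of the relative parameter and kernel errors.  With
#' \code{mode = "grid"}, a full image x kernel PSF-SNR table is computed at
#' the first level instead of paired draws.
#'
#' @param model A trained identification model.
#' @param family The \code{\link{operator_family}} the model was trained on.
#' @param noise_levels Numeric vector of \eqn{\eta_2} levels (include 0 as
#'   the reference point), or \code{NULL}.
#' @param amplitude_levels Numeric vector of \eqn{c_{max}} levels, or
#'   \code{NULL}.  Exactly one of the two axes must be given.
#' @param n Samples per level (paired mode) or per axis (grid mode).
#' @param phantom A \code{\link{phantom_spec}} used for the test images.
#' @param margin Boundary crop before identification; defaults to the PSF
#'   half-width.
#' @param seed Integer seed; the sweep is deterministic given (model, seed).
#' @param mode \code{"paired"} (default) or \code{"grid"}.
#' @return Object of class \code{evaluation_report}: list with a
#'   \code{summary} data frame (level, error quartiles, median PSF SNR), the
#'   per-sample \code{errors}, and in grid mode the \code{snr_table}.
#' @export
robustness_sweep <- function(model, family, noise_levels = NULL,
                             amplitude_levels = NULL, n = 50,
                             phantom = phantom_spec("mixture"),
                             margin = NULL, seed = 1L,
                             mode = c("paired", "grid")) {
  mode <- match.arg(mode)
  if (is.null(noise_levels) == is.null(amplitude_levels))
    stop("give exactly one of noise_levels or amplitude_levels")
  axis <- if (is.null(noise_levels)) "amplitude" else "noise"
  levels <- if (axis == "noise") noise_levels else amplitude_levels
  if (is.null(margin)) margin <- default_margin(family)
  set.seed(seed)
  level_seeds <- sample.int(.Machine$integer.max - 1L, length(levels))
  rows <- list(); errors <- list(); snr_table <- NULL
  for (li in seq_along(levels)) {
    set.seed(level_seeds[li])
    lev <- levels[li]
    fam <- family
    eta <- noise_params(0, 0)
    if (axis == "noise") {
      eta <- noise_params(0, lev)
    } else {
      fam$ranges <- matrix(rep(c(-lev, lev), each = fam$p), fam$p, 2)
    }
    if (mode == "grid" && li == 1L) {
      us <- lapply(seq_len(n), function(i) generate_phantom(phantom))
      ops <- lapply(seq_len(n), function(i) sample_operator(fam))
      snr_table <- matrix(NA_real_, n, n)
      for (ki in seq_len(n)) for (ii in seq_len(n)) {
        obs <- degrade(us[[ii]], ops[[ki]], eta, margin = margin)
        gh <- predict_params(model, obs$b)
        k_hat <- family_kernel(fam, gh)
        snr_table[ki, ii] <- psf_snr(k_hat, operator_kernel(ops[[ki]]))
      }
      err <- as.vector(1 / 10^(snr_table / 20))
    } else {
      err <- numeric(n); err_g <- numeric(n)
      for (i in seq_len(n)) {
        u <- generate_phantom(phantom)
        op <- sample_operator(fam)
        obs <- degrade(u, op, eta, margin = margin)
        gh <- predict_params(model, obs$b)
        err_g[i] <- relative_error(gh, op$gamma)
        err[i] <- relative_error(family_kernel(fam, gh),
                                 operator_kernel(op))
      }
      errors[[li]] <- data.frame(level = lev, kernel_error = err,
                                 param_error = err_g)
    }
    q <- stats::quantile(err, c(0.25, 0.5, 0.75))
    rows[[li]] <- data.frame(axis = axis, level = lev,
                             q25 = q[1], median = q[2], q75 = q[3],
                             median_snr_db = -20 * log10(q[2]))
  }
  structure(list(summary = do.call(rbind, rows),
                 errors = if (length(errors)) do.call(rbind, errors) else NULL,
                 snr_table = snr_table, seed = seed),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

# Kernel of a space-invariant operator / family member (used by sweeps).
operator_kernel <- function(op) {
  if (!is_conv_variant(op)) stop("operator has no space-invariant kernel")
  op$kernel
}

family_kernel <- function(family, gamma) {
  operator_kernel(family_operator(family, gamma))
}

# PSF half-width of a family: the default boundary margin.
default_margin <- function(family) {
  g <- if (!is.null(family$config)) family$config$psf_grid_size
       else dim(family$basis$kernels)[1]
  as.integer(g) %/% 2L
}
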