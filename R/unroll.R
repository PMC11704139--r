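#' Solver configuration for the unrolled Douglas-Rachford scheme
#'
#' @param K Number of unrolled iterations (>= 1); the paper-scale default
#'   is 4.
#' @param sigma Regularization scale of the data-term proximal step (> 0).
#'   A practical choice is \code{max(eta2^2, 1e-4)} for noise level
#'   \code{eta2}.
#' @param cg_iters Conjugate-gradient iterations for the initial guess
#'   (default 20).
#' @param exact_fourier_inverse Use the closed-form Fourier solution of the
#'   regularized inverse for space-invariant operators (exact and fast);
#'   otherwise CG is used.
#' @param output \code{"data"} returns the final data-consistency iterate
#'   \eqn{x_K}; \code{"prox"} returns the last proximal output.
#' @return Object of class \code{solver_config}.
#' @export
solver_config <- function(K = 4L, sigma = 1e-3, cg_iters = 20L,
                          exact_fourier_inverse = TRUE,
                          output = c("data", "prox")) {
  stopifnot(K >= 1, sigma > 0, cg_iters >= 1)
  structure(list(K = as.integer(K), sigma = sigma,
                 cg_iters = as.integer(cg_iters),
                 exact_fourier_inverse = isTRUE(exact_fourier_inverse),
                 output = match.arg(output)),
            class = "solver_config")
}

# Conjugate gradient for (H^T H + sigma I) x = rhs, fixed iteration budget.
cg_normal <- function(op, sigma, rhs, x0 = NULL, iters = 20L, tol = 1e-12) {
  A <- function(v) adjoint_operator(op, apply_operator(op, v)) + sigma * v
  x <- if (is.null(x0)) matrix(0, nrow(rhs), ncol(rhs)) else x0
  r <- rhs - A(x)
  p <- r
  rs <- sum(r * r)
  if (sqrt(rs) < tol) return(list(x = x, resid = sqrt(rs)))
  for (i in seq_len(iters)) {
    Ap <- A(p)
    alpha <- rs / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs_new <- sum(r * r)
    if (sqrt(rs_new) < tol) break
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  list(x = x, resid = sqrt(sum((rhs - A(x))^2)))
}

#' Regularized inverse (data-term proximal step)
#'
#' Solves \eqn{(H^T H + \sigma I)\,x = H^T b + \sigma z}, the proximal map of
#' the quadratic data term \eqn{\tfrac{1}{2\sigma}\|Hx-b\|^2} at \eqn{z}.
#' For space-invariant operators the solution is computed in closed form by
#' Fourier diagonalization; otherwise (or when
#' \code{exact_fourier = FALSE}) by conjugate gradient on the normal
#' equations, warning if the residual remains large.
#'
#' @param op A \code{\link{blur_operator}}.
#' @param sigma Regularization scale (> 0).
#' @param z Current estimate (the proximal point).
#' @param b Observation.
#' @param exact_fourier Use the Fourier closed form when available.
#' @param cg_iters Iteration budget for the CG fallback.
#' @return Image matrix.
#' @export
regularized_inverse <- function(op, sigma, z, b, exact_fourier = TRUE,
                                cg_iters = 50L) {
  stopifnot(sigma > 0)
  if (exact_fourier && is_conv_variant(op)) {
    otf <- kernel_otf(op$kernel, dim(b))
    num <- Conj(otf) * fft2(b) + sigma * fft2(z)
    return(Re(ifft2(num / (Mod(otf)^2 + sigma))))
  }
  rhs <- adjoint_operator(op, b) + sigma * z
  sol <- cg_normal(op, sigma, rhs, x0 = z, iters = cg_iters)
  if (sol$resid > 1e-6 * (1 + sqrt(sum(rhs^2))))
    warning("regularized_inverse: CG stopped with residual ",
            format(sol$resid), "; returning best iterate")
  sol$x
}

#' Initial guess by conjugate gradient
#'
#' Approximate Tikhonov-regularized solution of
#' \eqn{(H^T H + \sigma I) x = H^T b}, started from the zero image and run
#' for a fixed budget of CG iterations.
#'
#' @param op A \code{\link{blur_operator}}.
#' @param b Observation.
#' @param sigma Regularization scale (>= 0; must be > 0 if H is
#'   rank-deficient).
#' @param cg_iters CG iteration budget (default 20).
#' @return Image matrix.
#' @export
init_guess <- function(op, b, sigma, cg_iters = 20L) {
  stopifnot(sigma >= 0)
  cg_normal(op, sigma, adjoint_operator(op, b), x0 = NULL,
            iters = cg_iters)$x
}

#' Proximal network
#'
#' The learned (or classical) image-to-image regularization step of the
#' unrolled scheme.  Presets:
#' \describe{
#'   \item{\code{tiny_unet}}{a two-scale residual U-Net (widths 16/32) small
#'     enough for CPU training;}
#'   \item{\code{drunet_like}}{the same topology at widths 32/64, in the
#'     spirit of the deep plug-and-play denoisers;}
#'   \item{\code{identity}}{the identity map (no regularization; useful as a
#'     baseline);}
#'   \item{\code{classical_denoiser}}{a fixed Gaussian smoothing denoiser
#'     (no trainable weights).}
#' }
#' Trainable presets end in a final convolution initialized near zero, so an
#' untrained proximal network starts close to the identity.
#'
#' @param preset Architecture preset.
#' @param seed Integer seed for weight initialization.
#' @param denoise_sigma Smoothing scale of the classical denoiser (pixels).
#' @return Object of class \code{prox_network}.
#' @export
init_prox_network <- function(preset = c("tiny_unet", "drunet_like",
                                         "identity", "classical_denoiser"),
                              seed = 1L, denoise_sigma = 1) {
  preset <- match.arg(preset)
  params <- NULL
  widths <- NULL
  if (preset %in% c("tiny_unet", "drunet_like")) {
    widths <- if (preset == "tiny_unet") c(16L, 32L) else c(32L, 64L)
    set.seed(seed)
    w1 <- widths[1]; w2 <- widths[2]
    params <- list(c1 = init_conv(3L, 3L, 1L, w1),
                   c2 = init_conv(3L, 3L, w1, w1),
                   down = init_conv(3L, 3L, w1, w2),
                   c3 = init_conv(3L, 3L, w2, w2),
                   up = init_conv(3L, 3L, w2, w1),
                   c4 = init_conv(3L, 3L, w1, w1),
                   c5 = init_conv(3L, 3L, w1, 1L, gain = 0.05))
  }
  structure(list(preset = preset, params = params, widths = widths,
                 denoise_sigma = denoise_sigma, seed = seed),
            class = "prox_network")
}

#' @export
print.prox_network <- function(x, ...) {
  np <- if (is.null(x$params)) 0L else sum(rapply(x$params, length, how = "unlist"))
  cat(sprintf("<prox_network: %s, %d parameters>\n", x$preset, np))
  invisible(x)
}

prox_forward <- function(prox, x, keep = FALSE) {
  if (prox$preset == "identity")
    return(list(out = x, cache = NULL))
  if (prox$preset == "classical_denoiser") {
    d <- dim(x)
    out <- x
    k <- gaussian_kernel2(prox$denoise_sigma)
    for (nn in seq_len(d[4])) out[, , 1L, nn] <- fft_conv(x[, , 1L, nn], k)
    return(list(out = out, cache = NULL))
  }
  p <- prox$params
  h1 <- conv_fwd(x, p$c1$w, p$c1$b);  a1 <- relu_fwd(h1)
  h2 <- conv_fwd(a1, p$c2$w, p$c2$b); a2 <- relu_fwd(h2)
  hd <- conv_fwd(a2, p$down$w, p$down$b, stride = 2L); ad <- relu_fwd(hd)
  h3 <- conv_fwd(ad, p$c3$w, p$c3$b); a3 <- relu_fwd(h3)
  u2 <- upsample2_fwd(a3)
  u2 <- u2[seq_len(dim(a2)[1]), seq_len(dim(a2)[2]), , , drop = FALSE]
  hu <- conv_fwd(u2, p$up$w, p$up$b); au <- relu_fwd(hu)
  f <- au + a2
  h4 <- conv_fwd(f, p$c4$w, p$c4$b); a4 <- relu_fwd(h4)
  h5 <- conv_fwd(a4, p$c5$w, p$c5$b)
  out <- x + h5
  cache <- NULL
  if (keep)
    cache <- list(x = x, h1 = h1, a1 = a1, h2 = h2, a2 = a2, hd = hd,
                  ad = ad, h3 = h3, a3 = a3, u2 = u2, hu = hu, f = f,
                  h4 = h4, a4 = a4)
  list(out = out, cache = cache)
}

prox_backward <- function(prox, cache, g) {
  if (prox$preset == "identity")
    return(list(gx = g, grads = NULL))
  if (prox$preset == "classical_denoiser") {
    d <- dim(g)
    gx <- g
    k <- gaussian_kernel2(prox$denoise_sigma)
    for (nn in seq_len(d[4])) gx[, , 1L, nn] <- fft_corr(g[, , 1L, nn], k)
    return(list(gx = gx, grads = NULL))
  }
  p <- prox$params
  cb5 <- conv_bwd(cache$a4, p$c5$w, g)
  gh4 <- relu_bwd(cache$h4, cb5$gx)
  cb4 <- conv_bwd(cache$f, p$c4$w, gh4)
  gf <- cb4$gx
  ghu <- relu_bwd(cache$hu, gf)
  cbu <- conv_bwd(cache$u2, p$up$w, ghu)
  # undo the crop of the upsampled grid, then the upsampling
  d3 <- dim(cache$a3)
  gu2 <- array(0, c(2L * d3[1], 2L * d3[2], d3[3], d3[4]))
  gu2[seq_len(dim(cbu$gx)[1]), seq_len(dim(cbu$gx)[2]), , ] <- cbu$gx
  ga3 <- upsample2_bwd(gu2)
  gh3 <- relu_bwd(cache$h3, ga3)
  cb3 <- conv_bwd(cache$ad, p$c3$w, gh3)
  ghd <- relu_bwd(cache$hd, cb3$gx)
  cbd <- conv_bwd(cache$a2, p$down$w, ghd, stride = 2L)
  ga2 <- gf + cbd$gx
  gh2 <- relu_bwd(cache$h2, ga2)
  cb2 <- conv_bwd(cache$a1, p$c2$w, gh2)
  gh1 <- relu_bwd(cache$h1, cb2$gx)
  cb1 <- conv_bwd(cache$x, p$c1$w, gh1)
  gx <- g + cb1$gx
  grads <- list(c1 = list(w = cb1$gw, b = cb1$gb),
                c2 = list(w = cb2$gw, b = cb2$gb),
                down = list(w = cbd$gw, b = cbd$gb),
                c3 = list(w = cb3$gw, b = cb3$gb),
                up = list(w = cbu$gw, b = cbu$gb),
                c4 = list(w = cb4$gw, b = cb4$gb),
                c5 = list(w = cb5$gw, b = cb5$gb))
  list(gx = gx, grads = grads)
}

#' Apply a proximal network to an image
#'
#' @param prox A \code{\link{init_prox_network}} result, or a plain R
#'   function (any image-to-image map can serve as a classical plug-in
#'   proximal operator).
#' @param x Image matrix.
#' @return Image matrix of the same size.
#' @export
prox_apply <- function(prox, x) {
  if (is.function(prox)) return(prox(x))
  stopifnot(inherits(prox, "prox_network"))
  single <- is.matrix(x)
  out <- prox_forward(prox, as_batch(x))$out
  if (single) out[, , 1L, 1L] else out
}

#' Unrolled Douglas-Rachford deblurring
#'
#' Runs \code{K} iterations of the Douglas-Rachford splitting for the
#' quadratic data term \eqn{\tfrac12\|Hx-b\|^2} with learned (or classical)
#' proximal maps:
#' \deqn{x_{k+1} = (H^T H + \sigma I)^{-1}(H^T b + \sigma z_k), \quad
#'       z_{k+1} = z_k + \mathrm{Prox}_k(2 x_{k+1} - z_k) - x_{k+1},}
#' started from the conjugate-gradient initial guess
#' \eqn{x_0 = z_0 \approx (H^T H + \sigma I)^{-1} H^T b}.  By default the
#' final data-consistency iterate \eqn{x_K} is returned.
#'
#' @param b Observed (degraded) image.
#' @param op The \code{\link{blur_operator}} (true or estimated).
#' @param prox_list List of \code{K} \code{\link{init_prox_network}}
#'   objects (a single prox network is recycled).
#' @param config A \code{\link{solver_config}}.
#' @return Restored image matrix.
#' @export
douglas_rachford_unrolled <- function(b, op, prox_list,
                                      config = solver_config()) {
  stopifnot(inherits(config, "solver_config"))
  if (inherits(prox_list, "prox_network") || is.function(prox_list))
    prox_list <- rep(list(prox_list), config$K)
  if (length(prox_list) != config$K)
    stop("prox_list must have length K = ", config$K)
  sigma <- config$sigma
  fourier <- config$exact_fourier_inverse && is_conv_variant(op)
  otf <- if (fourier) kernel_otf(op$kernel, dim(b)) else NULL
  x <- init_guess(op, b, sigma, config$cg_iters)
  z <- x
  last_prox <- NULL
  for (k in seq_len(config$K)) {
    x <- if (fourier) {
      Re(ifft2((Conj(otf) * fft2(b) + sigma * fft2(z)) /
                 (Mod(otf)^2 + sigma)))
    } else {
      regularized_inverse(op, sigma, z, b, exact_fourier = FALSE,
                          cg_iters = config$cg_iters)
    }
    if (k < config$K || config$output == "prox") {
      pk <- prox_apply(prox_list[[k]], 2 * x - z)
      z <- z + pk - x
      last_prox <- pk
    }
  }
  if (config$output == "prox") last_prox else x
}

# Training-path forward/backward through the unrolled recursion for a
# space-invariant (Fourier-diagonal) operator.  Only the prox weights are
# trainable; the operator parameters enter as fixed inputs.
dr_forward_train <- function(b, otf, sigma, prox_list, K, cg_x0) {
  denom <- Mod(otf)^2 + sigma
  c_term <- Conj(otf) * fft2(b)
  ainv <- function(v) Re(ifft2(fft2(v) / denom))
  z <- cg_x0
  steps <- vector("list", K)
  x <- NULL
  for (k in seq_len(K)) {
    x <- Re(ifft2((c_term + sigma * fft2(z)) / denom))
    if (k < K) {
      y <- 2 * x - z
      pf <- prox_forward(prox_list[[k]], as_batch(y), keep = TRUE)
      z_new <- z + pf$out[, , 1L, 1L] - x
      steps[[k]] <- list(cache = pf$cache)
      z <- z_new
    }
  }
  list(x = x, steps = steps, ainv = ainv)
}

dr_backward_train <- function(gx_out, fw, sigma, prox_list, K) {
  ainv <- fw$ainv
  grads <- vector("list", K)
  gz <- sigma * ainv(gx_out)        # gradient w.r.t. z_{K-1}
  for (k in rev(seq_len(K - 1L))) {
    pb <- prox_backward(prox_list[[k]], fw$steps[[k]]$cache,
                        as_batch(gz))
    grads[[k]] <- pb$grads
    gy <- pb$gx[, , 1L, 1L]
    gxk <- 2 * gy - gz
    gz <- gz - gy + sigma * ainv(gxk)
  }
  grads
}

#' Train the deblurring network
#'
#' Minimizes the empirical reconstruction risk
#' \eqn{E\,\|DN(b, \hat\gamma) - u\|^2} over (clean image, operator, noise)
#' triples, where \eqn{\hat\gamma = IN(b)} is the parameter estimated by the
#' (already trained) identification network -- not the true one -- so that
#' the deblurring network learns to absorb identification errors.  Setting
#' \code{use_true_gamma = TRUE} trains against the true parameters instead
#' (ablation).  Only the proximal-network weights are trained (Adam); the
#' unrolled iterations are differentiated exactly through the Fourier-
#' diagonal regularized inverses, which requires a space-invariant family.
#'
#' @param prox_list List of \code{K} \code{\link{init_prox_network}}
#'   objects (untied weights).
#' @param identification_model Trained \code{identification_model} (may be
#'   \code{NULL} when \code{use_true_gamma = TRUE}).
#' @param image_source List of clean images in [0, 1].
#' @param family Space-invariant \code{\link{operator_family}}.
#' @param ranges Noise ranges, or \code{NULL} for noiseless training.
#' @param config A \code{\link{train_config}}.
#' @param solver A \code{\link{solver_config}}; its \code{K} must match
#'   \code{length(prox_list)}.
#' @param use_true_gamma Train with the true operator parameters.
#' @return List with the trained \code{prox_list} and a \code{history} data
#'   frame (epoch, training loss, and the fixed initial-guess baseline loss
#'   on the same samples).
#' @export
train_deblurring <- function(prox_list, identification_model, image_source,
                             family, ranges = NULL, config = train_config(),
                             solver = solver_config(),
                             use_true_gamma = FALSE) {
  stopifnot(inherits(family, "operator_family"),
            inherits(config, "train_config"),
            inherits(solver, "solver_config"),
            length(prox_list) == solver$K)
  if (!use_true_gamma && !inherits(identification_model, "identification_model"))
    stop("a trained identification model is required ",
         "(the two networks are trained sequentially)")
  if (!(family$variant %in% c("zernike_conv", "eigenpsf_conv")))
    stop("training differentiates the Fourier-diagonal inverse and ",
         "requires a space-invariant family")
  if (is.array(image_source) && length(dim(image_source)) == 3)
    image_source <- lapply(seq_len(dim(image_source)[3]),
                           function(i) image_source[, , i])
  n <- length(image_source)
  margin <- if (is.null(config$margin)) default_margin(family) else config$margin
  trainable <- which(vapply(prox_list, function(p) !is.null(p$params),
                            logical(1)))
  states <- lapply(prox_list[trainable], function(p) adam_init(p$params))
  set.seed(config$seed)
  K <- solver$K
  sigma <- solver$sigma
  history <- data.frame(epoch = integer(), loss = numeric(),
                        baseline = numeric())
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_base <- 0
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      B <- length(idx)
      acc <- NULL
      for (i in idx) {
        u <- image_source[[i]]
        op <- sample_operator(family)
        eta <- if (is.null(ranges)) noise_params(0, 0)
               else sample_noise_params(ranges)
        b <- degrade(u, op, eta)$b
        gamma_hat <- if (use_true_gamma) op$gamma
                     else predict_params(identification_model,
                                         crop_margins(b, margin))
        op_hat <- family_operator(family, gamma_hat)
        otf <- kernel_otf(op_hat$kernel, dim(b))
        x0 <- init_guess(op_hat, b, sigma, solver$cg_iters)
        fw <- dr_forward_train(b, otf, sigma, prox_list, K, x0)
        resid <- fw$x - u
        loss <- mean(resid^2)
        if (!is.finite(loss))
          stop("deblurring training diverged at epoch ", ep,
               ": non-finite loss")
        ep_loss <- ep_loss + loss
        ep_base <- ep_base + mean((x0 - u)^2)
        g <- dr_backward_train(2 * resid / length(resid), fw, sigma,
                               prox_list, K)
        acc <- if (is.null(acc)) g else accumulate_grads(acc, g)
      }
      for (ti in seq_along(trainable)) {
        k <- trainable[ti]
        if (is.null(acc[[k]])) next   # prox k received no gradient
        gk <- scale_grads(acc[[k]], 1 / B)
        upd <- adam_step(prox_list[[k]]$params, gk, states[[ti]],
                         lr = config$lr, beta1 = config$beta1,
                         beta2 = config$beta2, eps = config$eps)
        prox_list[[k]]$params <- upd$params
        states[[ti]] <- upd$state
      }
    }
    history <- rbind(history, data.frame(epoch = ep, loss = ep_loss / n,
                                         baseline = ep_base / n))
    if (config$verbose)
      message(sprintf("epoch %d: loss %.6f (init-guess baseline %.6f)",
                      ep, ep_loss / n, ep_base / n))
  }
  list(prox_list = prox_list, history = history)
}

accumulate_grads <- function(a, b) {
  rec <- function(x, y) {
    if (is.null(x)) return(y)
    if (is.null(y)) return(x)
    if (is.list(x)) return(Map(rec, x, y))
    x + y
  }
  Map(rec, a, b)
}

scale_grads <- function(g, s) {
  rec <- function(x) if (is.list(x)) lapply(x, rec) else x * s
  rec(g)
}

#' One-call blind deblurring
#'
#' The full two-network inference chain: identify the blur parameters from
#' the boundary-cropped observation, instantiate the estimated operator, and
#' run the unrolled Douglas-Rachford restoration.
#'
#' @param b Observed image.
#' @param family \code{\link{operator_family}}.
#' @param identification_model Trained identification model.
#' @param prox_list Trained proximal networks (or a single one, recycled).
#' @param config A \code{\link{solver_config}}.
#' @param reference Optional ground-truth image; when given, SSIM and image
#'   SNR of the observation and the restoration are reported.
#' @return List with the restored image \code{x}, the estimate
#'   \code{gamma_hat}, and \code{metrics} (when a reference is supplied).
#' @export
deblur <- function(b, family, identification_model, prox_list,
                   config = solver_config(), reference = NULL) {
  margin <- default_margin(family)
  gamma_hat <- predict_params(identification_model, crop_margins(b, margin))
  op_hat <- family_operator(family, gamma_hat)
  x <- douglas_rachford_unrolled(b, op_hat, prox_list, config)
  metrics <- NULL
  if (!is.null(reference)) {
    metrics <- list(ssim_observed = ssim(b, reference),
                    ssim_restored = ssim(x, reference),
                    snr_observed_db = image_snr(b, reference),
                    snr_restored_db = image_snr(x, reference))
  }
  list(x = x, gamma_hat = gamma_hat, sigma = config$sigma, K = config$K,
       metrics = metrics)
}
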