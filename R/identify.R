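#' Training configuration
#'
#' Optimizer and loop settings for the two training stages.  The optimizer is
#' Adam with learning rate 0.001, betas (0.9, 0.999), epsilon 1e-8 and no
#' weight decay.
#'
#' @param lr Learning rate (> 0).
#' @param beta1,beta2 Adam moment coefficients.
#' @param eps Adam epsilon.
#' @param weight_decay L2 penalty coefficient (0 disables).
#' @param batch_size Minibatch size.
#' @param epochs Number of passes over the training images.
#' @param lr_final Optional final learning rate; when set, the rate decays
#'   geometrically from \code{lr} to \code{lr_final} across epochs.
#' @param ema Optional exponential-moving-average decay for the weights
#'   (e.g. 0.998); when set, the returned model carries the averaged
#'   weights (Polyak averaging), which are less noisy than the last
#'   iterate.
#' @param seed Integer seed controlling data sampling and shuffling.
#' @param margin Boundary crop (pixels) applied to observations before
#'   identification; \code{NULL} means the PSF half-width of the family.
#' @param verbose Print per-epoch losses.
#' @return Object of class \code{train_config}.
#' @export
train_config <- function(lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         weight_decay = 0, batch_size = 16L, epochs = 10L,
                         lr_final = NULL, ema = NULL, seed = 1L,
                         margin = NULL, verbose = FALSE) {
  stopifnot(lr > 0, batch_size >= 1, epochs >= 1)
  structure(list(lr = lr, lr_final = lr_final, ema = ema,
                 beta1 = beta1, beta2 = beta2, eps = eps,
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 margin = margin, verbose = isTRUE(verbose)),
            class = "train_config")
}

arch_preset <- function(preset) {
  switch(preset,
    tiny = list(widths = c(16L, 32L, 64L, 64L), blocks = c(1L, 1L, 1L, 1L)),
    full = list(widths = c(64L, 128L, 256L, 512L),
                 blocks = c(2L, 2L, 2L, 2L)),
    stop("unknown architecture preset: ", preset))
}

#' Initialize the blur-identification encoder
#'
#' A residual convolutional encoder mapping a degraded image to the operator
#' parameter vector: a 3x3 stem convolution, a sequence of stages that each
#' halve the spatial resolution (strided convolution) and apply residual
#' blocks (each convolution followed by batch normalization and ReLU),
#' adaptive average pooling to a fixed 2x2 spatial grid, and a linear head
#' of size \code{p}.  Thanks to the adaptive pooling the encoder accepts
#' any input whose side lengths exceed the total downsampling factor and
#' always produces a length-\code{p} output.  The \code{"full"} preset is
#' an 18-layer-class encoder; the \code{"tiny"} preset (4 stages of one
#' block, widths 16-64, about 1.6e5 weights) trains in minutes on a CPU.
#'
#' @param p Output dimension (>= 1).
#' @param preset \code{"tiny"} or \code{"full"}.
#' @param seed Integer seed for the weight initialization.
#' @return Object of class \code{identification_model}.
#' @export
init_identification_model <- function(p, preset = c("tiny", "full"),
                                      seed = 1L) {
  preset <- match.arg(preset)
  stopifnot(p >= 1)
  a <- arch_preset(preset)
  set.seed(seed)
  widths <- a$widths
  conv_unit <- function(cin, cout, gain = 1)
    c(init_conv(3L, 3L, cin, cout, gain = gain), list(bn = bn_init(cout)))
  params <- list(stem = conv_unit(1L, widths[1]))
  stats <- list(stem = bn_stats_init(widths[1]))
  stages <- vector("list", length(widths))
  sstats <- vector("list", length(widths))
  cin <- widths[1]
  for (i in seq_along(widths)) {
    st <- list(down = conv_unit(cin, widths[i]))
    sst <- list(down = bn_stats_init(widths[i]))
    st$blocks <- lapply(seq_len(a$blocks[i]), function(j)
      list(c1 = conv_unit(widths[i], widths[i]),
           c2 = conv_unit(widths[i], widths[i], gain = 0.5)))
    sst$blocks <- lapply(seq_len(a$blocks[i]), function(j)
      list(c1 = bn_stats_init(widths[i]), c2 = bn_stats_init(widths[i])))
    stages[[i]] <- st
    sstats[[i]] <- sst
    cin <- widths[i]
  }
  params$stages <- stages
  stats$stages <- sstats
  pool_grid <- 2L
  params$fc <- init_linear(pool_grid^2 * widths[length(widths)], p)
  structure(list(params = params, bn_stats = stats,
                 arch = list(preset = preset, p = as.integer(p),
                             widths = widths, blocks = a$blocks,
                             pool_grid = pool_grid,
                             # smallest side whose ceil(n/2^stages) >= pool grid
                             min_input = (pool_grid - 1L) * 2L^length(widths) + 1L,
                             seed = seed),
                 target_scale = rep(1, p)),
            class = "identification_model")
}

#' @export
print.identification_model <- function(x, ...) {
  np <- sum(rapply(x$params, length, how = "unlist"))
  cat(sprintf("<identification_model: preset '%s', p = %d, %d parameters>\n",
              x$arch$preset, x$arch$p, np))
  invisible(x)
}

# conv -> batch-norm -> (cache); ReLU handled by callers where needed.
unit_fwd <- function(x, par, stats, training, stride = 1L) {
  h <- conv_fwd(x, par$w, par$b, stride = stride)
  bn <- bn_fwd(h, par$bn, stats, training)
  list(y = bn$y, stats = bn$stats,
       cache = list(x = x, h = h, bn = bn$cache))
}

unit_bwd <- function(par, cache, g, stride = 1L) {
  bb <- bn_bwd(cache$bn, par$bn, g)
  cb <- conv_bwd(cache$x, par$w, bb$gx, stride = stride)
  list(gx = cb$gx,
       g = list(w = cb$gw, b = cb$gb,
                bn = list(gamma = bb$ggamma, beta = bb$gbeta)))
}

encoder_forward <- function(model, x, keep = FALSE, training = FALSE) {
  p <- model$params
  bs <- model$bn_stats
  cache <- if (keep) list() else NULL
  u0 <- unit_fwd(x, p$stem, bs$stem, training)
  bs$stem <- u0$stats
  a <- relu_fwd(u0$y)
  if (keep) cache$stem <- list(unit = u0$cache, pre = u0$y)
  scache <- vector("list", length(p$stages))
  for (i in seq_along(p$stages)) {
    st <- p$stages[[i]]
    ud <- unit_fwd(a, st$down, bs$stages[[i]]$down, training, stride = 2L)
    bs$stages[[i]]$down <- ud$stats
    ad <- relu_fwd(ud$y)
    bcache <- vector("list", length(st$blocks))
    ain <- ad
    for (j in seq_along(st$blocks)) {
      bl <- st$blocks[[j]]
      u1 <- unit_fwd(ain, bl$c1, bs$stages[[i]]$blocks[[j]]$c1, training)
      bs$stages[[i]]$blocks[[j]]$c1 <- u1$stats
      r1 <- relu_fwd(u1$y)
      u2 <- unit_fwd(r1, bl$c2, bs$stages[[i]]$blocks[[j]]$c2, training)
      bs$stages[[i]]$blocks[[j]]$c2 <- u2$stats
      s <- ain + u2$y
      aout <- relu_fwd(s)
      if (keep) bcache[[j]] <- list(u1 = u1$cache, pre1 = u1$y,
                                    u2 = u2$cache, s = s)
      ain <- aout
    }
    if (keep) scache[[i]] <- list(ud = ud$cache, pred = ud$y,
                                  blocks = bcache)
    a <- ain
  }
  feat <- apool_fwd(a, model$arch$pool_grid)
  out <- linear_fwd(feat, p$fc$w, p$fc$b)
  if (keep) {
    cache$stages <- scache
    cache$final_dims <- dim(a)
    cache$feat <- feat
  }
  list(out = out, cache = cache, bn_stats = bs)
}

encoder_backward <- function(model, cache, gout) {
  p <- model$params
  g <- list(stem = NULL, stages = vector("list", length(p$stages)),
            fc = list(w = 0 * p$fc$w, b = 0 * p$fc$b))
  lb <- linear_bwd(cache$feat, p$fc$w, gout)
  g$fc$w <- lb$gw; g$fc$b <- lb$gb
  ga <- apool_bwd(cache$final_dims, model$arch$pool_grid, lb$gx)
  for (i in rev(seq_along(p$stages))) {
    st <- p$stages[[i]]
    sc <- cache$stages[[i]]
    gst <- list(down = NULL, blocks = vector("list", length(st$blocks)))
    for (j in rev(seq_along(st$blocks))) {
      bl <- st$blocks[[j]]
      bc <- sc$blocks[[j]]
      gs <- relu_bwd(bc$s, ga)
      b2 <- unit_bwd(bl$c2, bc$u2, gs)
      gr1 <- relu_bwd(bc$pre1, b2$gx)
      b1 <- unit_bwd(bl$c1, bc$u1, gr1)
      gst$blocks[[j]] <- list(c1 = b1$g, c2 = b2$g)
      ga <- gs + b1$gx
    }
    gad <- relu_bwd(sc$pred, ga)
    bd <- unit_bwd(st$down, sc$ud, gad, stride = 2L)
    gst$down <- bd$g
    g$stages[[i]] <- gst
    ga <- bd$gx
  }
  gh0 <- relu_bwd(cache$stem$pre, ga)
  b0 <- unit_bwd(p$stem, cache$stem$unit, gh0)
  g$stem <- b0$g
  g
}

#' Predict blur parameters from a degraded image
#'
#' Runs the identification encoder in inference mode (deterministic: two
#' identical inputs give identical outputs) and applies the inverse of the
#' per-coordinate target scaling stored at training time.
#'
#' For Zernike-pupil families an exact symmetry of the forward model is
#' available: a 180-degree rotation of the kernel corresponds to negating
#' all pupil coefficients, so rotating the observation and negating the
#' prediction is a second, equally valid estimate.  With
#' \code{symmetrize = TRUE} (enabled automatically for models trained on a
#' Zernike family) the two estimates are averaged, which cancels the
#' estimator's parity-asymmetric errors.
#'
#' @param model A (trained) \code{identification_model}.
#' @param b Image matrix, or an (H, W, 1, N) array for a batch.
#' @param symmetrize Average with the rotation-negation estimate (valid for
#'   Zernike-pupil families); \code{NULL} uses the setting stored at
#'   training time.
#' @return Numeric vector \eqn{\hat\gamma} of length \code{p} (or a p x N
#'   matrix for a batch).
#' @export
predict_params <- function(model, b, symmetrize = NULL) {
  stopifnot(inherits(model, "identification_model"))
  if (is.null(symmetrize)) symmetrize <- isTRUE(model$zernike_symmetry)
  single <- is.matrix(b)
  x <- as_batch(b)
  if (any(dim(x)[1:2] < model$arch$min_input))
    stop("input smaller than the encoder's total downsampling factor (",
         model$arch$min_input, " pixels)")
  if (any(!is.finite(x))) stop("input image contains non-finite values")
  out <- encoder_forward(model, x)$out * model$target_scale
  if (symmetrize && !is.null(model$flip_signs)) {
    ri <- rev(seq_len(dim(x)[1])); ci <- rev(seq_len(dim(x)[2]))
    sv <- model$flip_signs$v; sh <- model$flip_signs$h
    xv <- x[ri, , , , drop = FALSE]
    xh <- x[, ci, , , drop = FALSE]
    xr <- x[ri, ci, , , drop = FALSE]
    out <- (out +
            sv * encoder_forward(model, xv)$out * model$target_scale +
            sh * encoder_forward(model, xh)$out * model$target_scale +
            (sv * sh) * encoder_forward(model, xr)$out * model$target_scale) / 4
  }
  if (single) as.numeric(out) else out
}

#' Train the identification network
#'
#' Empirical risk minimization of
#' \eqn{E\,\|IN(b) - \gamma\|^2} over triples (clean image, operator
#' parameters, noise) where \eqn{b} is the boundary-cropped degraded
#' observation.  Operators are drawn uniformly from the family and a fresh
#' image/operator pairing and fresh noise are used at every epoch.  Targets
#' are rescaled per-coordinate to [-1, 1] by the family ranges, and the
#' inverse scaling is stored in the model and applied by
#' \code{\link{predict_params}}.
#'
#' @param model An \code{\link{init_identification_model}} result.
#' @param image_source List of clean images in [0, 1] (or an (H, W, n)
#'   array).
#' @param family \code{\link{operator_family}} to sample operators from.
#' @param ranges Noise ranges (\code{\link{noise_ranges}}), or \code{NULL}
#'   for noiseless training.
#' @param config A \code{\link{train_config}}.
#' @return List with the trained \code{model} and a \code{history} data
#'   frame (epoch, mean training loss on the scaled targets).
#' @export
train_identification <- function(model, image_source, family, ranges = NULL,
                                 config = train_config()) {
  stopifnot(inherits(model, "identification_model"),
            inherits(family, "operator_family"),
            inherits(config, "train_config"))
  if (is.array(image_source) && length(dim(image_source)) == 3)
    image_source <- lapply(seq_len(dim(image_source)[3]),
                           function(i) image_source[, , i])
  n <- length(image_source)
  stopifnot(n >= 1)
  margin <- if (is.null(config$margin)) default_margin(family) else config$margin
  scale <- pmax(abs(family$ranges[, 1]), abs(family$ranges[, 2]))
  scale[scale == 0] <- 1
  model$target_scale <- scale
  # reflection/rotation symmetries of Zernike-pupil kernels: used both as a
  # training-time augmentation and as test-time symmetrization
  zsym <- family$variant == "zernike_conv"
  model$zernike_symmetry <- zsym
  if (zsym) {
    model$flip_signs <- list(v = zernike_flip_signs(family$noll_indices, "v"),
                             h = zernike_flip_signs(family$noll_indices, "h"))
  }
  set.seed(config$seed)
  state <- adam_init(model$params)
  ema_params <- if (!is.null(config$ema)) model$params else NULL
  ema_blend <- function(e, p, d) {
    if (is.list(e)) return(Map(ema_blend, e, p, MoreArgs = list(d = d)))
    d * e + (1 - d) * p
  }
  history <- data.frame(epoch = integer(), loss = numeric())
  p <- family$p
  for (ep in seq_len(config$epochs)) {
    lr_ep <- if (is.null(config$lr_final)) config$lr
             else config$lr * (config$lr_final / config$lr)^
                    ((ep - 1) / max(config$epochs - 1, 1))
    ord <- sample.int(n)
    ep_loss <- 0; n_batches <- 0L
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      B <- length(idx)
      xb <- NULL
      yb <- matrix(0, p, B)
      for (k in seq_len(B)) {
        u <- image_source[[idx[k]]]
        op <- sample_operator(family)   # fresh operator per presentation
        eta <- if (is.null(ranges)) noise_params(0, 0)
               else sample_noise_params(ranges)
        obs <- degrade(u, op, eta, margin = margin)
        bi <- obs$b
        gi <- op$gamma
        if (zsym) {
          tf <- sample.int(4L, 1L)
          if (tf == 2L) {               # vertical reflection
            bi <- bi[rev(seq_len(nrow(bi))), ]
            gi <- model$flip_signs$v * gi
          } else if (tf == 3L) {        # horizontal reflection
            bi <- bi[, rev(seq_len(ncol(bi)))]
            gi <- model$flip_signs$h * gi
          } else if (tf == 4L) {        # 180-degree rotation
            bi <- bi[rev(seq_len(nrow(bi))), rev(seq_len(ncol(bi)))]
            gi <- model$flip_signs$v * model$flip_signs$h * gi
          }
        }
        if (is.null(xb))
          xb <- array(0, c(dim(bi), 1L, B))
        xb[, , 1L, k] <- bi
        yb[, k] <- gi / scale
      }
      fw <- encoder_forward(model, xb, keep = TRUE, training = TRUE)
      model$bn_stats <- fw$bn_stats
      resid <- fw$out - yb
      loss <- mean(resid^2)
      if (!is.finite(loss))
        stop("training diverged at epoch ", ep, ": non-finite loss")
      gout <- 2 * resid / length(resid)
      grads <- encoder_backward(model, fw$cache, gout)
      if (config$weight_decay > 0)
        grads <- add_weight_decay(grads, model$params, config$weight_decay)
      upd <- adam_step(model$params, grads, state, lr = lr_ep,
                       beta1 = config$beta1, beta2 = config$beta2,
                       eps = config$eps)
      model$params <- upd$params
      state <- upd$state
      if (!is.null(ema_params))
        ema_params <- Map(ema_blend, ema_params, model$params,
                          MoreArgs = list(d = config$ema))
      ep_loss <- ep_loss + loss
      n_batches <- n_batches + 1L
    }
    history <- rbind(history,
                     data.frame(epoch = ep, loss = ep_loss / n_batches))
    if (config$verbose)
      message(sprintf("epoch %d: loss %.6f", ep, ep_loss / n_batches))
  }
  if (!is.null(ema_params)) model$params <- ema_params
  list(model = model, history = history)
}

add_weight_decay <- function(grads, params, wd) {
  rec <- function(g, p) {
    if (is.list(g)) return(Map(rec, g, p))
    g + wd * p
  }
  Map(rec, grads, params)
}
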