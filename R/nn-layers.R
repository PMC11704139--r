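# Internal neural-network primitives.  Images move through the layers as
# (H, W, C, N) arrays; convolution weights are (kh, kw, Cin, Cout) arrays.
# Forward passes return the output plus whatever the backward pass needs.
# There is deliberately no autodiff: each architecture hand-codes its
# backward pass, which keeps the dependency footprint at base R + a small
# C++ im2col/GEMM kernel.

as_batch <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L, 1L)
  stopifnot(length(dim(x)) == 4)
  x
}

conv_fwd <- function(x, w, b, stride = 1L, pad = NULL) {
  dx <- dim(x); dw <- dim(w)
  if (is.null(pad)) pad <- (dw[1] - 1L) %/% 2L
  wt <- matrix(w, dw[1] * dw[2] * dw[3], dw[4])
  y <- nn_conv_fwd(array(x, c(dx[1], dx[2], dx[3] * dx[4])), dx[3], dx[4],
                   wt, as.numeric(b), dw[1], dw[2], as.integer(stride),
                   as.integer(pad))
  dy <- dim(y)
  array(y, c(dy[1], dy[2], dw[4], dx[4]))
}

conv_bwd <- function(x, w, gy, stride = 1L, pad = NULL) {
  dx <- dim(x); dw <- dim(w); dgy <- dim(gy)
  if (is.null(pad)) pad <- (dw[1] - 1L) %/% 2L
  wt <- matrix(w, dw[1] * dw[2] * dw[3], dw[4])
  r <- nn_conv_bwd(array(x, c(dx[1], dx[2], dx[3] * dx[4])),
                   array(gy, c(dgy[1], dgy[2], dgy[3] * dgy[4])),
                   dx[3], dx[4], wt, dw[1], dw[2], as.integer(stride),
                   as.integer(pad))
  list(gx = array(r$gx, dx), gw = array(r$gw, dw), gb = as.numeric(r$gb))
}

relu_fwd <- function(x) {
  y <- x
  y[y < 0] <- 0
  y
}

relu_bwd <- function(x, gy) {
  gy[x <= 0] <- 0
  gy
}

# Global average pooling: (H, W, C, N) -> (C, N).
gap_fwd <- function(x) {
  d <- dim(x)
  m <- matrix(x, d[1] * d[2], d[3] * d[4])
  matrix(colMeans(m), d[3], d[4])
}

gap_bwd <- function(dims, g) {
  gx <- array(rep(as.vector(g), each = dims[1] * dims[2]), dims)
  gx / (dims[1] * dims[2])
}

# Adaptive average pooling to a fixed g x g spatial grid (any input size
# >= g): contiguous bins with floor/ceil boundaries, as in the standard
# deep-learning adaptive pool.  (H, W, C, N) -> (g*g*C, N).
adaptive_bins <- function(n, g) {
  lo <- floor((seq_len(g) - 1L) * n / g) + 1L
  hi <- ceiling(seq_len(g) * n / g)
  cbind(lo, hi)
}

apool_fwd <- function(x, g) {
  d <- dim(x)
  bh <- adaptive_bins(d[1], g); bw <- adaptive_bins(d[2], g)
  out <- array(0, c(g, g, d[3], d[4]))
  for (i in seq_len(g)) for (j in seq_len(g)) {
    blk <- x[bh[i, 1]:bh[i, 2], bw[j, 1]:bw[j, 2], , , drop = FALSE]
    out[i, j, , ] <- apply(blk, c(3, 4), mean)
  }
  matrix(out, g * g * d[3], d[4])
}

apool_bwd <- function(dims, g, gout) {
  gx <- array(0, dims)
  ga <- array(gout, c(g, g, dims[3], dims[4]))
  bh <- adaptive_bins(dims[1], g); bw <- adaptive_bins(dims[2], g)
  for (i in seq_len(g)) for (j in seq_len(g)) {
    nh <- bh[i, 2] - bh[i, 1] + 1L; nw <- bw[j, 2] - bw[j, 1] + 1L
    contrib <- ga[i, j, , , drop = FALSE] / (nh * nw)
    gx[bh[i, 1]:bh[i, 2], bw[j, 1]:bw[j, 2], , ] <-
      gx[bh[i, 1]:bh[i, 2], bw[j, 1]:bw[j, 2], , , drop = FALSE] +
      array(rep(as.vector(contrib), each = nh * nw), c(nh, nw, dims[3], dims[4]))
  }
  gx
}

linear_fwd <- function(feat, w, b) w %*% feat + b   # feat: F x N, w: p x F

linear_bwd <- function(feat, w, g) {
  list(gx = crossprod(w, g), gw = tcrossprod(g, feat), gb = rowSums(g))
}

# Nearest-neighbor 2x upsampling and its adjoint (sum pooling).
upsample2_fwd <- function(x) {
  d <- dim(x)
  idx_h <- rep(seq_len(d[1]), each = 2L)
  idx_w <- rep(seq_len(d[2]), each = 2L)
  x[idx_h, idx_w, , , drop = FALSE]
}

upsample2_bwd <- function(g) {
  d <- dim(g)
  h <- d[1] %/% 2L; w <- d[2] %/% 2L
  g1 <- g[seq(1, 2 * h, 2), seq(1, 2 * w, 2), , , drop = FALSE] +
        g[seq(2, 2 * h, 2), seq(1, 2 * w, 2), , , drop = FALSE] +
        g[seq(1, 2 * h, 2), seq(2, 2 * w, 2), , , drop = FALSE] +
        g[seq(2, 2 * h, 2), seq(2, 2 * w, 2), , , drop = FALSE]
  g1
}

# Batch normalization over (H, W, N) per channel.  Trainable scale/shift
# live with the other parameters; running statistics are buffers carried on
# the model and updated only during training-mode forward passes.
bn_init <- function(C) list(gamma = rep(1, C), beta = rep(0, C))

bn_stats_init <- function(C) list(mean = rep(0, C), var = rep(1, C))

# x: (H, W, C, N).  Returns y, cache for backward, and updated running stats.
bn_fwd <- function(x, par, stats, training, momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  r <- nn_bn_fwd(array(x, c(d[1], d[2], d[3] * d[4])), d[3], d[4],
                 par$gamma, par$beta, stats$mean, stats$var,
                 training, momentum, eps)
  list(y = array(r$y, d), stats = list(mean = as.numeric(r$mean),
                                       var = as.numeric(r$var)),
       cache = list(xhat = r$xhat, inv_std = as.numeric(r$inv_std),
                    dims = d, training = training))
}

bn_bwd <- function(cache, par, g) {
  d <- cache$dims
  r <- nn_bn_bwd(array(g, c(d[1], d[2], d[3] * d[4])), cache$xhat,
                 cache$inv_std, par$gamma, d[3], d[4], cache$training)
  list(gx = array(r$gx, d), ggamma = as.numeric(r$ggamma),
       gbeta = as.numeric(r$gbeta))
}

# He-scaled initializers; all randomness through the R RNG.
init_conv <- function(kh, kw, cin, cout, gain = 1) {
  sd <- gain * sqrt(2 / (kh * kw * cin))
  list(w = array(stats::rnorm(kh * kw * cin * cout, 0, sd),
                 c(kh, kw, cin, cout)),
       b = numeric(cout))
}

init_linear <- function(fin, fout, gain = 1) {
  sd <- gain * sqrt(2 / fin)
  list(w = matrix(stats::rnorm(fin * fout, 0, sd), fout, fin),
       b = numeric(fout))
}

# Adam over an arbitrarily nested list of numeric arrays.
adam_init <- function(params) {
  zero <- function(p) if (is.list(p)) lapply(p, zero) else p * 0
  list(m = zero(params), v = zero(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(upd, p, g, m, v)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  out <- Map(upd, params, grads, state$m, state$v)
  list(params = lapply(out, `[[`, "p"),
       state = list(m = lapply(out, `[[`, "m"),
                    v = lapply(out, `[[`, "v"), t = t))
}
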