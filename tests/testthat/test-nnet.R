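# The convolution/backprop primitives behind both networks.

test_that("batched convolution matches a direct triple-loop oracle", {
  set.seed(61)
  H <- 6L; W <- 5L; Cin <- 2L; Cout <- 3L; N <- 2L
  x <- array(rnorm(H * W * Cin * N), c(H, W, Cin, N))
  w <- array(rnorm(3 * 3 * Cin * Cout), c(3, 3, Cin, Cout))
  b <- rnorm(Cout)
  for (stride in c(1L, 2L)) {
    y <- varblur:::conv_fwd(x, w, b, stride = stride)
    pad <- 1L
    Ho <- (H + 2 * pad - 3) %/% stride + 1L
    Wo <- (W + 2 * pad - 3) %/% stride + 1L
    ref <- array(0, c(Ho, Wo, Cout, N))
    for (n in 1:N) for (co in 1:Cout) for (ho in 1:Ho) for (wo in 1:Wo) {
      acc <- b[co]
      for (ci in 1:Cin) for (ki in 1:3) for (kj in 1:3) {
        ih <- (ho - 1) * stride + ki - pad
        iw <- (wo - 1) * stride + kj - pad
        if (ih >= 1 && ih <= H && iw >= 1 && iw <= W)
          acc <- acc + w[ki, kj, ci, co] * x[ih, iw, ci, n]
      }
      ref[ho, wo, co, n] <- acc
    }
    expect_equal(y, ref, tolerance = 1e-12)
  }
})

test_that("convolution backward passes a finite-difference check", {
  set.seed(62)
  x <- array(rnorm(7 * 7 * 2 * 2), c(7, 7, 2, 2))
  w <- array(rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3))
  b <- rnorm(3)
  g <- array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2))
  bw <- varblur:::conv_bwd(x, w, g, stride = 2L)
  lossf <- function(xx, ww, bb)
    sum(varblur:::conv_fwd(xx, ww, bb, stride = 2L) * g)
  eps <- 1e-6
  for (probe in list(c(2, 3, 1, 1), c(5, 5, 2, 2))) {
    xp <- x; xp[probe[1], probe[2], probe[3], probe[4]] <- xp[probe[1], probe[2], probe[3], probe[4]] + eps
    xm <- x; xm[probe[1], probe[2], probe[3], probe[4]] <- xm[probe[1], probe[2], probe[3], probe[4]] - eps
    num <- (lossf(xp, w, b) - lossf(xm, w, b)) / (2 * eps)
    expect_equal(num, bw$gx[probe[1], probe[2], probe[3], probe[4]],
                 tolerance = 1e-5)
  }
  wp <- w; wp[1, 2, 2, 3] <- wp[1, 2, 2, 3] + eps
  wm <- w; wm[1, 2, 2, 3] <- wm[1, 2, 2, 3] - eps
  expect_equal((lossf(x, wp, b) - lossf(x, wm, b)) / (2 * eps),
               bw$gw[1, 2, 2, 3], tolerance = 1e-5)
  bp <- b; bp[2] <- bp[2] + eps
  bm <- b; bm[2] <- bm[2] - eps
  expect_equal((lossf(x, w, bp) - lossf(x, w, bm)) / (2 * eps), bw$gb[2],
               tolerance = 1e-5)
})

test_that("encoder backprop is exact against finite differences", {
  set.seed(63)
  m <- init_identification_model(2, "tiny", seed = 3)
  x <- array(runif(17 * 17), c(17, 17, 1, 1))
  y <- matrix(c(0.3, -0.2), 2, 1)
  fw <- varblur:::encoder_forward(m, x, keep = TRUE)
  g <- varblur:::encoder_backward(m, fw$cache, 2 * (fw$out - y) / 2)
  lossf <- function(mm) mean((varblur:::encoder_forward(mm, x)$out - y)^2)
  eps <- 1e-5
  mp <- m; mp$params$stem$w[2, 2, 1, 4] <- mp$params$stem$w[2, 2, 1, 4] + eps
  mm2 <- m; mm2$params$stem$w[2, 2, 1, 4] <- mm2$params$stem$w[2, 2, 1, 4] - eps
  expect_equal((lossf(mp) - lossf(mm2)) / (2 * eps), g$stem$w[2, 2, 1, 4],
               tolerance = 1e-4)
  mp <- m; mp$params$fc$w[1, 7] <- mp$params$fc$w[1, 7] + eps
  mm2 <- m; mm2$params$fc$w[1, 7] <- mm2$params$fc$w[1, 7] - eps
  expect_equal((lossf(mp) - lossf(mm2)) / (2 * eps), g$fc$w[1, 7],
               tolerance = 1e-4)
})

test_that("prox-network backprop is exact against finite differences", {
  set.seed(64)
  px <- init_prox_network("tiny_unet", seed = 5)
  x <- array(runif(12 * 12), c(12, 12, 1, 1))
  g <- array(rnorm(12 * 12), c(12, 12, 1, 1))
  fw <- varblur:::prox_forward(px, x, keep = TRUE)
  bw <- varblur:::prox_backward(px, fw$cache, g)
  lossf <- function(pp) sum(varblur:::prox_forward(pp, x)$out * g)
  eps <- 1e-6
  for (nm in c("c1", "down", "c5")) {
    pp <- px; pp$params[[nm]]$w[2, 2, 1, 1] <- pp$params[[nm]]$w[2, 2, 1, 1] + eps
    pm <- px; pm$params[[nm]]$w[2, 2, 1, 1] <- pm$params[[nm]]$w[2, 2, 1, 1] - eps
    expect_equal((lossf(pp) - lossf(pm)) / (2 * eps), bw$grads[[nm]]$w[2, 2, 1, 1],
                 tolerance = 1e-4)
  }
  # input gradient
  i <- 40L
  xp <- x; xp[i] <- xp[i] + eps
  xm <- x; xm[i] <- xm[i] - eps
  expect_equal((sum(varblur:::prox_forward(px, xp)$out * g) -
                sum(varblur:::prox_forward(px, xm)$out * g)) / (2 * eps),
               bw$gx[i], tolerance = 1e-4)
})

test_that("Adam reproduces the hand-computed first update", {
  params <- list(a = matrix(1, 1, 1))
  grads <- list(a = matrix(0.5, 1, 1))
  st <- varblur:::adam_init(params)
  upd <- varblur:::adam_step(params, grads, st, lr = 0.1)
  # first step: m_hat = g, v_hat = g^2 -> update = lr * g/(|g| + eps)
  expect_equal(upd$params$a[1, 1], 1 - 0.1 * 0.5 / (0.5 + 1e-8),
               tolerance = 1e-12)
})
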