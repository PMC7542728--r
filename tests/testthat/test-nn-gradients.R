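# Backward passes are validated against central finite differences — the
# independent oracle for every hand-written gradient in the package.

cs <- asNamespace("cardiosynth")

num_grad <- function(f, x, eps = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

test_that("layer backward passes match finite differences", {
  set.seed(42)
  checks <- list(
    list(layer = cs$lyr_conv(3, 3, 2, 3), dims = c(5, 5, 2, 2)),
    list(layer = cs$lyr_conv(4, 4, 2, 3, pad = 0L), dims = c(4, 4, 2, 2)),
    list(layer = cs$lyr_pixelnorm(1e-8), dims = c(3, 3, 4, 2)),
    list(layer = cs$lyr_mbstd(), dims = c(2, 2, 3, 4)),
    list(layer = cs$lyr_maxpool2(), dims = c(4, 4, 3, 2)),
    list(layer = cs$lyr_avgpool2(), dims = c(4, 4, 3, 2)),
    list(layer = cs$lyr_upsample2(), dims = c(4, 4, 3, 2)),
    list(layer = cs$lyr_d2s(), dims = c(3, 3, 8, 2)),
    list(layer = cs$lyr_lrelu(0.2), dims = c(4, 4, 2, 2))
  )
  for (ck in checks) {
    x <- array(rnorm(prod(ck$dims)), ck$dims)
    f <- cs$layer_fwd(ck$layer, x)
    gy <- array(rnorm(length(f$y)), dim(f$y))
    b <- cs$layer_bwd(ck$layer, f$cache, gy)
    loss <- function(xv) sum(cs$layer_fwd(ck$layer, array(xv, ck$dims))$y * gy)
    expect_lt(max(abs(num_grad(loss, as.vector(x)) - as.vector(b$gx))), 1e-6,
              label = paste("gx for", ck$layer$kind))
    if (!is.null(b$grads$w)) {
      l2 <- ck$layer
      loss_w <- function(wv) {
        l2$w <- array(wv, dim(ck$layer$w))
        sum(cs$layer_fwd(l2, x)$y * gy)
      }
      expect_lt(max(abs(num_grad(loss_w, as.vector(ck$layer$w)) -
                          as.vector(b$grads$w))), 1e-6,
                label = paste("gw for", ck$layer$kind))
    }
  }
})

test_that("generator and critic backward passes (with fade-in) match finite differences", {
  set.seed(7)
  cfg <- gan_config(latent_dim = 6, max_resolution = 16,
                    filters_per_stage = c(5, 4, 3))
  m <- cs$gan_new(cfg, 3)
  z <- matrix(rnorm(12), 6, 2)
  fw <- cs$gen_forward(m$generator, z, 1L, 0.4)
  gy <- array(rnorm(length(fw$y)), dim(fw$y))
  bw <- cs$gen_backward(m$generator, fw, gy)
  lo <- function(zv) sum(cs$gen_forward(m$generator, matrix(zv, 6, 2), 1L, 0.4)$y * gy)
  expect_lt(max(abs(num_grad(lo, as.vector(z)) - as.vector(bw$gz))), 1e-6)
  w0 <- m$generator$blocks[[2]][[2]]$w
  low <- function(wv) {
    g2 <- m$generator
    g2$blocks[[2]][[2]]$w <- array(wv, dim(w0))
    sum(cs$gen_forward(g2, z, 1L, 0.4)$y * gy)
  }
  expect_lt(max(abs(num_grad(low, as.vector(w0)) -
                      as.vector(bw$grads$blocks[[2]][[2]]$w))), 1e-6)

  img <- array(rnorm(8 * 8 * 3), c(8, 8, 1, 3))
  fc <- cs$crit_forward(m$critic, img, 1L, 0.4)
  gs <- rnorm(3)
  bc <- cs$crit_backward(m$critic, fc, gs)
  loc <- function(xv) sum(cs$crit_forward(m$critic, array(xv, dim(img)), 1L, 0.4)$scores * gs)
  expect_lt(max(abs(num_grad(loc, as.vector(img)) - as.vector(bc$g_img))), 1e-6)
  wc <- m$critic$blocks[[1]][[2]]$w
  locw <- function(wv) {
    c2 <- m$critic
    c2$blocks[[1]][[2]]$w <- array(wv, dim(wc))
    sum(cs$crit_forward(c2, img, 1L, 0.4)$scores * gs)
  }
  expect_lt(max(abs(num_grad(locw, as.vector(wc)) -
                      as.vector(bc$grads$blocks[[1]][[2]]$w))), 1e-6)
})

test_that("U-Net backward pass matches finite differences through the loss", {
  set.seed(9)
  ucfg <- unet_config(input_resolution = 8, n_classes = 3, depth = 2,
                      base_channels = 4)
  net <- cs$unet_new(ucfg, 5)
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 1, 2))
  mask <- matrix(sample(0:2, 64, TRUE), 8, 8)
  oh <- array(0, c(8, 8, 3, 2))
  for (k in 1:3) for (n in 1:2) oh[, , k, n] <- mask == (k - 1)
  fw <- cs$unet_forward(net, x)
  sc <- cs$softmax_ce(fw$y, oh)
  g <- cs$unet_backward(net, fw, sc$grad)
  for (probe in list(c("enc", 1, 1), c("up", 2, 1), c("final", 1))) {
    getw <- function(n) if (length(probe) == 3)
      n[[probe[1]]][[as.integer(probe[2])]][[as.integer(probe[3])]]$w
    else n[[probe[1]]][[as.integer(probe[2])]]$w
    w0 <- getw(net)
    lo <- function(wv) {
      n2 <- net
      if (length(probe) == 3)
        n2[[probe[1]]][[as.integer(probe[2])]][[as.integer(probe[3])]]$w <- array(wv, dim(w0))
      else n2[[probe[1]]][[as.integer(probe[2])]]$w <- array(wv, dim(w0))
      cs$softmax_ce(cs$unet_forward(n2, x)$y, oh)$loss
    }
    gw <- if (length(probe) == 3)
      g[[probe[1]]][[as.integer(probe[2])]][[as.integer(probe[3])]]$w
    else g[[probe[1]]][[as.integer(probe[2])]]$w
    expect_lt(max(abs(num_grad(lo, as.vector(w0)) - as.vector(gw))), 1e-6,
              label = paste("unet", paste(probe, collapse = "/")))
  }
})
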