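# Minimal neural-network core: stride-1 conv layers (C++ back-end), pooling,
# upsampling, activations, pixelwise feature normalization, minibatch-stddev,
# dense layers, sequential chains with hand-written backprop, and Adam.
# All tensors are R arrays laid out [H, W, C, N]; latent batches are matrices
# [dim, N]. Every backward pass is validated against finite differences in the
# test suite.

new_layer <- function(kind, ...) {
  structure(list(kind = kind, ...), class = "cs_layer")
}

#' @noRd
lyr_conv <- function(kh, kw, cin, cout, pad = NULL, gain = sqrt(2)) {
  if (is.null(pad)) pad <- (kh - 1L) %/% 2L
  w <- array(stats::rnorm(kh * kw * cin * cout, sd = gain / sqrt(kh * kw * cin)),
             dim = c(kh, kw, cin, cout))
  new_layer("conv", w = w, b = numeric(cout), pad = as.integer(pad))
}

lyr_dense <- function(nin, nout, gain = 1) {
  w <- matrix(stats::rnorm(nin * nout, sd = gain / sqrt(nin)), nin, nout)
  new_layer("dense", w = w, b = numeric(nout))
}

lyr_reshape <- function(h, w, c) new_layer("reshape", h = h, w = w, c = c)
lyr_lrelu <- function(leak = 0.2) new_layer("lrelu", leak = leak)
lyr_relu <- function() new_layer("lrelu", leak = 0)
lyr_pixelnorm <- function(eps = 1e-8) new_layer("pixelnorm", eps = eps)
lyr_mbstd <- function() new_layer("mbstd")
lyr_upsample2 <- function() new_layer("upsample2")
lyr_avgpool2 <- function() new_layer("avgpool2")
lyr_maxpool2 <- function() new_layer("maxpool2")
lyr_d2s <- function() new_layer("d2s")
lyr_flatten <- function() new_layer("flatten")

# ---- primitive ops -----------------------------------------------------------

nn_upsample2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , , drop = FALSE]
}

nn_upsample2_bwd <- function(gy) {
  d <- dim(gy)
  o1 <- seq(1L, d[1], 2L); o2 <- seq(1L, d[2], 2L)
  gy[o1, o2, , , drop = FALSE] + gy[o1 + 1L, o2, , , drop = FALSE] +
    gy[o1, o2 + 1L, , , drop = FALSE] + gy[o1 + 1L, o2 + 1L, , , drop = FALSE]
}

nn_avgpool2 <- function(x) {
  d <- dim(x)
  o1 <- seq(1L, d[1], 2L); o2 <- seq(1L, d[2], 2L)
  (x[o1, o2, , , drop = FALSE] + x[o1 + 1L, o2, , , drop = FALSE] +
     x[o1, o2 + 1L, , , drop = FALSE] + x[o1 + 1L, o2 + 1L, , , drop = FALSE]) / 4
}

nn_avgpool2_bwd <- function(gy) nn_upsample2(gy) / 4

pixelnorm_fwd <- function(x, eps) {
  d <- dim(x)
  ms <- array(0, c(d[1], d[2], 1L, d[4]))
  for (n in seq_len(d[4])) {
    xm <- matrix(x[, , , n], d[1] * d[2], d[3])
    ms[, , 1L, n] <- rowSums(xm * xm) / d[3]
  }
  r <- sqrt(ms + eps)
  y <- x / r[, , rep(1L, d[3]), , drop = FALSE]
  list(y = y, r = r)
}

pixelnorm_bwd <- function(x, r, gy, eps) {
  d <- dim(x)
  rb <- r[, , rep(1L, d[3]), , drop = FALSE]
  s <- array(0, c(d[1], d[2], 1L, d[4]))
  for (n in seq_len(d[4])) {
    gm <- matrix(gy[, , , n] * x[, , , n], d[1] * d[2], d[3])
    s[, , 1L, n] <- rowSums(gm)
  }
  sb <- s[, , rep(1L, d[3]), , drop = FALSE]
  gy / rb - x * sb / (d[3] * rb^3)
}

#' Append a minibatch standard deviation channel
#'
#' Computes, for a feature batch, the across-batch (population) standard
#' deviation of every feature, averages those standard deviations, and appends
#' the resulting scalar as an extra constant channel. Used in the critic to
#' expose batch diversity and discourage mode collapse.
#'
#' @param x Numeric array `[H, W, C, N]`.
#' @return Numeric array `[H, W, C + 1, N]`; the appended channel is constant.
#' @export
minibatch_stddev_channel <- function(x) {
  stopifnot(is.array(x), length(dim(x)) == 4L)
  mbstd_fwd(x)$y
}

mbstd_fwd <- function(x) {
  d <- dim(x)
  n <- d[4]
  mu <- apply(x, c(1, 2, 3), mean)
  v <- apply(x, c(1, 2, 3), function(z) mean((z - mean(z))^2))
  sdv <- sqrt(v)
  s <- mean(sdv)
  y <- array(0, c(d[1], d[2], d[3] + 1L, n))
  y[, , seq_len(d[3]), ] <- x
  y[, , d[3] + 1L, ] <- s
  list(y = y, mu = mu, sdv = sdv)
}

mbstd_bwd <- function(x, mu, sdv, gy) {
  d <- dim(x)
  gs <- sum(gy[, , d[3] + 1L, , drop = FALSE])
  gx <- gy[, , seq_len(d[3]), , drop = FALSE]
  denom <- sdv * (d[4] * prod(d[1:3]))
  inv <- ifelse(sdv > 0, 1 / denom, 0)
  mb <- array(mu, c(d[1:3], d[4]))
  ib <- array(inv, c(d[1:3], d[4]))
  gx + gs * (x - mb) * ib
}

nn_maxpool2 <- function(x) {
  d <- dim(x)
  o1 <- seq(1L, d[1], 2L); o2 <- seq(1L, d[2], 2L)
  a <- x[o1, o2, , , drop = FALSE]; b <- x[o1 + 1L, o2, , , drop = FALSE]
  cc <- x[o1, o2 + 1L, , , drop = FALSE]; dd <- x[o1 + 1L, o2 + 1L, , , drop = FALSE]
  y <- pmax(a, b, cc, dd)
  ma <- a == y
  mb <- (b == y) & !ma
  mc <- (cc == y) & !(ma | mb)
  md <- !(ma | mb | mc)
  list(y = y, masks = list(ma, mb, mc, md))
}

nn_maxpool2_bwd <- function(gy, masks) {
  d <- dim(gy)
  gx <- array(0, c(2L * d[1], 2L * d[2], d[3], d[4]))
  o1 <- seq(1L, 2L * d[1], 2L); o2 <- seq(1L, 2L * d[2], 2L)
  gx[o1, o2, , ] <- gy * masks[[1]]
  gx[o1 + 1L, o2, , ] <- gy * masks[[2]]
  gx[o1, o2 + 1L, , ] <- gy * masks[[3]]
  gx[o1 + 1L, o2 + 1L, , ] <- gy * masks[[4]]
  gx
}

# depth-to-space, block 2: [H, W, 4C, N] -> [2H, 2W, C, N]; channel group g
# (0..3) lands at spatial offset (g %% 2, g %/% 2). Together with a 1x1 conv
# this realizes a 2x2 up-convolution (transposed conv, stride 2).
nn_d2s <- function(x) {
  d <- dim(x)
  c_out <- d[3] %/% 4L
  y <- array(0, c(2L * d[1], 2L * d[2], c_out, d[4]))
  o1 <- seq(1L, 2L * d[1], 2L); o2 <- seq(1L, 2L * d[2], 2L)
  for (g in 0:3) {
    ch <- seq_len(c_out) + g * c_out
    y[o1 + g %% 2L, o2 + g %/% 2L, , ] <- x[, , ch, , drop = FALSE]
  }
  y
}

nn_d2s_bwd <- function(gy) {
  d <- dim(gy)
  h <- d[1] %/% 2L; w <- d[2] %/% 2L
  gx <- array(0, c(h, w, 4L * d[3], d[4]))
  o1 <- seq(1L, d[1], 2L); o2 <- seq(1L, d[2], 2L)
  for (g in 0:3) {
    ch <- seq_len(d[3]) + g * d[3]
    gx[, , ch, ] <- gy[o1 + g %% 2L, o2 + g %/% 2L, , , drop = FALSE]
  }
  gx
}

# ---- layer dispatch ----------------------------------------------------------

layer_fwd <- function(l, x) {
  switch(l$kind,
    conv = list(y = .conv2d_fwd(x, l$w, l$b, l$pad), cache = x),
    dense = {
      xm <- if (is.matrix(x)) x else matrix(x, nrow = prod(dim(x)[1:3]))
      list(y = crossprod(l$w, xm) + l$b, cache = list(xm = xm, dims = dim(x)))
    },
    reshape = {
      n <- ncol(x)
      list(y = array(x, c(l$h, l$w, l$c, n)), cache = NULL)
    },
    flatten = list(y = matrix(x, nrow = prod(dim(x)[1:3])), cache = dim(x)),
    lrelu = {
      m <- x > 0
      list(y = x * m + l$leak * (x * !m), cache = m)
    },
    pixelnorm = {
      f <- pixelnorm_fwd(x, l$eps)
      list(y = f$y, cache = list(x = x, r = f$r))
    },
    mbstd = {
      f <- mbstd_fwd(x)
      list(y = f$y, cache = list(x = x, mu = f$mu, sdv = f$sdv))
    },
    upsample2 = list(y = nn_upsample2(x), cache = NULL),
    avgpool2 = list(y = nn_avgpool2(x), cache = NULL),
    maxpool2 = {
      f <- nn_maxpool2(x)
      list(y = f$y, cache = f$masks)
    },
    d2s = list(y = nn_d2s(x), cache = NULL),
    stop("unknown layer kind: ", l$kind)
  )
}

layer_bwd <- function(l, cache, gy) {
  switch(l$kind,
    conv = {
      g <- .conv2d_bwd(cache, l$w, gy, l$pad)
      list(gx = g$gx, grads = list(w = g$gw, b = g$gb))
    },
    dense = {
      gx <- l$w %*% gy
      if (length(cache$dims) == 4L) gx <- array(gx, cache$dims)
      list(gx = gx,
           grads = list(w = cache$xm %*% t(gy), b = rowSums(gy)))
    },
    reshape = list(gx = matrix(gy, nrow = l$h * l$w * l$c), grads = NULL),
    flatten = list(gx = array(gy, cache), grads = NULL),
    lrelu = list(gx = gy * cache + l$leak * (gy * !cache), grads = NULL),
    pixelnorm = list(gx = pixelnorm_bwd(cache$x, cache$r, gy, l$eps), grads = NULL),
    mbstd = list(gx = mbstd_bwd(cache$x, cache$mu, cache$sdv, gy), grads = NULL),
    upsample2 = list(gx = nn_upsample2_bwd(gy), grads = NULL),
    avgpool2 = list(gx = nn_avgpool2_bwd(gy), grads = NULL),
    maxpool2 = list(gx = nn_maxpool2_bwd(gy, cache), grads = NULL),
    d2s = list(gx = nn_d2s_bwd(gy), grads = NULL),
    stop("unknown layer kind: ", l$kind)
  )
}

chain_fwd <- function(layers, x) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    f <- layer_fwd(layers[[i]], x)
    x <- f$y
    caches[[i]] <- f$cache
  }
  list(y = x, caches = caches)
}

chain_bwd <- function(layers, caches, gy) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    b <- layer_bwd(layers[[i]], caches[[i]], gy)
    gy <- b$gx
    grads[i] <- list(b$grads) # keep NULL placeholders for parameterless layers
  }
  list(gx = gy, grads = grads)
}

# ---- parameter trees and Adam ------------------------------------------------

is_layer <- function(x) inherits(x, "cs_layer")

# walk two parallel trees (model, grads); f(layer, grad) returns updated layer
tree_update <- function(model, grads, f) {
  if (is_layer(model)) return(f(model, grads))
  if (is.list(model)) {
    for (i in seq_along(model)) {
      if (is.null(grads[[i]])) next
      model[[i]] <- tree_update(model[[i]], grads[[i]], f)
    }
  }
  model
}

tree_scale_acc <- function(acc, grads, scale = 1) {
  # acc <- acc + scale * grads, matching structure; NULLs pass through
  if (is.null(grads)) return(acc)
  if (is.numeric(grads)) {
    if (is.null(acc)) return(scale * grads)
    return(acc + scale * grads)
  }
  if (is.null(acc)) acc <- vector("list", length(grads))
  for (i in seq_along(grads))
    acc[i] <- list(tree_scale_acc(acc[[i]], grads[[i]], scale))
  names(acc) <- names(grads)
  acc
}

adam_new <- function(lr = 1e-3, beta1 = 0, beta2 = 0.99, eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L, state = list())
}

adam_step <- function(opt, model, grads) {
  opt$t <- opt$t + 1L
  st <- opt$state
  path <- character(0)
  upd <- function(m, g) {
    for (nm in c("w", "b")) {
      if (is.null(g[[nm]])) next
      k <- paste(c(path, nm), collapse = "/")
      if (is.null(st[[k]])) st[[k]] <<- list(m1 = 0 * g[[nm]], m2 = 0 * g[[nm]])
      s <- st[[k]]
      s$m1 <- opt$beta1 * s$m1 + (1 - opt$beta1) * g[[nm]]
      s$m2 <- opt$beta2 * s$m2 + (1 - opt$beta2) * g[[nm]]^2
      st[[k]] <<- s
      mhat <- s$m1 / (1 - opt$beta1^opt$t)
      vhat <- s$m2 / (1 - opt$beta2^opt$t)
      m[[nm]] <- m[[nm]] - opt$lr * mhat / (sqrt(vhat) + opt$eps)
    }
    m
  }
  # stable path-based state keys: blocks untouched in early growth stages must
  # not shift the keys of later ones
  walk <- function(m, g, p) {
    if (is_layer(m)) {
      path <<- p
      return(upd(m, g))
    }
    if (is.list(m)) {
      for (i in seq_along(m)) {
        if (is.null(g[[i]])) next
        m[[i]] <- walk(m[[i]], g[[i]], c(p, as.character(i)))
      }
    }
    m
  }
  model <- walk(model, grads, character(0))
  opt$state <- st
  list(opt = opt, model = model)
}

clip_weights <- function(model, clip) {
  tree_update(model, model, function(m, g) {
    m$w <- pmin(pmax(m$w, -clip), clip)
    m
  })
}
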