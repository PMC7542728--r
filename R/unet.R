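# U-Net chamber segmentation: symmetric encoder/decoder with channel doubling
# per contraction step, concatenation skip connections, same-padded 3x3
# convolutions (output maps keep the input size), 2x2 max pooling, and 2x2
# up-convolutions realized as a 1x1 convolution followed by depth-to-space.
# Per-pixel multi-class cross-entropy over softmax maps; argmax prediction
# with ties broken toward the lowest class index.

#' U-Net configuration
#'
#' @param input_resolution Input side length (default 128); must be divisible
#'   by `2^depth`.
#' @param n_classes Output classes including background: 3 for SAX
#'   (background, LV, RV), 4 for LAX (+ RA).
#' @param depth Number of pooling steps (default 4).
#' @param base_channels Channels of the first level (default 64); doubled at
#'   every contraction step.
#' @param channel_growth Per-step channel multiplier (default 2).
#' @return A validated `unet_config`.
#' @export
unet_config <- function(input_resolution = 128, n_classes = 3, depth = 4,
                        base_channels = 64, channel_growth = 2) {
  cfg <- structure(list(input_resolution = as.integer(input_resolution),
                        input_channels = 1L,
                        n_classes = as.integer(n_classes),
                        depth = as.integer(depth),
                        base_channels = as.integer(base_channels),
                        channel_growth = channel_growth),
                   class = "unet_config")
  if (cfg$n_classes < 2) cs_abort("n_classes must be >= 2", "cs_config_error")
  if (cfg$input_resolution %% 2^cfg$depth != 0)
    cs_abort("input_resolution must be divisible by 2^depth", "cs_config_error")
  cfg
}

unet_channels <- function(cfg) as.integer(cfg$base_channels * cfg$channel_growth^(0:cfg$depth))

#' Declarative U-Net architecture spec
#'
#' Lists the contracting path (two 3x3 convolutions + ReLU per level, 2x2 max
#' pooling between levels, channels doubling at each step), the bottleneck,
#' and the expanding path (2x2 up-convolution, concatenation with the
#' matching encoder level, two 3x3 convolutions), ending in a 1x1 map to
#' `n_classes` maps of the input size.
#'
#' @param config A [unet_config()].
#' @return An `architecture_spec` with `encoder_channels`,
#'   `bottleneck_channels`, `n_concat` junctions and a `blocks` tibble.
#' @export
build_unet_spec <- function(config) {
  stopifnot(inherits(config, "unet_config"))
  ch <- unet_channels(config)
  res <- config$input_resolution %/% 2^(0:config$depth)
  rows <- list()
  add <- function(kind, cin, cout, r) rows[[length(rows) + 1L]] <<-
    spec_block(kind, cin, cout, r, if (kind == "conv3x3") "relu" else "linear", 0)
  cin <- config$input_channels
  for (l in seq_len(config$depth)) {
    add("conv3x3", cin, ch[l], res[l]); add("conv3x3", ch[l], ch[l], res[l])
    add("maxpool2x", ch[l], ch[l], res[l + 1])
    cin <- ch[l]
  }
  add("conv3x3", cin, ch[config$depth + 1L], res[config$depth + 1L])
  add("conv3x3", ch[config$depth + 1L], ch[config$depth + 1L], res[config$depth + 1L])
  for (l in rev(seq_len(config$depth))) {
    add("upconv2x2", ch[l + 1L], ch[l], res[l])
    add("concat", ch[l] + ch[l], ch[l] + ch[l], res[l])
    add("conv3x3", 2L * ch[l], ch[l], res[l]); add("conv3x3", ch[l], ch[l], res[l])
  }
  add("to_classmaps", ch[1], config$n_classes, res[1])
  structure(list(network = "unet",
                 blocks = do.call(rbind, rows),
                 encoder_channels = ch[seq_len(config$depth)],
                 bottleneck_channels = ch[config$depth + 1L],
                 n_concat = config$depth,
                 input_resolution = config$input_resolution,
                 output_resolution = config$input_resolution,
                 n_classes = config$n_classes),
            class = "architecture_spec")
}

unet_new <- function(config, rng_seed = 1L) {
  ch <- unet_channels(config)
  d <- config$depth
  with_seed(rng_seed, {
    enc <- vector("list", d)
    cin <- config$input_channels
    for (l in seq_len(d)) {
      enc[[l]] <- list(lyr_conv(3, 3, cin, ch[l]), lyr_relu(),
                       lyr_conv(3, 3, ch[l], ch[l]), lyr_relu())
      cin <- ch[l]
    }
    bott <- list(lyr_conv(3, 3, ch[d], ch[d + 1L]), lyr_relu(),
                 lyr_conv(3, 3, ch[d + 1L], ch[d + 1L]), lyr_relu())
    up <- vector("list", d)
    dec <- vector("list", d)
    for (l in rev(seq_len(d))) {
      up[[l]] <- list(lyr_conv(1, 1, ch[l + 1L], 4L * ch[l]), lyr_d2s())
      dec[[l]] <- list(lyr_conv(3, 3, 2L * ch[l], ch[l]), lyr_relu(),
                       lyr_conv(3, 3, ch[l], ch[l]), lyr_relu())
    }
    final <- list(lyr_conv(1, 1, ch[1], config$n_classes, gain = 1))
    list(enc = enc, bott = bott, up = up, dec = dec, final = final)
  })
}

unet_forward <- function(net, x) {
  d <- length(net$enc)
  enc_caches <- vector("list", d)
  pool_caches <- vector("list", d)
  skips <- vector("list", d)
  for (l in seq_len(d)) {
    f <- chain_fwd(net$enc[[l]], x)
    enc_caches[[l]] <- f$caches
    skips[[l]] <- f$y
    p <- nn_maxpool2(f$y)
    pool_caches[[l]] <- p$masks
    x <- p$y
  }
  fb <- chain_fwd(net$bott, x)
  x <- fb$y
  up_caches <- vector("list", d)
  dec_caches <- vector("list", d)
  cat_dims <- vector("list", d)
  for (l in rev(seq_len(d))) {
    fu <- chain_fwd(net$up[[l]], x)
    up_caches[[l]] <- fu$caches
    xc <- abind4(fu$y, skips[[l]])
    cat_dims[[l]] <- dim(fu$y)[3]
    fd <- chain_fwd(net$dec[[l]], xc)
    dec_caches[[l]] <- fd$caches
    x <- fd$y
  }
  ff <- chain_fwd(net$final, x)
  list(y = ff$y, enc_caches = enc_caches, pool_caches = pool_caches,
       bott_cache = fb$caches, up_caches = up_caches, dec_caches = dec_caches,
       final_cache = ff$caches, cat_dims = cat_dims)
}

abind4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

unet_backward <- function(net, fwd, gy) {
  d <- length(net$enc)
  g <- list(enc = vector("list", d), bott = NULL, up = vector("list", d),
            dec = vector("list", d), final = NULL)
  bf <- chain_bwd(net$final, fwd$final_cache, gy)
  g$final <- bf$grads
  gx <- bf$gx
  g_skip <- vector("list", d)
  for (l in seq_len(d)) {
    bd <- chain_bwd(net$dec[[l]], fwd$dec_caches[[l]], gx)
    g$dec[[l]] <- bd$grads
    cu <- fwd$cat_dims[[l]]
    g_up <- bd$gx[, , seq_len(cu), , drop = FALSE]
    g_skip[[l]] <- bd$gx[, , cu + seq_len(dim(bd$gx)[3] - cu), , drop = FALSE]
    bu <- chain_bwd(net$up[[l]], fwd$up_caches[[l]], g_up)
    g$up[[l]] <- bu$grads
    gx <- bu$gx
  }
  bb <- chain_bwd(net$bott, fwd$bott_cache, gx)
  g$bott <- bb$grads
  gx <- bb$gx
  for (l in rev(seq_len(d))) {
    gp <- nn_maxpool2_bwd(gx, fwd$pool_caches[[l]]) + g_skip[[l]]
    be <- chain_bwd(net$enc[[l]], fwd$enc_caches[[l]], gp)
    g$enc[[l]] <- be$grads
    gx <- be$gx
  }
  g
}

softmax_ce <- function(logits, onehot) {
  d <- dim(logits)
  m <- apply(logits, c(1, 2, 4), max)
  mb <- array(m, c(d[1], d[2], 1, d[4]))[, , rep(1L, d[3]), , drop = FALSE]
  e <- exp(logits - mb)
  ssum <- array(0, c(d[1], d[2], 1, d[4]))
  for (n in seq_len(d[4]))
    ssum[, , 1, n] <- rowSums(matrix(e[, , , n], d[1] * d[2], d[3]))
  sb <- ssum[, , rep(1L, d[3]), , drop = FALSE]
  p <- e / sb
  n_pix <- d[1] * d[2] * d[4]
  loss <- -sum(onehot * log(pmax(p, 1e-12))) / n_pix
  glogits <- (p - onehot) / n_pix
  list(loss = loss, grad = glogits, probs = p)
}

mask_to_onehot <- function(mask, n_classes) {
  d <- dim(mask)
  oh <- array(0, c(d[1], d[2], n_classes, 1))
  for (k in seq_len(n_classes)) oh[, , k, 1] <- mask == (k - 1L)
  oh
}

#' Segmentation training settings
#'
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param validation_split Held-out fraction (default 5%), taken as the last
#'   fraction after a seeded shuffle.
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param loss `"cross_entropy"` (default) or `"soft_dice"`.
#' @param rng_seed Integer seed.
#' @return A `seg_train_config`.
#' @export
seg_train_config <- function(epochs = 10, batch_size = 8,
                             validation_split = 0.05, learning_rate = 1e-4,
                             loss = c("cross_entropy", "soft_dice"),
                             rng_seed = 1L) {
  loss <- match.arg(loss)
  if (!(validation_split > 0 && validation_split < 1))
    cs_abort("validation_split must be in (0, 1)", "cs_config_error")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 validation_split = validation_split,
                 learning_rate = learning_rate, loss = loss,
                 rng_seed = as.integer(rng_seed)),
            class = "seg_train_config")
}

soft_dice_loss <- function(probs, onehot) {
  # mean over foreground classes of (1 - soft Dice); gradient wrt probs
  d <- dim(probs)
  eps <- 1e-6
  loss <- 0
  gp <- array(0, d)
  ks <- 2:d[3]
  for (k in ks) {
    p <- probs[, , k, , drop = FALSE]
    t <- onehot[, , k, , drop = FALSE]
    num <- 2 * sum(p * t) + eps
    den <- sum(p) + sum(t) + eps
    loss <- loss + (1 - num / den)
    gp[, , k, ] <- -(2 * t * den - num) / den^2
  }
  list(loss = loss / length(ks), grad = gp / length(ks))
}

#' Train a U-Net on frame/mask pairs
#'
#' Pairs are shuffled once with the configured seed; the last
#' `validation_split` fraction is held out. Frames are mapped to `[-1, 1]`;
#' masks are one-hot encoded with an explicit background class. Adam on
#' per-pixel softmax cross-entropy (or soft Dice).
#'
#' @param pairs List of `list(frame, mask, view)` entries, all at
#'   `unet_config$input_resolution`.
#' @param config A [unet_config()].
#' @param train_config A [seg_train_config()].
#' @return A `seg_model` with the trained network, both configs, the view,
#'   and a per-epoch log tibble (`epoch`, `train_loss`, `val_loss`), all
#'   losses finite.
#' @export
train_unet <- function(pairs, config, train_config = seg_train_config()) {
  if (length(pairs) < 2) cs_abort("at least 2 training pairs required", "cs_data_error")
  res <- config$input_resolution
  ok <- vapply(pairs, function(p) all(dim(p$frame) == res) && all(dim(p$mask) == res),
               logical(1))
  if (!all(ok)) cs_abort("all pairs must match input_resolution", "cs_resolution_error")
  view <- toupper(pairs[[1]]$view %||% if (config$n_classes >= 4) "LAX" else "SAX")
  n <- length(pairs)
  ord <- with_seed(derive_seed(train_config$rng_seed, "split"), sample.int(n))
  n_val <- max(1L, floor(n * train_config$validation_split))
  val_idx <- ord[(n - n_val + 1L):n]
  tr_idx <- ord[seq_len(n - n_val)]

  net <- unet_new(config, derive_seed(train_config$rng_seed, "unet_init"))
  opt <- adam_new(train_config$learning_rate, beta1 = 0.9, beta2 = 0.999)

  to_x <- function(idx) {
    a <- array(0, c(res, res, 1L, length(idx)))
    for (j in seq_along(idx)) a[, , 1L, j] <- pairs[[idx[j]]]$frame * 2 - 1
    a
  }
  to_t <- function(idx) {
    a <- array(0, c(res, res, config$n_classes, length(idx)))
    for (j in seq_along(idx)) a[, , , j] <- mask_to_onehot(pairs[[idx[j]]]$mask,
                                                           config$n_classes)
    a
  }
  eval_loss <- function(idx) {
    tot <- 0
    bs <- train_config$batch_size
    for (start in seq(1, length(idx), bs)) {
      b <- idx[start:min(start + bs - 1L, length(idx))]
      fwd <- unet_forward(net, to_x(b))
      tot <- tot + softmax_ce(fwd$y, to_t(b))$loss * length(b)
    }
    tot / length(idx)
  }

  set.seed(derive_seed(train_config$rng_seed, "epochs"))
  log_rows <- vector("list", train_config$epochs)
  for (ep in seq_len(train_config$epochs)) {
    perm <- sample(tr_idx)
    bs <- train_config$batch_size
    ep_loss <- 0
    for (start in seq(1, length(perm), bs)) {
      b <- perm[start:min(start + bs - 1L, length(perm))]
      x <- to_x(b)
      t <- to_t(b)
      fwd <- unet_forward(net, x)
      sc <- softmax_ce(fwd$y, t)
      if (train_config$loss == "soft_dice") {
        sd_ <- soft_dice_loss(sc$probs, t)
        # chain soft-dice grad through softmax
        d <- dim(sc$probs)
        dot <- array(0, c(d[1], d[2], 1, d[4]))
        for (nn in seq_len(d[4]))
          dot[, , 1, nn] <- rowSums(matrix((sd_$grad * sc$probs)[, , , nn],
                                           d[1] * d[2], d[3]))
        gy <- sc$probs * (sd_$grad - dot[, , rep(1L, d[3]), , drop = FALSE])
        loss_val <- sd_$loss
      } else {
        gy <- sc$grad
        loss_val <- sc$loss
      }
      if (!is.finite(loss_val))
        cs_abort(sprintf("non-finite loss in epoch %d", ep), "cs_training_error")
      g <- unet_backward(net, fwd, gy)
      st <- adam_step(opt, net, g)
      opt <- st$opt; net <- st$model
      ep_loss <- ep_loss + loss_val * length(b)
    }
    log_rows[[ep]] <- data.frame(epoch = ep,
                                 train_loss = ep_loss / length(perm),
                                 val_loss = eval_loss(val_idx))
  }
  structure(list(net = net, config = config, train_config = train_config,
                 view = view,
                 log = tibble::as_tibble(do.call(rbind, log_rows))),
            class = "seg_model")
}

#' @export
print.seg_model <- function(x, ...) {
  cat(sprintf("<seg_model> %s view, %d classes @ %d px; final train loss %.4f\n",
              x$view, x$config$n_classes, x$config$input_resolution,
              x$log$train_loss[nrow(x$log)]))
  invisible(x)
}

#' Predict chamber masks for one frame
#'
#' Per-pixel class is the argmax over the softmax class maps (ties broken
#' toward the lowest class index); returned chamber masks are therefore
#' pairwise disjoint. Background is not returned.
#'
#' @param model A `seg_model`.
#' @param image Numeric frame matrix at the model's input resolution (no
#'   silent resizing).
#' @return Named list of logical chamber masks (LV, RV[, RA]) with the
#'   predicted label matrix attached as attribute `labels`.
#' @export
predict_segmentation <- function(model, image) {
  res <- model$config$input_resolution
  if (!all(dim(image) == res))
    cs_abort(sprintf("image must be %d x %d (no silent resizing)", res, res),
             "cs_resolution_error")
  x <- array(image * 2 - 1, c(res, res, 1L, 1L))
  y <- unet_forward(model$net, x)$y
  k <- dim(y)[3]
  flat <- matrix(y[, , , 1L], res * res, k)
  cls <- max.col(flat, ties.method = "first") - 1L
  labels <- matrix(as.integer(cls), res, res)
  ch <- chambers_for_view(model$view)
  out <- chamber_masks(labels, model$view)
  attr(out, "labels") <- labels
  out
}
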