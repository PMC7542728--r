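# Progressive GAN training: parameterized generator/critic networks realizing
# the declarative specs, fade-in forward/backward passes, the Wasserstein
# objective with an interpolated-sample gradient penalty (directional
# finite-difference estimator) or weight clipping, and progressive growth.
# Training images are normalized to [-1, 1]; generator output is linear and
# mapped back to [0, 1] on sampling.

gan_new <- function(config, rng_seed = 1L) {
  f <- config$filters_per_stage
  lk <- config$leakiness
  ns <- n_stages(config)
  with_seed(rng_seed, {
    gen_blocks <- vector("list", ns)
    gen_blocks[[1]] <- list(
      lyr_dense(config$latent_dim, 16L * f[1], gain = sqrt(2)),
      lyr_reshape(4L, 4L, f[1]),
      lyr_lrelu(lk), lyr_pixelnorm(config$epsilon_pixelnorm),
      lyr_conv(3, 3, f[1], f[1]),
      lyr_lrelu(lk), lyr_pixelnorm(config$epsilon_pixelnorm)
    )
    for (k in seq_len(ns - 1L)) {
      gen_blocks[[k + 1L]] <- list(
        lyr_upsample2(),
        lyr_conv(3, 3, f[k], f[k + 1]),
        lyr_lrelu(lk), lyr_pixelnorm(config$epsilon_pixelnorm),
        lyr_conv(3, 3, f[k + 1], f[k + 1]),
        lyr_lrelu(lk), lyr_pixelnorm(config$epsilon_pixelnorm)
      )
    }
    gen_to_img <- lapply(seq_len(ns), function(k)
      list(lyr_conv(1, 1, f[k], config$output_channels, gain = 1)))

    crit_from_img <- lapply(seq_len(ns), function(k)
      list(lyr_conv(1, 1, config$output_channels, f[k], gain = 1), lyr_lrelu(lk)))
    crit_blocks <- vector("list", ns)
    crit_blocks[[1]] <- list(
      lyr_mbstd(),
      lyr_conv(3, 3, f[1] + 1L, f[1]), lyr_lrelu(lk),
      lyr_conv(4, 4, f[1], f[1], pad = 0L), lyr_lrelu(lk),
      lyr_flatten(),
      lyr_dense(f[1], 1L, gain = 1)
    )
    for (k in seq_len(ns - 1L)) {
      crit_blocks[[k + 1L]] <- list(
        lyr_conv(3, 3, f[k + 1], f[k + 1]), lyr_lrelu(lk),
        lyr_conv(3, 3, f[k + 1], f[k]), lyr_lrelu(lk),
        lyr_avgpool2()
      )
    }
    list(generator = list(blocks = gen_blocks, to_img = gen_to_img),
         critic = list(blocks = crit_blocks, from_img = crit_from_img),
         config = config)
  })
}

# generator forward; z is [latent_dim, N]
gen_forward <- function(gen, z, stage, alpha = 1) {
  caches <- vector("list", stage + 1L)
  x <- z
  feats <- vector("list", stage + 1L)
  for (k in 0:stage) {
    f <- chain_fwd(gen$blocks[[k + 1L]], x)
    x <- f$y
    caches[[k + 1L]] <- f$caches
    feats[[k + 1L]] <- x
  }
  fine <- chain_fwd(gen$to_img[[stage + 1L]], x)
  if (stage > 0 && alpha < 1) {
    coarse <- chain_fwd(gen$to_img[[stage]], feats[[stage]])
    y <- fade_in_blend(nn_upsample2(coarse$y), fine$y, alpha)
    skip_cache <- coarse$caches
  } else {
    y <- fine$y
    skip_cache <- NULL
  }
  list(y = y, caches = caches, fine_cache = fine$caches,
       skip_cache = skip_cache, stage = stage, alpha = alpha)
}

gen_backward <- function(gen, fwd, gy) {
  stage <- fwd$stage; alpha <- fwd$alpha
  g_blocks <- vector("list", length(gen$blocks))
  g_to_img <- vector("list", length(gen$to_img))
  blend <- stage > 0 && alpha < 1
  g_fine <- if (blend) alpha * gy else gy
  bf <- chain_bwd(gen$to_img[[stage + 1L]], fwd$fine_cache, g_fine)
  g_to_img[[stage + 1L]] <- bf$grads
  gx <- bf$gx
  g_skip_feat <- NULL
  if (blend) {
    g_coarse <- nn_upsample2_bwd((1 - alpha) * gy)
    bs <- chain_bwd(gen$to_img[[stage]], fwd$skip_cache, g_coarse)
    g_to_img[[stage]] <- bs$grads
    g_skip_feat <- bs$gx
  }
  for (k in stage:0) {
    b <- chain_bwd(gen$blocks[[k + 1L]], fwd$caches[[k + 1L]], gx)
    g_blocks[[k + 1L]] <- b$grads
    gx <- b$gx
    if (blend && k == stage && !is.null(g_skip_feat)) gx <- gx + g_skip_feat
  }
  list(gz = gx, grads = list(blocks = g_blocks, to_img = g_to_img))
}

# critic forward; img is [H, W, 1, N]; returns scores as length-N vector
crit_forward <- function(crit, img, stage, alpha = 1) {
  h <- chain_fwd(crit$from_img[[stage + 1L]], img)
  x <- h$y
  top <- chain_fwd(crit$blocks[[stage + 1L]], x)
  x <- top$y
  blend <- stage > 0 && alpha < 1
  skip <- NULL
  if (blend) {
    skip <- chain_fwd(crit$from_img[[stage]], nn_avgpool2(img))
    x <- fade_in_blend(skip$y, x, alpha)
  }
  lower <- vector("list", stage)
  if (stage > 0) {
    for (k in (stage - 1L):0) {
      f <- chain_fwd(crit$blocks[[k + 1L]], x)
      lower[[k + 1L]] <- f$caches
      x <- f$y
    }
  }
  list(scores = as.numeric(x), head_cache = h$caches, top_cache = top$caches,
       skip_cache = if (blend) skip$caches else NULL,
       lower_caches = lower, stage = stage, alpha = alpha, img_dim = dim(img))
}

# gy_scores: length-N vector of dLoss/dscore
crit_backward <- function(crit, fwd, gy_scores) {
  stage <- fwd$stage; alpha <- fwd$alpha
  blend <- stage > 0 && alpha < 1
  g_blocks <- vector("list", length(crit$blocks))
  g_from_img <- vector("list", length(crit$from_img))
  gx <- matrix(gy_scores, nrow = 1)
  if (stage > 0) {
    for (k in 0:(stage - 1L)) {
      b <- chain_bwd(crit$blocks[[k + 1L]], fwd$lower_caches[[k + 1L]], gx)
      g_blocks[[k + 1L]] <- tree_scale_acc(g_blocks[[k + 1L]], b$grads)
      gx <- b$gx
    }
  }
  g_img <- NULL
  if (blend) {
    bs <- chain_bwd(crit$from_img[[stage]], fwd$skip_cache, (1 - alpha) * gx)
    g_from_img[[stage]] <- bs$grads
    g_img <- nn_avgpool2_bwd(bs$gx)
    gx <- alpha * gx
  }
  bt <- chain_bwd(crit$blocks[[stage + 1L]], fwd$top_cache, gx)
  g_blocks[[stage + 1L]] <- tree_scale_acc(g_blocks[[stage + 1L]], bt$grads)
  bh <- chain_bwd(crit$from_img[[stage + 1L]], fwd$head_cache, bt$gx)
  g_from_img[[stage + 1L]] <- bh$grads
  g_img <- if (is.null(g_img)) bh$gx else g_img + bh$gx
  list(g_img = g_img, grads = list(blocks = g_blocks, from_img = g_from_img))
}

acc_crit_grads <- function(a, b, scale = 1) {
  list(blocks = tree_scale_acc(a$blocks, b$blocks, scale),
       from_img = tree_scale_acc(a$from_img, b$from_img, scale))
}

# resolve training input to a list of [0, 1] matrices at `resolution`
gan_training_images <- function(dataset, resolution) {
  imgs <- if (inherits(dataset, "phantom_dataset")) {
    lapply(file.path(dataset$dir, dataset$manifest$frame), read_frame)
  } else if (is.character(dataset) && length(dataset) == 1L && dir.exists(dataset)) {
    files <- sort(list.files(dataset, pattern = "\\.png$", full.names = TRUE))
    files <- files[!grepl("mask", basename(files))]
    lapply(files, read_frame)
  } else if (is.character(dataset) && length(dataset) == 1L && file.exists(dataset)) {
    lapply(load_pairs(dataset), `[[`, "frame")
  } else if (is.list(dataset)) {
    dataset
  } else cs_abort("unrecognized dataset input", "cs_data_error")
  if (length(imgs) == 0) cs_abort("empty training dataset", "cs_data_error")
  lapply(imgs, function(im) {
    if (nrow(im) != resolution) resize_frame(im, resolution) else im
  })
}

#' Train a progressive GAN
#'
#' Grows generator and critic jointly from 4x4 to the schedule's final
#' resolution. Within each stage, the new block's contribution is faded in
#' with a linearly increasing blend weight over `fade_fraction` of the
#' stage's steps; all previously grown layers remain trainable throughout.
#' Critic and generator alternate single Adam steps on the Wasserstein
#' objective; stabilization is an interpolated-sample gradient penalty whose
#' parameter gradient is estimated by a central finite difference along a
#' random unit direction (or plain weight clipping, per the config). Real
#' images are average-pooled down to each stage's working resolution.
#'
#' @param dataset A [generate_phantom_dataset()] result, a manifest path, a
#'   directory of PNG frames, or a list of `[0, 1]` matrices.
#' @param config A [gan_config()].
#' @param schedule A [growth_schedule()]; its final resolution must not
#'   exceed `config$max_resolution`.
#' @param rng_seed Integer seed; with single-threaded BLAS the run is
#'   reproducible.
#' @param verbose Print a line every 50 steps.
#' @return A `pggan_model`: generator, critic, config, schedule, and a
#'   training log tibble (step, stage, resolution, alpha, critic and
#'   generator loss). Non-finite losses abort with a stage/step diagnostic.
#' @export
train_pggan <- function(dataset, config, schedule, rng_seed = 1L,
                        verbose = FALSE) {
  final_res <- schedule$stage_resolutions[length(schedule$stage_resolutions)]
  if (final_res > config$max_resolution)
    cs_abort("schedule exceeds config max_resolution", "cs_config_error")
  imgs <- gan_training_images(dataset, final_res)
  n_img <- length(imgs)
  model <- gan_new(config, derive_seed(rng_seed, "gan_init"))
  gen <- model$generator; crit <- model$critic
  opt_g <- adam_new(config$learning_rate, config$adam_beta1, config$adam_beta2)
  opt_d <- adam_new(config$learning_rate, config$adam_beta1, config$adam_beta2)
  use_gp <- config$stabilizer == "gradient_penalty"

  # per-stage image pyramids in [-1, 1]
  stack_at <- function(res) {
    a <- array(0, c(res, res, 1L, n_img))
    for (i in seq_len(n_img)) {
      im <- imgs[[i]]
      while (nrow(im) > res)
        im <- matrix(nn_avgpool2(array(im, c(dim(im), 1L, 1L))), nrow(im) / 2)
      a[, , 1L, i] <- im
    }
    a * 2 - 1
  }

  log_rows <- vector("list", sum(schedule$steps_per_stage))
  li <- 0L
  global_step <- 0L
  set.seed(derive_seed(rng_seed, "gan_train"))
  n_stage_run <- length(schedule$stage_resolutions)

  for (s in seq_len(n_stage_run) - 1L) {
    res <- schedule$stage_resolutions[s + 1L]
    steps <- schedule$steps_per_stage[s + 1L]
    batch <- min(schedule$batch_per_stage[s + 1L], n_img)
    reals <- stack_at(res)
    fade_steps <- if (s == 0) 0L else max(1L, round(schedule$fade_fraction * steps))

    for (step in seq_len(steps)) {
      alpha <- if (s == 0 || step >= fade_steps) 1 else step / fade_steps
      # real images seen by the critic are faded in like the generator path,
      # so the new resolution's high frequencies appear gradually
      blend_real <- function(x) {
        if (alpha >= 1) return(x)
        fade_in_blend(nn_upsample2(nn_avgpool2(x)), x, alpha)
      }
      # ---- critic step(s)
      for (ic in seq_len(config$n_critic)) {
        idx <- sample.int(n_img, batch, replace = n_img < batch)
        real <- blend_real(reals[, , , idx, drop = FALSE])
        z <- matrix(rnorm(config$latent_dim * batch), config$latent_dim, batch)
        gf <- gen_forward(gen, z, s, alpha)
        fake <- gf$y
        fr <- crit_forward(crit, real, s, alpha)
        ff <- crit_forward(crit, fake, s, alpha)
        gp <- 0
        grads_d <- NULL
        bw_real <- crit_backward(crit, fr, -1 / batch +
                                   2 * config$drift_weight * fr$scores / batch)
        bw_fake <- crit_backward(crit, ff, rep(1 / batch, batch))
        grads_d <- acc_crit_grads(bw_real$grads, bw_fake$grads)
        if (use_gp) {
          mix <- array(rep(runif(batch), each = res * res), dim(real))
          xhat <- mix * real + (1 - mix) * fake
          dim_n <- res * res
          u <- array(rnorm(length(xhat)), dim(xhat))
          for (b in seq_len(batch)) {
            nb <- sqrt(sum(u[, , , b]^2))
            u[, , , b] <- u[, , , b] / nb
          }
          h <- 1e-3
          fp <- crit_forward(crit, xhat + h * u, s, alpha)
          fm <- crit_forward(crit, xhat - h * u, s, alpha)
          dd <- sqrt(dim_n) * (fp$scores - fm$scores) / (2 * h)
          gp <- mean((abs(dd) - 1)^2)
          gdd <- 2 * (abs(dd) - 1) * sign(dd) * sqrt(dim_n) / (2 * h * batch)
          bw_p <- crit_backward(crit, fp, config$gradient_penalty_weight * gdd)
          bw_m <- crit_backward(crit, fm, -config$gradient_penalty_weight * gdd)
          grads_d <- acc_crit_grads(grads_d, bw_p$grads)
          grads_d <- acc_crit_grads(grads_d, bw_m$grads)
        }
        losses <- critic_losses(fr$scores, ff$scores, gp,
                                if (use_gp) config$gradient_penalty_weight else 0)
        sd_ <- adam_step(opt_d, crit, grads_d)
        opt_d <- sd_$opt; crit <- sd_$model
        if (!use_gp) crit <- clip_weights(crit, config$clip_value)
      }

      # ---- generator step
      z2 <- matrix(rnorm(config$latent_dim * batch), config$latent_dim, batch)
      gf2 <- gen_forward(gen, z2, s, alpha)
      ff2 <- crit_forward(crit, gf2$y, s, alpha)
      gen_loss <- -mean(ff2$scores)
      bwc <- crit_backward(crit, ff2, rep(-1 / batch, batch))
      bwg <- gen_backward(gen, gf2, bwc$g_img)
      sg <- adam_step(opt_g, gen, bwg$grads)
      opt_g <- sg$opt; gen <- sg$model

      global_step <- global_step + 1L
      li <- li + 1L
      log_rows[[li]] <- data.frame(step = global_step, stage = s,
                                   resolution = res, alpha = alpha,
                                   critic_loss = losses$critic_loss,
                                   generator_loss = gen_loss)
      if (!is.finite(losses$critic_loss) || !is.finite(gen_loss))
        cs_abort(sprintf("non-finite loss at stage %d step %d (critic %.3g, generator %.3g)",
                         s, step, losses$critic_loss, gen_loss),
                 "cs_training_error")
      if (verbose && step %% 50 == 0)
        message(sprintf("stage %d (%dpx) step %d/%d alpha %.2f critic %.3f gen %.3f",
                        s, res, step, steps, alpha, losses$critic_loss, gen_loss))
    }
  }
  structure(list(generator = gen, critic = crit, config = config,
                 schedule = schedule,
                 final_stage = n_stage_run - 1L,
                 final_resolution = final_res,
                 log = tibble::as_tibble(do.call(rbind, log_rows[seq_len(li)]))),
            class = "pggan_model")
}

#' @export
print.pggan_model <- function(x, ...) {
  cat(sprintf("<pggan_model> grown to %d x %d; %d training steps logged\n",
              x$final_resolution, x$final_resolution, nrow(x$log)))
  invisible(x)
}

#' Sample synthetic frames from a trained generator
#'
#' Draws standard-normal latents, runs the generator at its final stage, and
#' affinely maps the linear output from `[-1, 1]` to `[0, 1]` (clipped).
#'
#' @param model A `pggan_model`.
#' @param n Number of frames (>= 1).
#' @param rng_seed Integer seed; identical seeds give identical frames.
#' @return List of `n` numeric matrices in `[0, 1]`.
#' @export
sample_synthetic <- function(model, n, rng_seed = 1L) {
  stopifnot(n >= 1)
  z <- with_seed(rng_seed,
                 matrix(rnorm(model$config$latent_dim * n),
                        model$config$latent_dim, n))
  y <- gen_forward(model$generator, z, model$final_stage, alpha = 1)$y
  lapply(seq_len(n), function(i)
    pmin(pmax((matrix(y[, , 1L, i], dim(y)[1]) + 1) / 2, 0), 1))
}

#' Plot a GAN training log
#'
#' Critic and generator loss traces over steps, shaded by growth stage.
#'
#' @param model A `pggan_model`.
#' @return A ggplot object.
#' @export
plot_training_log <- function(model) {
  lg <- model$log
  long <- rbind(
    data.frame(step = lg$step, loss = lg$critic_loss, which = "critic"),
    data.frame(step = lg$step, loss = lg$generator_loss, which = "generator")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = step, y = loss, colour = which)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(title = "Progressive GAN training", x = "step", y = "loss") +
    ggplot2::theme_minimal()
}

#' Save / load a model archive
#'
#' Self-describing archive (configs, schedules, weights, growth state) for
#' `pggan_model` and `seg_model` objects.
#' @param model Model object.
#' @param path Destination file.
#' @export
save_model <- function(model, path) {
  saveRDS(list(format = "cardiosynth_model", version = 1L, model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "cardiosynth_model"))
    cs_abort("not a cardiosynth model archive", "cs_io_error")
  x$model
}
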