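# Progressive Wasserstein GAN: configuration, growth schedule, declarative
# architecture specs, and the elementary stabilization operators (pixelwise
# feature normalization, minibatch stddev, fade-in blending, critic losses).

#' Progressive GAN configuration
#'
#' Defaults follow the grayscale cardiac-MR adaptation: one output channel,
#' latent dimension 64, leaky ReLU with leakiness 0.2, maximum resolution
#' 256 and per-stage filter counts 48, 32, 24, 16, 16, 16, 16.
#'
#' @param latent_dim Latent vector dimension (>= 1).
#' @param leakiness Leaky-ReLU slope, in (0, 1).
#' @param output_channels Image channels (1 = grayscale).
#' @param max_resolution Final stage resolution (power of two >= 4).
#' @param filters_per_stage Integer vector, one entry per stage; length must
#'   equal `log2(max_resolution) - 1`.
#' @param epsilon_pixelnorm Numerical floor inside pixel normalization.
#' @param learning_rate,adam_beta1,adam_beta2 Adam settings (progressive-GAN
#'   convention: beta1 = 0, beta2 = 0.99, lr 1e-3).
#' @param gradient_penalty_weight Weight of the interpolated-sample gradient
#'   penalty (default 10).
#' @param drift_weight Small penalty on squared real scores keeping the critic
#'   output scale bounded.
#' @param stabilizer `"gradient_penalty"` (default) or `"weight_clip"`.
#' @param clip_value Weight-clipping bound when `stabilizer = "weight_clip"`.
#' @param n_critic Critic updates per generator update (default 1).
#' @param equalized_lr If `TRUE`, uses runtime He-scaling of weights instead
#'   of scaled initialization (off by default).
#' @return A validated `gan_config` object.
#' @export
gan_config <- function(latent_dim = 64, leakiness = 0.2, output_channels = 1,
                       max_resolution = 256,
                       filters_per_stage = c(48, 32, 24, 16, 16, 16, 16),
                       epsilon_pixelnorm = 1e-8,
                       learning_rate = 1e-3, adam_beta1 = 0, adam_beta2 = 0.99,
                       gradient_penalty_weight = 10, drift_weight = 1e-3,
                       stabilizer = c("gradient_penalty", "weight_clip"),
                       clip_value = 0.01, n_critic = 1, equalized_lr = FALSE) {
  stabilizer <- match.arg(stabilizer)
  cfg <- list(latent_dim = as.integer(latent_dim), leakiness = leakiness,
              output_channels = as.integer(output_channels),
              max_resolution = as.integer(max_resolution),
              filters_per_stage = as.integer(filters_per_stage),
              epsilon_pixelnorm = epsilon_pixelnorm,
              learning_rate = learning_rate, adam_beta1 = adam_beta1,
              adam_beta2 = adam_beta2,
              gradient_penalty_weight = gradient_penalty_weight,
              drift_weight = drift_weight, stabilizer = stabilizer,
              clip_value = clip_value, n_critic = as.integer(n_critic),
              equalized_lr = equalized_lr)
  class(cfg) <- "gan_config"
  validate_gan_config(cfg)
}

validate_gan_config <- function(cfg) {
  if (cfg$latent_dim < 1) cs_abort("latent_dim must be >= 1", "cs_config_error")
  if (!(cfg$leakiness > 0 && cfg$leakiness < 1))
    cs_abort("leakiness must be in (0, 1)", "cs_config_error")
  if (!is_pow2(cfg$max_resolution) || cfg$max_resolution < 4)
    cs_abort("max_resolution must be a power of two >= 4", "cs_config_error")
  n_stages <- log2(cfg$max_resolution) - 1
  if (length(cfg$filters_per_stage) != n_stages)
    cs_abort(sprintf("filters_per_stage must have length log2(max_resolution) - 1 = %d",
                     n_stages), "cs_config_error")
  cfg
}

n_stages <- function(cfg) as.integer(log2(cfg$max_resolution) - 1)
stage_resolutions <- function(cfg) as.integer(4 * 2^(seq_len(n_stages(cfg)) - 1))

#' Progressive growth schedule
#'
#' Stage resolutions double from 4 up to `max_resolution`; batch sizes must be
#' non-increasing across stages (they shrink as resolution grows).
#'
#' @param max_resolution Final resolution (power of two >= 4).
#' @param steps_per_stage Training steps per stage (recycled to all stages).
#' @param batch_per_stage Minibatch size per stage (recycled); non-increasing.
#' @param fade_fraction Fraction of each stage spent fading the new block in,
#'   in `[0, 1)`; alpha ramps linearly over that window.
#' @return A validated `growth_schedule`.
#' @export
growth_schedule <- function(max_resolution = 256, steps_per_stage = 500,
                            batch_per_stage = 16, fade_fraction = 0.5) {
  if (!is_pow2(max_resolution) || max_resolution < 4)
    cs_abort("max_resolution must be a power of two >= 4", "cs_config_error")
  k <- as.integer(log2(max_resolution) - 1)
  res <- as.integer(4 * 2^(seq_len(k) - 1))
  steps <- rep_len(as.integer(steps_per_stage), k)
  batch <- rep_len(as.integer(batch_per_stage), k)
  if (any(diff(batch) > 0))
    cs_abort("batch sizes must be non-increasing across stages", "cs_config_error")
  if (!(fade_fraction >= 0 && fade_fraction < 1))
    cs_abort("fade_fraction must be in [0, 1)", "cs_config_error")
  structure(list(stage_resolutions = res, steps_per_stage = steps,
                 batch_per_stage = batch, fade_fraction = fade_fraction),
            class = "growth_schedule")
}

# ---- declarative architecture specs -----------------------------------------

spec_block <- function(kind, in_channels, out_channels, resolution,
                       activation = "lrelu", leakiness = 0.2) {
  tibble::tibble(kind = kind, in_channels = in_channels,
                 out_channels = out_channels, resolution = resolution,
                 activation = activation, leakiness = leakiness)
}

#' Generator architecture spec at a growth stage
#'
#' Declarative layer-block listing for the generator grown to `stage`
#' (0-based): a 4x4 "from latent" block, one upscale + two 3x3 convolution
#' blocks per additional stage (leaky ReLU + pixelwise feature normalization
#' inside every generator block), and a linear 1x1 to-image head.
#'
#' @param config A [gan_config()].
#' @param stage 0-based stage index; `0 <= stage < n_stages`.
#' @return An `architecture_spec`: `resolution_blocks` (list of per-stage
#'   layer tibbles), `head`, `output_resolution`, `output_channels`.
#' @export
build_generator_spec <- function(config, stage) {
  ns <- n_stages(config)
  if (stage < 0 || stage >= ns)
    cs_abort(sprintf("stage must be in [0, %d]", ns - 1), "cs_stage_error")
  f <- config$filters_per_stage
  lk <- config$leakiness
  blocks <- vector("list", stage + 1L)
  res <- stage_resolutions(config)
  blocks[[1]] <- rbind(
    spec_block("conv4x4", config$latent_dim, f[1], 4, "lrelu", lk),
    spec_block("pixelnorm", f[1], f[1], 4, "linear", 0),
    spec_block("conv3x3", f[1], f[1], 4, "lrelu", lk),
    spec_block("pixelnorm", f[1], f[1], 4, "linear", 0)
  )
  for (k in seq_len(stage)) {
    blocks[[k + 1L]] <- rbind(
      spec_block("upscale2x", f[k], f[k], res[k + 1], "linear", 0),
      spec_block("conv3x3", f[k], f[k + 1], res[k + 1], "lrelu", lk),
      spec_block("pixelnorm", f[k + 1], f[k + 1], res[k + 1], "linear", 0),
      spec_block("conv3x3", f[k + 1], f[k + 1], res[k + 1], "lrelu", lk),
      spec_block("pixelnorm", f[k + 1], f[k + 1], res[k + 1], "linear", 0)
    )
  }
  structure(list(
    network = "generator",
    resolution_blocks = blocks,
    head = spec_block("to_image", f[stage + 1L], config$output_channels,
                      res[stage + 1L], "linear", 0),
    output_resolution = res[stage + 1L],
    output_channels = config$output_channels
  ), class = "architecture_spec")
}

#' Discriminator (critic) architecture spec at a growth stage
#'
#' Symmetric to the generator: a 1x1 from-image head, one two-convolution +
#' average-pooling block per stage above the first (channel counts mirror the
#' generator's in reverse), and a final 4x4 block containing the single
#' minibatch-stddev layer before reduction to a scalar score.
#'
#' @inheritParams build_generator_spec
#' @return An `architecture_spec` whose blocks consume `stage` resolution and
#'   emit a scalar score.
#' @export
build_discriminator_spec <- function(config, stage) {
  ns <- n_stages(config)
  if (stage < 0 || stage >= ns)
    cs_abort(sprintf("stage must be in [0, %d]", ns - 1), "cs_stage_error")
  f <- config$filters_per_stage
  lk <- config$leakiness
  res <- stage_resolutions(config)
  blocks <- vector("list", stage + 1L)
  # blocks listed from input (finest) down to the 4x4 block
  for (k in rev(seq_len(stage))) {
    blocks[[stage - k + 1L]] <- rbind(
      spec_block("conv3x3", f[k + 1], f[k + 1], res[k + 1], "lrelu", lk),
      spec_block("conv3x3", f[k + 1], f[k], res[k + 1], "lrelu", lk),
      spec_block("avgpool2x", f[k], f[k], res[k], "linear", 0)
    )
  }
  blocks[[stage + 1L]] <- rbind(
    spec_block("minibatch_stddev", f[1], f[1] + 1L, 4, "linear", 0),
    spec_block("conv3x3", f[1] + 1L, f[1], 4, "lrelu", lk),
    spec_block("conv4x4", f[1], f[1], 1, "lrelu", lk)
  )
  structure(list(
    network = "discriminator",
    resolution_blocks = blocks,
    head = spec_block("from_image", config$output_channels, f[stage + 1L],
                      res[stage + 1L], "lrelu", lk),
    score = spec_block("dense", f[1], 1, 1, "linear", 0),
    output_resolution = 1L,
    input_resolution = res[stage + 1L]
  ), class = "architecture_spec")
}

#' @export
print.architecture_spec <- function(x, ...) {
  cat(sprintf("<architecture_spec> %s, %d resolution block(s)\n",
              x$network, length(x$resolution_blocks)))
  invisible(x)
}

# ---- elementary operators ----------------------------------------------------

#' Pixelwise feature vector normalization
#'
#' Replaces each spatial position's channel vector `x` with
#' `x / sqrt(mean(x^2) + epsilon)`, so the per-pixel mean square is 1 (up to
#' `epsilon`). Accepts a single `[H, W, C]` map or a batch `[H, W, C, N]`.
#'
#' @param feature_map Numeric array.
#' @param epsilon Positive numerical floor.
#' @return Array of the input shape.
#' @export
pixelwise_feature_norm <- function(feature_map, epsilon = 1e-8) {
  stopifnot(epsilon > 0)
  d <- dim(feature_map)
  x <- if (length(d) == 3L) array(feature_map, c(d, 1L)) else feature_map
  y <- pixelnorm_fwd(x, epsilon)$y
  if (length(d) == 3L) array(y, d) else y
}

#' Fade-in blend between the upscaled coarse path and the fine path
#'
#' `(1 - alpha) * coarse_upscaled + alpha * fine`: the smooth transition used
#' while a freshly added resolution block is faded in.
#'
#' @param coarse_upscaled,fine Arrays of identical shape.
#' @param alpha Blend weight in `[0, 1]`.
#' @return Blended array.
#' @export
fade_in_blend <- function(coarse_upscaled, fine, alpha) {
  if (!identical(dim(coarse_upscaled), dim(fine)))
    cs_abort("fade-in inputs must have identical shape", "cs_shape_error")
  stopifnot(alpha >= 0, alpha <= 1)
  (1 - alpha) * coarse_upscaled + alpha * fine
}

#' Wasserstein critic and generator losses
#'
#' `critic_loss = mean(fake) - mean(real) + gp_weight * gradient_penalty`;
#' `generator_loss = -mean(fake)`. With `gp_weight = 0` this is the plain
#' Wasserstein critic objective.
#'
#' @param real_scores,fake_scores Non-empty numeric score vectors.
#' @param gradient_penalty Scalar penalty value (already aggregated).
#' @param gp_weight Penalty weight.
#' @return List with `critic_loss` and `generator_loss`.
#' @export
critic_losses <- function(real_scores, fake_scores, gradient_penalty = 0,
                          gp_weight = 0) {
  if (length(real_scores) == 0 || length(fake_scores) == 0)
    cs_abort("score vectors must be non-empty", "cs_stat_error")
  list(critic_loss = mean(fake_scores) - mean(real_scores) +
         gp_weight * gradient_penalty,
       generator_loss = -mean(fake_scores))
}
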