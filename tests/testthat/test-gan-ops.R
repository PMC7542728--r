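cs <- asNamespace("cardiosynth")

test_that("pixelwise feature normalization divides by the root mean square channel energy", {
  x <- array(0, c(1, 1, 2, 1))
  x[1, 1, , 1] <- c(3, 4)
  y <- pixelwise_feature_norm(x, 1e-12)
  # mean square of (3, 4) is 12.5
  expect_equal(as.vector(y), c(3, 4) / sqrt(12.5), tolerance = 1e-9)
  set.seed(1)
  r <- array(rnorm(4 * 4 * 5 * 2), c(4, 4, 5, 2))
  yr <- pixelwise_feature_norm(r, 1e-10)
  ms <- apply(yr^2, c(1, 2, 4), mean)
  expect_equal(as.vector(ms), rep(1, length(ms)), tolerance = 1e-6)
  # normalizing twice equals normalizing once (up to epsilon terms)
  expect_equal(pixelwise_feature_norm(yr, 1e-10), yr, tolerance = 1e-6)
  # all-zero input stays zero thanks to epsilon
  z <- array(0, c(2, 2, 3, 1))
  expect_identical(pixelwise_feature_norm(z, 1e-8), z)
})

test_that("minibatch stddev channel encodes across-batch variability", {
  set.seed(2)
  one <- array(rnorm(3 * 3 * 2), c(3, 3, 2, 1))
  dup <- one[, , , rep(1, 4), drop = FALSE]
  y <- minibatch_stddev_channel(dup)
  expect_identical(dim(y), c(3L, 3L, 3L, 4L))
  expect_equal(as.vector(y[, , 3, ]), rep(0, 36))
  # population sd of {0, 2} is 1
  x <- array(c(0, 2), c(1, 1, 1, 2))
  y2 <- minibatch_stddev_channel(x)
  expect_equal(as.vector(y2[, , 2, ]), c(1, 1))
  expect_equal(as.vector(y2[, , 1, ]), c(0, 2))
})

test_that("fade-in blend hits its endpoints and is linear", {
  a <- matrix(0, 4, 4); b <- matrix(1, 4, 4)
  expect_identical(fade_in_blend(a, b, 0), a)
  expect_identical(fade_in_blend(a, b, 1), b)
  expect_identical(fade_in_blend(a, b, 0.5), matrix(0.5, 4, 4))
  expect_error(fade_in_blend(matrix(0, 2, 2), b, 0.5), class = "cs_shape_error")
})

test_that("critic losses implement the Wasserstein objective with optional penalty", {
  l <- critic_losses(c(1, 1), c(0, 0), 0, 0)
  expect_identical(l$critic_loss, -1)
  expect_identical(l$generator_loss, 0)
  expect_identical(critic_losses(c(2, 3), c(2, 3))$critic_loss, 0)
  # swapping real and fake negates the Wasserstein term
  r <- rnorm(5); f <- rnorm(5)
  expect_equal(critic_losses(r, f)$critic_loss, -critic_losses(f, r)$critic_loss)
  # penalty enters weighted
  expect_equal(critic_losses(c(1, 1), c(0, 0), gradient_penalty = 2,
                             gp_weight = 10)$critic_loss, -1 + 20)
  expect_error(critic_losses(numeric(0), 1), class = "cs_stat_error")
})

test_that("generator specs grow one block pair per stage with the configured filters", {
  cfg <- gan_config()
  s0 <- build_generator_spec(cfg, 0)
  expect_identical(s0$output_resolution, 4L)
  expect_identical(s0$output_channels, 1L)
  expect_length(s0$resolution_blocks, 1L)
  s6 <- build_generator_spec(cfg, 6)
  expect_identical(s6$output_resolution, 256L)
  expect_length(s6$resolution_blocks, 7L)
  for (k in 0:5) {
    a <- build_generator_spec(cfg, k)
    b <- build_generator_spec(cfg, k + 1)
    expect_length(b$resolution_blocks, length(a$resolution_blocks) + 1L)
    expect_identical(a$resolution_blocks, b$resolution_blocks[seq_len(k + 1)])
  }
  first_conv <- s6$resolution_blocks[[1]]
  expect_identical(first_conv$out_channels[1], 48L)
  expect_true(all(vapply(s6$resolution_blocks, function(b)
    any(b$kind == "pixelnorm"), logical(1))))
  expect_error(build_generator_spec(cfg, 7), class = "cs_stage_error")
  expect_error(build_generator_spec(cfg, -1), class = "cs_stage_error")
})

test_that("discriminator specs mirror generator channels and contain one minibatch-stddev block", {
  cfg <- gan_config()
  for (stage in c(0, 3, 6)) {
    d <- build_discriminator_spec(cfg, stage)
    expect_identical(d$input_resolution, as.integer(4 * 2^stage))
    expect_identical(d$score$out_channels, 1)
    all_kinds <- unlist(lapply(d$resolution_blocks, function(b) b$kind))
    expect_identical(sum(all_kinds == "minibatch_stddev"), 1L)
    # discriminator consumes, per resolution, the channel width the generator
    # produces there (mirrored order); +1 at the 4x4 block for the stddev map
    f <- cfg$filters_per_stage
    expect_identical(d$head$out_channels, f[stage + 1])
    if (stage > 0) {
      d_first_in <- vapply(d$resolution_blocks[seq_len(stage)],
                           function(b) b$in_channels[1], integer(1))
      expect_identical(d_first_in, rev(f[2:(stage + 1)]))
    }
    final <- d$resolution_blocks[[stage + 1]]
    expect_identical(final$in_channels[final$kind == "conv3x3"], f[1] + 1L)
  }
  expect_error(build_discriminator_spec(gan_config(), 9), class = "cs_stage_error")
})

test_that("growth schedule doubles resolution and rejects increasing batch sizes", {
  sch <- growth_schedule(64, steps_per_stage = 10,
                         batch_per_stage = c(64, 32, 16, 16, 16))
  expect_identical(sch$stage_resolutions, c(4L, 8L, 16L, 32L, 64L))
  expect_error(growth_schedule(64, 10, c(16, 32, 16, 16, 16)),
               class = "cs_config_error")
  expect_error(gan_config(max_resolution = 64), class = "cs_config_error")
  expect_no_error(gan_config(max_resolution = 64,
                             filters_per_stage = c(48, 32, 24, 16, 16)))
})

test_that("a grown generator at alpha = 0 reproduces the upscaled previous-stage output", {
  cfg <- gan_config(latent_dim = 8, max_resolution = 16,
                    filters_per_stage = c(6, 5, 4))
  m <- cs$gan_new(cfg, 11)
  z <- matrix(rnorm(16), 8, 2)
  for (stage in 1:2) {
    prev <- cs$gen_forward(m$generator, z, stage - 1L, 1)$y
    grown <- cs$gen_forward(m$generator, z, stage, 0)$y
    expect_equal(grown, cs$nn_upsample2(prev), tolerance = 1e-12)
  }
})

test_that("synthetic sampling is seed-deterministic with the requested count and range", {
  cfg <- gan_config(latent_dim = 8, max_resolution = 8, filters_per_stage = c(6, 5))
  m <- cs$gan_new(cfg, 2)
  model <- structure(list(generator = m$generator, config = cfg,
                          final_stage = 1L, final_resolution = 8L),
                     class = "pggan_model")
  s1 <- sample_synthetic(model, 5, 13)
  s2 <- sample_synthetic(model, 5, 13)
  expect_identical(s1, s2)
  expect_length(s1, 5L)
  expect_identical(dim(s1[[1]]), c(8L, 8L))
  expect_true(all(vapply(s1, function(f) all(f >= 0 & f <= 1), logical(1))))
  s3 <- sample_synthetic(model, 5, 14)
  expect_false(identical(s1, s3))
})
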