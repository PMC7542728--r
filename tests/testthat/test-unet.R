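test_that("U-Net spec doubles channels per contraction step with one junction per level", {
  spec <- build_unet_spec(unet_config(128, 3, depth = 4, base_channels = 64))
  expect_identical(spec$encoder_channels, c(64L, 128L, 256L, 512L))
  expect_identical(spec$bottleneck_channels, 1024L)
  expect_identical(spec$n_concat, 4L)
  expect_identical(spec$output_resolution, spec$input_resolution)
  expect_identical(sum(spec$blocks$kind == "concat"), 4L)
  expect_identical(spec$blocks$out_channels[nrow(spec$blocks)], 3L)
  expect_error(unet_config(100, 3, depth = 4), class = "cs_config_error")
  expect_error(unet_config(64, 1), class = "cs_config_error")
})

test_that("augmentation with zero limits is the identity and preserves label sets", {
  pr <- phantom_pairs(55, 32)[[1]]
  null_spec <- augmentation_spec(0, 0, 0, 0, 0)
  out <- augment_pair(pr$frame, pr$mask, null_spec, 3)
  expect_identical(out$frame, pr$frame)
  expect_identical(out$mask, pr$mask)
  spec <- augmentation_spec()
  a1 <- augment_pair(pr$frame, pr$mask, spec, 7)
  a2 <- augment_pair(pr$frame, pr$mask, spec, 7)
  expect_identical(a1, a2)
  expect_true(all(unique(as.vector(a1$mask)) %in% unique(as.vector(pr$mask))))
  expect_error(augment_pair(pr$frame, pr$mask[1:16, 1:16], spec, 1),
               class = "cs_shape_error")
})

test_that("a small pure rotation preserves the area of a centered disk mask", {
  g <- expand.grid(r = 1:64, c = 1:64)
  disk <- matrix((g$r - 32.5)^2 + (g$c - 32.5)^2 < 15^2, 64, 64)
  mask <- matrix(as.integer(disk), 64, 64)
  frame <- mask * 0.8
  rot_only <- augmentation_spec(15, 0, 0, 0, 0)
  for (seed in 1:5) {
    out <- augment_pair(frame, mask, rot_only, seed)
    expect_lt(abs(sum(out$mask == 1) / sum(mask == 1) - 1), 0.05)
  }
})

test_that("dataset expansion multiplies counts deterministically", {
  pairs <- phantom_pairs(60:64, 32)
  big <- expand_dataset(pairs, augmentation_spec(), factor = 10, rng_seed = 5)
  expect_length(big, 50L)
  expect_identical(big, expand_dataset(pairs, augmentation_spec(), 10, 5))
  same <- expand_dataset(pairs, augmentation_spec(0, 0, 0, 0, 0), 1, 5)
  expect_identical(lapply(same, `[[`, "frame"), lapply(pairs, `[[`, "frame"))
  expect_identical(lapply(same, `[[`, "mask"), lapply(pairs, `[[`, "mask"))
})

test_that("U-Net training reduces the loss and is seed-deterministic", {
  pairs <- phantom_pairs(70:85, 16)
  ucfg <- unet_config(16, 3, depth = 2, base_channels = 4)
  tc <- seg_train_config(epochs = 3, batch_size = 4, validation_split = 0.1,
                         learning_rate = 1e-3, rng_seed = 21)
  m1 <- train_unet(pairs, ucfg, tc)
  expect_lt(m1$log$train_loss[3], m1$log$train_loss[1])
  expect_true(all(is.finite(m1$log$train_loss)) && all(is.finite(m1$log$val_loss)))
  m2 <- train_unet(pairs, ucfg, tc)
  expect_identical(m1$log, m2$log)
  expect_error(train_unet(pairs[1], ucfg, tc), class = "cs_data_error")
  expect_error(train_unet(phantom_pairs(1:4, 32), ucfg, tc),
               class = "cs_resolution_error")
})

test_that("the 4-class LAX pathway trains and predicts all three chambers", {
  pairs <- phantom_pairs(130:141, 16, view = "LAX")
  ucfg <- unet_config(16, 4, depth = 2, base_channels = 4)
  m <- train_unet(pairs, ucfg,
                  seg_train_config(epochs = 2, batch_size = 4,
                                   validation_split = 0.1,
                                   learning_rate = 1e-3, rng_seed = 8))
  expect_identical(m$view, "LAX")
  pred <- predict_segmentation(m, pairs[[1]]$frame)
  expect_named(pred, c("LV", "RV", "RA"))
  expect_identical(sum(pred$LV & pred$RA), 0L)
})

test_that("predictions are disjoint label maps at the input size, better than empty masks", {
  pairs <- phantom_pairs(70:85, 16)
  ucfg <- unet_config(16, 3, depth = 2, base_channels = 4)
  m <- train_unet(pairs, ucfg,
                  seg_train_config(epochs = 15, batch_size = 4,
                                   validation_split = 0.1,
                                   learning_rate = 3e-3, rng_seed = 3))
  tp <- phantom_pairs(500, 16)[[1]]
  pred1 <- predict_segmentation(m, tp$frame)
  pred2 <- predict_segmentation(m, tp$frame)
  expect_identical(pred1, pred2)
  expect_named(pred1, c("LV", "RV"))
  expect_identical(dim(pred1$LV), c(16L, 16L))
  expect_identical(sum(pred1$LV & pred1$RV), 0L)
  truth <- chamber_masks(tp$mask, "SAX")
  expect_gt(dice_coefficient(pred1$LV, truth$LV),
            dice_coefficient(matrix(FALSE, 16, 16), truth$LV))
  expect_error(predict_segmentation(m, matrix(0, 32, 32)),
               class = "cs_resolution_error")
})
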