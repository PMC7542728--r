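test_that("Dice coefficient identities, symmetry and hand counts", {
  a <- matrix(FALSE, 8, 8); a[2:3, 2:3] <- TRUE
  expect_identical(dice_coefficient(a, a), 1)
  b <- matrix(FALSE, 8, 8); b[6:7, 6:7] <- TRUE
  expect_identical(dice_coefficient(a, b), 0)
  # |A| = 4, |B| = 4, overlap 2 -> 2*2/8
  c2 <- matrix(FALSE, 8, 8); c2[2:3, 3:4] <- TRUE
  expect_identical(dice_coefficient(a, c2), 0.5)
  expect_identical(dice_coefficient(a, c2), dice_coefficient(c2, a))
  expect_identical(dice_coefficient(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)), 1)
  expect_error(dice_coefficient(a, matrix(FALSE, 4, 4)), class = "cs_shape_error")
})

test_that("percent area variation ratios and degenerate cases", {
  t100 <- matrix(FALSE, 20, 20); t100[1:10, 1:10] <- TRUE
  expect_identical(percent_area_variation(t100, t100), 0)
  p110 <- t100; p110[11, 1:10] <- TRUE
  expect_identical(percent_area_variation(p110, t100), 0.1)
  expect_identical(percent_area_variation(matrix(FALSE, 20, 20), t100), 1)
  expect_error(percent_area_variation(t100, matrix(FALSE, 20, 20)),
               class = "cs_degenerate_error")
  # equal areas in different places: zero area variation but zero Dice
  off <- matrix(FALSE, 20, 20); off[11:20, 11:20] <- TRUE
  expect_identical(percent_area_variation(off, t100), 0)
  expect_identical(dice_coefficient(off, t100), 0)
})

test_that("median [IQR] uses linear interpolation and is order-invariant", {
  s <- median_iqr(c(1, 2, 3, 4, 5))
  expect_identical(c(s$q1, s$median, s$q3), c(2, 3, 4))
  sc <- median_iqr(rep(7.5, 10))
  expect_identical(c(sc$q1, sc$median, sc$q3), c(7.5, 7.5, 7.5))
  v <- rnorm(31)
  expect_identical(median_iqr(v)[1:3], median_iqr(sample(v))[1:3])
  expect_true(s$q1 <= s$median && s$median <= s$q3)
  expect_error(median_iqr(numeric(0)), class = "cs_stat_error")
})

test_that("signed-rank exact branch equals exhaustive sign enumeration (n = 8)", {
  set.seed(31)
  d <- round(rnorm(8, sd = 2), 3)
  d <- d + (duplicated(abs(d)) | d == 0) * 0.011 # ensure no zeros or ties
  x <- rnorm(8)
  y <- x + d
  got <- paired_wilcoxon(x, y)
  expect_identical(got$method, "exact")
  # enumeration oracle: distribution of V over all 2^8 sign assignments
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), 8))
  v_all <- as.matrix(signs) %*% r
  p_enum <- min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
  expect_equal(got$p_value, p_enum, tolerance = 1e-12)
  # agreement with the reference implementation on the same branch
  expect_equal(got$p_value, stats::wilcox.test(x, y, paired = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("a constant shift on 20 distinct pairs is detected and approximations agree with the reference", {
  set.seed(17)
  x <- rnorm(20)
  y <- x + 1
  expect_lt(paired_wilcoxon(x, y)$p_value, 0.05)
  # tie-corrected normal approximation branch matches wilcox.test
  x2 <- rnorm(40)
  y2 <- x2 + c(rep(0.4, 20), rep(-0.2, 20))
  got <- paired_wilcoxon(x2, y2)
  expect_identical(got$method, "normal_approx")
  ref <- suppressWarnings(stats::wilcox.test(x2, y2, paired = TRUE,
                                             exact = FALSE, correct = TRUE))
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  expect_error(paired_wilcoxon(1:10, 1:10), class = "cs_degenerate_error")
  expect_error(paired_wilcoxon(1:3, 2:4), class = "cs_stat_error")
})

test_that("type-I error of the signed-rank test is near nominal under the null", {
  set.seed(99)
  rejections <- 0L
  n_sim <- 1000L
  for (i in seq_len(n_sim)) {
    x <- rnorm(20)
    y <- rnorm(20)
    if (paired_wilcoxon(x, y)$p_value < 0.05) rejections <- rejections + 1L
  }
  rate <- rejections / n_sim
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("comparison report has the view's chamber rows, valid ranges, and flags degenerate self-comparison", {
  pairs <- phantom_pairs(300:315, 16)
  ucfg <- unet_config(16, 3, depth = 2, base_channels = 4)
  m1 <- train_unet(pairs, ucfg,
                   seg_train_config(epochs = 2, batch_size = 4,
                                    validation_split = 0.1,
                                    learning_rate = 1e-3, rng_seed = 1))
  m2 <- train_unet(pairs, ucfg,
                   seg_train_config(epochs = 2, batch_size = 4,
                                    validation_split = 0.1,
                                    learning_rate = 1e-3, rng_seed = 2))
  test_pairs <- phantom_pairs(400:409, 16)
  rep <- compare_training_sources(m1, m2, test_pairs)
  expect_s3_class(rep, "comparison_report")
  dice_rows <- rep$table[rep$table$metric == "dice", ]
  expect_setequal(dice_rows$chamber, c("LV", "RV"))
  expect_true(all(rep$table$median_a >= 0 & dice_rows$median_a <= 1))
  expect_true(all(rep$table[rep$table$metric == "percent_variation", ]$median_a >= 0))
  expect_true(all(rep$table$q1_a <= rep$table$median_a &
                    rep$table$median_a <= rep$table$q3_a))
  # self-comparison: every paired difference is zero
  rep_self <- compare_training_sources(m1, m1, test_pairs)
  expect_true(all(rep_self$table$degenerate))
  expect_true(all(is.na(rep_self$table$p_value)))
  expect_error(compare_training_sources(m1, m2, test_pairs[1:4]),
               class = "cs_stat_error")
  # tidy/glance accessors
  expect_identical(tidy(rep), rep$table)
  expect_identical(glance(rep)$n_frames, 10L)
})
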