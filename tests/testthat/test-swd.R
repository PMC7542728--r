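test_that("Laplacian pyramid reconstructs exactly and has the expected band count", {
  set.seed(3)
  img <- matrix(runif(64 * 64), 64, 64)
  pyr <- laplacian_pyramid(img, 16)
  expect_length(pyr, 3L) # 64, 32 difference bands + 16 residual
  expect_identical(vapply(pyr, function(b) b$resolution, numeric(1)), c(64, 32, 16))
  expect_lt(max(abs(reconstruct_pyramid(pyr) - img)), 1e-6)
  big <- matrix(runif(256 * 256), 256, 256)
  expect_length(laplacian_pyramid(big, 16), 5L)
  # constant image: all difference bands vanish, residual carries the constant
  cpyr <- laplacian_pyramid(matrix(0.4, 32, 32), 16)
  expect_lt(max(abs(cpyr[[1]]$image)), 1e-12)
  expect_equal(cpyr[[2]]$image, matrix(0.4, 16, 16), tolerance = 1e-12)
  expect_error(laplacian_pyramid(matrix(0, 48, 48), 16), class = "cs_size_error")
})

test_that("patch descriptors are seeded, standardized, and shape-correct", {
  band <- list(level = 0L, resolution = 32L,
               image = matrix(rnorm(32 * 32), 32, 32), is_residual = FALSE)
  d1 <- sample_patch_descriptors(band, 64, 7, 5)
  d2 <- sample_patch_descriptors(band, 64, 7, 5)
  expect_identical(d1, d2)
  expect_identical(dim(d1$patches), c(64L, 49L))
  expect_equal(unname(rowMeans(d1$patches)), rep(0, 64), tolerance = 1e-12)
  expect_equal(apply(d1$patches, 1, stats::sd), rep(1, 64), tolerance = 1e-12)
  const <- list(level = 0L, resolution = 16L, image = matrix(2, 16, 16),
                is_residual = TRUE)
  expect_true(all(sample_patch_descriptors(const, 8, 5, 1)$patches == 0))
  expect_error(sample_patch_descriptors(const, 8, 17, 1), class = "cs_patch_error")
})

test_that("sliced Wasserstein matches the brute-force project-sort-average oracle", {
  set.seed(8)
  for (trial in 1:5) {
    n <- sample(4:32, 1)
    d <- sample(c(1, 3, 10), 1)
    a <- matrix(rnorm(n * d), n, d)
    b <- matrix(rnorm(n * d), n, d)
    n_proj <- sample(1:8, 1)
    seed <- trial * 31L
    got <- sliced_wasserstein(a, b, n_proj, seed)
    dirs <- swd_directions(d, n_proj, seed)
    expect_equal(got, swd_oracle(a, b, dirs), tolerance = 1e-10)
    expect_gte(got, 0)
  }
})

test_that("sliced Wasserstein identity, 1-D shift closed form, and Lipschitz bound hold", {
  set.seed(4)
  a <- matrix(rnorm(20 * 5), 20, 5)
  expect_identical(sliced_wasserstein(a, a, 16, 3), 0)
  # 1-D: zero set vs constant c; any unit direction is +/-1, so distance = |c|
  z <- matrix(0, 10, 1)
  cc <- matrix(2.5, 10, 1)
  expect_equal(sliced_wasserstein(z, cc, 32, 9), 2.5, tolerance = 1e-12)
  # 1-D translation changes the distance to the zero set by at most |c|
  x <- matrix(rnorm(10), 10, 1)
  d0 <- sliced_wasserstein(x, z, 16, 2)
  d1 <- sliced_wasserstein(x + 0.7, z, 16, 2)
  expect_lte(abs(d1 - d0), 0.7 + 1e-12)
  expect_error(sliced_wasserstein(a, matrix(0, 20, 4), 8, 1),
               class = "cs_descriptor_error")
  expect_error(sliced_wasserstein(a, a[1:5, ], 8, 1),
               class = "cs_descriptor_error")
})

test_that("multi-scale distance is zero on identical sets, symmetric, and positive vs noise", {
  set_a <- phantom_frames(1:6, 32)
  cfg <- swd_config(n_patches = 32, n_projections = 64, seed = 7)
  r_same <- multiscale_swd(set_a, set_a, cfg)
  expect_equal(r_same$per_level$distance, rep(0, nrow(r_same$per_level)))
  set_b <- phantom_frames(11:16, 32)
  expect_identical(multiscale_swd(set_a, set_b, cfg)$average,
                   multiscale_swd(set_b, set_a, cfg)$average)
  noise <- cardiosynth:::with_seed(5, lapply(1:6, function(i)
    matrix(runif(32 * 32), 32, 32)))
  expect_gt(multiscale_swd(noise, set_a, cfg)$average, 0)
  expect_error(multiscale_swd(set_a, list(matrix(0, 16, 16)), cfg),
               class = "cs_size_error")
})

test_that("nearest-reference lookup retrieves exact and near copies first", {
  refs <- phantom_frames(21:25, 32)
  cfg <- swd_config(n_patches = 48, n_projections = 64, seed = 13)
  r <- rank_most_similar(refs[[3]], refs, cfg)
  expect_identical(r$ranking$index[1], 3L)
  expect_identical(r$ranking$distance[1], 0)
  expect_identical(sort(r$ranking$index), 1:5)
  expect_false(is.unsorted(r$ranking$distance))
  # a noisy copy outranks an unrelated phantom
  noisy <- pmin(pmax(refs[[1]] +
    cardiosynth:::with_seed(2, matrix(rnorm(32 * 32, sd = 0.02), 32, 32)), 0), 1)
  r2 <- rank_most_similar(refs[[1]], list(noisy, refs[[5]]), cfg)
  expect_identical(r2$ranking$index[1], 1L)
  expect_error(rank_most_similar(refs[[1]], list(), cfg),
               class = "cs_descriptor_error")
})
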