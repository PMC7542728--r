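# Multi-scale statistical similarity: Laplacian-pyramid band decomposition,
# normalized patch descriptors, and sliced Wasserstein distance (average over
# random 1-D projections of the exact 1-D Wasserstein-1 between projected
# point sets). Used both as a GAN quality audit and for nearest-real-image
# retrieval (memorization check).

# ---- Laplacian pyramid -------------------------------------------------------

# 5-tap binomial low-pass [1,4,6,4,1]/16, separable, symmetric boundary
blur5_1d <- function(m) {
  n <- nrow(m)
  reflect <- function(k) ifelse(k < 1, 2 - k, ifelse(k > n, 2 * n - k, k))
  k <- c(1, 4, 6, 4, 1) / 16
  out <- 0
  for (o in -2:2) out <- out + k[o + 3] * m[reflect(seq_len(n) + o), , drop = FALSE]
  out
}

blur5 <- function(img) t(blur5_1d(t(blur5_1d(img))))

pyr_down <- function(img) {
  b <- blur5(img)
  b[seq(1, nrow(b), 2), seq(1, ncol(b), 2), drop = FALSE]
}

pyr_up <- function(img) {
  n <- nrow(img)
  z <- matrix(0, 2 * n, 2 * n)
  z[seq(1, 2 * n, 2), seq(1, 2 * n, 2)] <- img
  4 * blur5(z)
}

#' Laplacian pyramid of a square image
#'
#' Decomposes an image into difference-of-lowpass bands from full resolution
#' down to `min_resolution`, plus the low-pass residual at `min_resolution`.
#' The decomposition is exactly invertible: [reconstruct_pyramid()] recovers
#' the input to numerical precision.
#'
#' @param image Square numeric matrix with power-of-two side.
#' @param min_resolution Coarsest level side (power of two, default 16).
#' @return List of bands; each band is a list with `level` (0 = finest),
#'   `resolution`, `image`, and `is_residual`.
#' @export
laplacian_pyramid <- function(image, min_resolution = 16) {
  side <- nrow(image)
  if (ncol(image) != side || !is_pow2(side))
    cs_abort("image must be square with power-of-two side", "cs_size_error")
  if (!is_pow2(min_resolution) || min_resolution > side)
    cs_abort("min_resolution must be a power of two <= image side", "cs_size_error")
  bands <- list()
  cur <- unclass(image)
  attributes(cur) <- list(dim = dim(image))
  lvl <- 0L
  while (nrow(cur) > min_resolution) {
    low <- pyr_down(cur)
    bands[[lvl + 1L]] <- list(level = lvl, resolution = nrow(cur),
                              image = cur - pyr_up(low), is_residual = FALSE)
    cur <- low
    lvl <- lvl + 1L
  }
  bands[[lvl + 1L]] <- list(level = lvl, resolution = nrow(cur),
                            image = cur, is_residual = TRUE)
  bands
}

#' @rdname laplacian_pyramid
#' @param bands A list of bands as returned by [laplacian_pyramid()].
#' @export
reconstruct_pyramid <- function(bands) {
  cur <- bands[[length(bands)]]$image
  for (i in rev(seq_len(length(bands) - 1L))) cur <- bands[[i]]$image + pyr_up(cur)
  cur
}

# ---- patch descriptors -------------------------------------------------------

#' Sample normalized patch descriptors from a pyramid band
#'
#' Draws `n_patches` square patches at uniformly random valid top-left
#' positions and standardizes each patch to mean 0 and standard deviation 1
#' (constant patches map to the all-zero vector), removing trivial brightness
#' matches.
#'
#' @param band A band from [laplacian_pyramid()].
#' @param n_patches Number of patches (>= 1).
#' @param patch_size Patch side (default 7); must not exceed the band side.
#' @param rng_seed Integer seed.
#' @return A `descriptor_set`: matrix (`n_patches` x `patch_size^2`) plus
#'   `level` and `patch_size` attributes.
#' @export
sample_patch_descriptors <- function(band, n_patches, patch_size = 7, rng_seed = 1L) {
  img <- band$image
  side <- nrow(img)
  if (patch_size > side)
    cs_abort("patch_size exceeds band side", "cs_patch_error")
  stopifnot(n_patches >= 1)
  pos_max <- side - patch_size + 1L
  rc <- with_seed(rng_seed, cbind(sample.int(pos_max, n_patches, replace = TRUE),
                                  sample.int(pos_max, n_patches, replace = TRUE)))
  d <- patch_size^2
  patches <- matrix(0, n_patches, d)
  for (i in seq_len(n_patches)) {
    p <- img[rc[i, 1]:(rc[i, 1] + patch_size - 1L),
             rc[i, 2]:(rc[i, 2] + patch_size - 1L)]
    mu <- mean(p)
    s <- stats::sd(p)
    patches[i, ] <- if (s > 0) (as.vector(p) - mu) / s else rep(0, d)
  }
  structure(list(patches = patches, level = band$level, patch_size = patch_size),
            class = "descriptor_set")
}

#' Sliced Wasserstein distance between two descriptor sets
#'
#' Averages, over `n_projections` random unit directions, the exact 1-D
#' Wasserstein-1 distance between the projected point sets (mean absolute
#' difference of sorted projections). Requires equally sized sets of equal
#' dimensionality.
#'
#' @param descA,descB `descriptor_set` objects (or plain matrices with
#'   observations in rows).
#' @param n_projections Number of random unit directions.
#' @param rng_seed Integer seed for the directions.
#' @return Nonnegative scalar distance; 0 for identical sets.
#' @export
sliced_wasserstein <- function(descA, descB, n_projections = 256, rng_seed = 1L) {
  a <- if (inherits(descA, "descriptor_set")) descA$patches else as.matrix(descA)
  b <- if (inherits(descB, "descriptor_set")) descB$patches else as.matrix(descB)
  if (nrow(a) == 0L || nrow(b) == 0L)
    cs_abort("descriptor sets must be non-empty", "cs_descriptor_error")
  if (ncol(a) != ncol(b))
    cs_abort("descriptor dimensionality mismatch", "cs_descriptor_error")
  if (nrow(a) != nrow(b))
    cs_abort("descriptor sets must have equal size", "cs_descriptor_error")
  d <- ncol(a)
  dirs <- with_seed(rng_seed, {
    m <- matrix(rnorm(d * n_projections), d, n_projections)
    sweep(m, 2, sqrt(colSums(m^2)), "/")
  })
  pa <- a %*% dirs
  pb <- b %*% dirs
  sa <- apply(pa, 2, sort, method = "quick")
  sb <- apply(pb, 2, sort, method = "quick")
  mean(abs(sa - sb))
}

# ---- multi-scale comparison --------------------------------------------------

#' SWD configuration
#'
#' @param min_resolution Coarsest pyramid level (default 16).
#' @param patch_size Patch side (default 7).
#' @param n_patches Patches per image per level (default 128).
#' @param n_projections Random directions per level (default 256).
#' @param seed Master seed for patch positions and projections.
#' @export
swd_config <- function(min_resolution = 16, patch_size = 7, n_patches = 128,
                       n_projections = 256, seed = 1L) {
  list(min_resolution = min_resolution, patch_size = patch_size,
       n_patches = n_patches, n_projections = n_projections,
       seed = as.integer(seed))
}

# descriptors per pyramid level for one image; patch-position seeds depend on
# (level, image index) only, never on which set the image belongs to, so the
# distance is exactly symmetric under set exchange and zero for identical sets
image_level_descriptors <- function(image, config, image_index) {
  bands <- laplacian_pyramid(image, config$min_resolution)
  lapply(bands, function(b) {
    ps <- min(config$patch_size, b$resolution)
    sample_patch_descriptors(b, config$n_patches, ps,
                             derive_seed(config$seed, paste0("patch_L", b$level),
                                         image_index))
  })
}

pool_level_descriptors <- function(images, config) {
  per_img <- lapply(seq_along(images), function(i)
    image_level_descriptors(images[[i]], config, i))
  n_levels <- length(per_img[[1]])
  lapply(seq_len(n_levels), function(l)
    do.call(rbind, lapply(per_img, function(x) x[[l]]$patches)))
}

#' Multi-scale sliced Wasserstein distance between two image sets
#'
#' Pools normalized patch descriptors per Laplacian-pyramid level across each
#' set and reports the sliced Wasserstein distance per level plus their mean.
#'
#' @param setA,setB Lists of square numeric matrices, all of the same
#'   power-of-two size.
#' @param config From [swd_config()].
#' @return An `swd_result` with `per_level` (tibble: level, resolution,
#'   distance) and `average`.
#' @export
multiscale_swd <- function(setA, setB, config = swd_config()) {
  sizes <- vapply(c(setA, setB), nrow, integer(1))
  if (length(unique(sizes)) != 1L)
    cs_abort("all images must share one square power-of-two size", "cs_size_error")
  da <- pool_level_descriptors(setA, config)
  db <- pool_level_descriptors(setB, config)
  # equalize pooled set sizes if the image counts differ
  n <- min(nrow(da[[1]]), nrow(db[[1]]))
  res <- nrow(setA[[1]])
  levels <- seq_along(da) - 1L
  dist <- vapply(seq_along(da), function(l) {
    a <- da[[l]]; b <- db[[l]]
    if (nrow(a) > n) a <- a[with_seed(derive_seed(config$seed, "subsample_a", l),
                                      sample.int(nrow(a), n)), , drop = FALSE]
    if (nrow(b) > n) b <- b[with_seed(derive_seed(config$seed, "subsample_b", l),
                                      sample.int(nrow(b), n)), , drop = FALSE]
    sliced_wasserstein(a, b, config$n_projections,
                       derive_seed(config$seed, "proj_L", l - 1L))
  }, numeric(1))
  structure(list(
    per_level = tibble::tibble(level = levels,
                               resolution = res %/% 2^levels,
                               distance = dist),
    average = mean(dist)
  ), class = "swd_result")
}

#' @export
print.swd_result <- function(x, ...) {
  cat("<swd_result> average distance:", format(x$average, digits = 6), "\n")
  print(x$per_level)
  if (!is.null(x$ranking)) {
    cat("top of ranking:\n")
    print(utils::head(x$ranking, 3))
  }
  invisible(x)
}

#' Rank reference images by similarity to a query
#'
#' Computes the average multi-scale sliced Wasserstein distance from the query
#' to every reference and returns references in ascending distance order —
#' the nearest-real-image lookup used to audit GAN memorization.
#'
#' @param query Square numeric matrix.
#' @param references Non-empty list of matrices of the same size as `query`.
#' @param config From [swd_config()].
#' @return An `swd_result` whose `ranking` tibble has columns
#'   `rank`, `index`, `distance`.
#' @export
rank_most_similar <- function(query, references, config = swd_config()) {
  if (length(references) == 0L)
    cs_abort("references must be non-empty", "cs_descriptor_error")
  qd <- image_level_descriptors(query, config, 1L)
  dist <- vapply(references, function(ref) {
    rd <- image_level_descriptors(ref, config, 1L)
    mean(vapply(seq_along(qd), function(l)
      sliced_wasserstein(qd[[l]], rd[[l]], config$n_projections,
                         derive_seed(config$seed, "proj_L", l - 1L)),
      numeric(1)))
  }, numeric(1))
  ord <- order(dist)
  structure(list(
    per_level = NULL,
    average = min(dist),
    ranking = tibble::tibble(rank = seq_along(ord), index = ord,
                             distance = dist[ord])
  ), class = "swd_result")
}
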