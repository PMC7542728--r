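# Paired geometric augmentation: one random affine (rotation, shift, shear,
# zoom; flips disabled) applied identically to a frame (bilinear) and its
# label mask (nearest neighbour, so labels are preserved exactly).

#' Augmentation limits
#'
#' Defaults reproduce the training recipe: rotations within +/-20 degrees,
#' width/height shifts of 5%, shear up to 20%, zoom up to 10%, flipping
#' disabled.
#'
#' @param rotation_limit Max absolute rotation, degrees.
#' @param width_shift,height_shift Max shift as a fraction of the side.
#' @param shear_limit Max absolute shear factor.
#' @param zoom_limit Max absolute relative zoom.
#' @param flips Must remain `FALSE` in the faithful recipe.
#' @return An `augmentation_spec`.
#' @export
augmentation_spec <- function(rotation_limit = 20, width_shift = 0.05,
                              height_shift = 0.05, shear_limit = 0.20,
                              zoom_limit = 0.10, flips = FALSE) {
  stopifnot(rotation_limit >= 0, width_shift >= 0, height_shift >= 0,
            shear_limit >= 0, zoom_limit >= 0)
  structure(list(rotation_limit = rotation_limit, width_shift = width_shift,
                 height_shift = height_shift, shear_limit = shear_limit,
                 zoom_limit = zoom_limit, flips = isTRUE(flips)),
            class = "augmentation_spec")
}

# draw one affine transform within the spec limits; returns the inverse 2x2
# map and translation used for output -> input coordinate lookup
draw_affine <- function(spec, side) {
  rot <- runif(1, -spec$rotation_limit, spec$rotation_limit) * pi / 180
  tx <- runif(1, -spec$width_shift, spec$width_shift) * side
  ty <- runif(1, -spec$height_shift, spec$height_shift) * side
  sh <- runif(1, -spec$shear_limit, spec$shear_limit)
  zm <- 1 + runif(1, -spec$zoom_limit, spec$zoom_limit)
  R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2, 2)
  S <- matrix(c(1, 0, sh, 1), 2, 2)
  M <- (R %*% S) * zm
  list(Minv = solve(M), t = c(tx, ty))
}

apply_affine <- function(img, tr, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  side <- nrow(img)
  ctr <- (side - 1) / 2
  g <- seq_len(side) - 1
  oy <- matrix(rep(g, side), side, side)          # row
  ox <- matrix(rep(g, each = side), side, side)   # col
  dx <- ox - ctr - tr$t[1]
  dy <- oy - ctr - tr$t[2]
  ix <- tr$Minv[1, 1] * dx + tr$Minv[1, 2] * dy + ctr
  iy <- tr$Minv[2, 1] * dx + tr$Minv[2, 2] * dy + ctr
  v <- if (interp == "bilinear") sample_bilinear(img, as.vector(iy), as.vector(ix))
  else sample_nearest(img, as.vector(iy), as.vector(ix))
  matrix(v, side, side)
}

#' Augment one frame/mask pair
#'
#' Draws a single affine transform within the spec limits and applies it
#' identically to the frame (bilinear interpolation) and the mask (nearest
#' neighbour). With all limits zero the pair is returned unchanged.
#'
#' @param image Numeric frame matrix.
#' @param mask Integer label matrix of the same shape.
#' @param spec An [augmentation_spec()].
#' @param rng_seed Integer seed; the transform is deterministic given it.
#' @return List with `frame` and `mask`.
#' @export
augment_pair <- function(image, mask, spec = augmentation_spec(), rng_seed = 1L) {
  if (!identical(dim(image), dim(mask)))
    cs_abort("image and mask resolutions differ", "cs_shape_error")
  tr <- with_seed(rng_seed, draw_affine(spec, nrow(image)))
  identity_tr <- all(abs(tr$Minv - diag(2)) < 1e-12) && all(tr$t == 0)
  if (identity_tr) return(list(frame = image, mask = mask))
  m <- apply_affine(mask, tr, "nearest")
  storage.mode(m) <- "integer"
  list(frame = apply_affine(image, tr, "bilinear"), mask = m)
}

#' Expand a dataset by repeated augmentation
#'
#' Produces `factor` augmented copies of every input pair (so 1,000 pairs and
#' factor 10 give 10,000), with per-item seeds derived deterministically from
#' `rng_seed`.
#'
#' @param pairs List of `list(frame, mask, ...)` entries.
#' @param spec An [augmentation_spec()].
#' @param factor Number of augmented copies per input pair (>= 1).
#' @param rng_seed Integer seed.
#' @return List of `factor * length(pairs)` pairs.
#' @export
expand_dataset <- function(pairs, spec = augmentation_spec(), factor = 1L,
                           rng_seed = 1L) {
  stopifnot(factor >= 1)
  out <- vector("list", length(pairs) * factor)
  k <- 0L
  for (j in seq_len(factor)) {
    for (i in seq_along(pairs)) {
      k <- k + 1L
      a <- augment_pair(pairs[[i]]$frame, pairs[[i]]$mask, spec,
                        derive_seed(rng_seed, "augment", (j - 1L) * length(pairs) + i))
      p <- pairs[[i]]
      p$frame <- a$frame
      p$mask <- a$mask
      out[[k]] <- p
    }
  }
  out
}
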