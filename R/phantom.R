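# Cardiac phantom generator: seeded short-axis (SAX) and 4-chamber long-axis
# (LAX) cine-style frames with ground-truth chamber masks. The phantom is a
# piecewise-constant tissue model (blood pool / myocardium / background) built
# from rotated ellipses, plus additive Gaussian noise clipped to [0, 1]. It
# stands in for patient data so the GAN, the similarity audit and the
# segmentation stage are all exercisable without any download.

phantom_midpoints <- function(view) {
  view <- toupper(view)
  if (view == "SAX") {
    list(
      LV = list(center = c(0.60, 0.52), semi = c(0.14, 0.14),
                orientation = 0, wall_ratio = 1.50),
      RV = list(center = c(0.33, 0.47), semi = c(0.17, 0.21),
                orientation = -20, wall_ratio = 1.15)
    )
  } else if (view == "LAX") {
    list(
      LV = list(center = c(0.66, 0.35), semi = c(0.115, 0.185),
                orientation = 10, wall_ratio = 1.18),
      RV = list(center = c(0.32, 0.33), semi = c(0.105, 0.175),
                orientation = -8, wall_ratio = 1.18),
      RA = list(center = c(0.38, 0.72), semi = c(0.115, 0.135),
                orientation = 0, wall_ratio = 1.18)
    )
  } else cs_abort(paste0("unknown view: ", view), "cs_view_error")
}

#' Draw randomized phantom parameters
#'
#' Chamber geometry, tissue intensities, noise level and a global rotation are
#' drawn uniformly within `variability`-scaled bands around configured
#' anatomical midpoints. `variability = 0` returns the midpoints exactly.
#' Chamber centers are clamped so every chamber (including its myocardial
#' wall) lies fully inside the unit frame for any draw.
#'
#' @param view `"SAX"` (chambers LV, RV) or `"LAX"` (LV, RV, RA).
#' @param rng_seed Integer seed; identical seeds give identical parameters.
#' @param variability Fraction in `[0, 1]` scaling all random bands.
#' @return A `phantom_params` object.
#' @export
make_phantom_params <- function(view, rng_seed, variability = 0.2) {
  if (!toupper(view) %in% c("SAX", "LAX"))
    cs_abort(paste0("unknown view: ", view), "cs_view_error")
  stopifnot(variability >= 0, variability <= 1)
  view <- toupper(view)
  mids <- phantom_midpoints(view)
  v <- variability
  u <- function() runif(1, -1, 1)
  params <- with_seed(rng_seed, {
    chambers <- lapply(mids, function(ch) {
      ch$center <- ch$center + c(u(), u()) * 0.05 * v
      ch$semi <- ch$semi * (1 + c(u(), u()) * 0.25 * v)
      ch$orientation <- ch$orientation + u() * 12 * v
      # clamp so the full wall stays inside the frame
      ext <- max(ch$semi) * ch$wall_ratio + 0.02
      ch$center <- pmin(pmax(ch$center, ext), 1 - ext)
      ch
    })
    list(
      view = view,
      chambers = chambers,
      intensities = list(
        blood_pool_mean = 0.85 + u() * 0.08 * v,
        myocardium_mean = 0.45 + u() * 0.08 * v,
        background_mean = 0.12 + u() * 0.05 * v
      ),
      noise_sd = 0.03 * (1 + u() * 0.5 * v),
      global_rotation = u() * 15 * v,
      seed = as.integer(rng_seed)
    )
  })
  structure(params, class = "phantom_params")
}

validate_phantom_params <- function(p) {
  stopifnot(inherits(p, "phantom_params"))
  ints <- p$intensities
  if (!(ints$blood_pool_mean > ints$myocardium_mean &&
        ints$myocardium_mean > ints$background_mean))
    cs_abort("intensity ordering blood > myocardium > background violated",
             "cs_params_error")
  expected <- chambers_for_view(p$view)
  if (!identical(sort(names(p$chambers)), sort(expected)))
    cs_abort("chamber set does not match view", "cs_params_error")
  for (ch in p$chambers) {
    ext <- max(ch$semi) * ch$wall_ratio
    if (any(ch$center - ext < 0) || any(ch$center + ext > 1))
      cs_abort("chamber geometry extends outside the frame", "cs_params_error")
  }
  invisible(p)
}

# squared normalized ellipse coordinate: <= 1 inside the ellipse
ellipse_q <- function(px, py, ch) {
  th <- ch$orientation * pi / 180
  dx <- px - ch$center[1]; dy <- py - ch$center[2]
  u <- cos(th) * dx + sin(th) * dy
  v <- -sin(th) * dx + cos(th) * dy
  (u / ch$semi[1])^2 + (v / ch$semi[2])^2
}

#' Render a phantom frame and its chamber masks
#'
#' Rasterizes the piecewise-constant tissue model at the requested resolution
#' (pixel centers at `(i + 0.5) / res`, row-major, origin top-left), adds
#' seeded Gaussian noise, and clips intensities to `[0, 1]`. Chamber masks are
#' the blood-pool regions; pools are assigned with a priority order
#' (LV, RV, RA) and a small exclusion margin, so they are pairwise disjoint
#' and separated by a myocardial wall.
#'
#' @param params A `phantom_params` object.
#' @param resolution Side length; power of two in `[4, 256]`.
#' @return List with `frame` (numeric matrix in `[0, 1]`) and `mask`
#'   (integer label matrix: 0 background, 1 LV, 2 RV, 3 RA).
#' @export
render_phantom <- function(params, resolution) {
  validate_phantom_params(params)
  if (!is_pow2(resolution) || resolution < 4 || resolution > 256)
    cs_abort("resolution must be a power of two in [4, 256]", "cs_resolution_error")
  res <- as.integer(resolution)
  g <- (seq_len(res) - 0.5) / res
  py <- matrix(rep(g, res), res, res)        # row coordinate (y)
  px <- matrix(rep(g, each = res), res, res) # column coordinate (x)
  # inverse global rotation about the frame center
  th <- -params$global_rotation * pi / 180
  dx <- px - 0.5; dy <- py - 0.5
  rx <- 0.5 + cos(th) * dx - sin(th) * dy
  ry <- 0.5 + sin(th) * dx + cos(th) * dy

  CLS_BG <- 0L; CLS_MYO <- 9L
  cls <- matrix(CLS_BG, res, res)
  chn <- names(params$chambers)
  q <- lapply(params$chambers, function(ch) ellipse_q(rx, ry, ch))

  if (params$view == "SAX") {
    lv <- params$chambers$LV; rv <- params$chambers$RV
    cls[q$LV <= lv$wall_ratio^2] <- CLS_MYO
    cls[q$LV <= 1] <- MASK_LABELS[["LV"]]
    excl <- q$LV <= (lv$wall_ratio * 1.06)^2
    cls[q$RV <= rv$wall_ratio^2 & cls == CLS_BG] <- CLS_MYO
    cls[q$RV <= 1 & !excl] <- MASK_LABELS[["RV"]]
  } else {
    for (nm in chn)
      cls[q[[nm]] <= params$chambers[[nm]]$wall_ratio^2 & cls == CLS_BG] <- CLS_MYO
    assigned <- matrix(FALSE, res, res)
    for (nm in chn) {
      pool <- q[[nm]] <= 1 & !assigned
      cls[pool] <- MASK_LABELS[[nm]]
      assigned <- assigned | q[[nm]] <= 1.15^2
    }
  }

  ints <- params$intensities
  frame <- matrix(ints$background_mean, res, res)
  frame[cls == CLS_MYO] <- ints$myocardium_mean
  frame[cls %in% MASK_LABELS] <- ints$blood_pool_mean
  if (params$noise_sd > 0) {
    noise <- with_seed(derive_seed(params$seed, "render_noise", res),
                       matrix(rnorm(res * res, sd = params$noise_sd), res, res))
    frame <- frame + noise
  }
  frame <- pmin(pmax(frame, 0), 1)
  mask <- cls
  mask[cls == CLS_MYO] <- 0L
  storage.mode(mask) <- "integer"
  list(frame = frame, mask = mask)
}

#' Generate a phantom dataset on disk
#'
#' Writes `n` frame/mask PNG pairs plus a `manifest.csv`
#' (columns `frame`, `mask`, `view`, `seed`). Per-entry seeds are derived
#' deterministically from `rng_seed`, so a rerun with the same arguments
#' reproduces every file bitwise.
#'
#' @inheritParams make_phantom_params
#' @param n Number of frame/mask pairs (>= 1).
#' @param resolution Power of two in `[4, 256]`.
#' @param out_dir Output directory (created if missing).
#' @return A `phantom_dataset` object: manifest tibble, directory, view,
#'   resolution, and the per-entry parameter draws.
#' @export
generate_phantom_dataset <- function(n, view, resolution, rng_seed, out_dir,
                                     variability = 0.2) {
  stopifnot(n >= 1)
  if (!dir.exists(out_dir)) {
    ok <- tryCatch(dir.create(out_dir, recursive = TRUE), warning = function(w) FALSE)
    if (!isTRUE(ok) || !dir.exists(out_dir))
      cs_abort(paste0("cannot create output directory: ", out_dir), "cs_io_error")
  }
  if (file.access(out_dir, 2) != 0)
    cs_abort(paste0("output directory not writable: ", out_dir), "cs_io_error")
  entries <- vector("list", n)
  params_list <- vector("list", n)
  for (i in seq_len(n)) {
    si <- derive_seed(rng_seed, "phantom_entry", i)
    p <- make_phantom_params(view, si, variability)
    r <- render_phantom(p, resolution)
    f <- sprintf("frame_%04d.png", i)
    m <- sprintf("mask_%04d.png", i)
    write_frame(r$frame, file.path(out_dir, f))
    write_mask(r$mask, file.path(out_dir, m))
    entries[[i]] <- data.frame(frame = f, mask = m, view = toupper(view),
                               seed = si, stringsAsFactors = FALSE)
    params_list[[i]] <- p
  }
  manifest <- tibble::as_tibble(do.call(rbind, entries))
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  structure(list(manifest = manifest, dir = out_dir, view = toupper(view),
                 resolution = as.integer(resolution), params = params_list,
                 manifest_path = file.path(out_dir, "manifest.csv")),
            class = "phantom_dataset")
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cat(sprintf("<phantom_dataset> %d %s frames @ %d x %d in %s\n",
              nrow(x$manifest), x$view, x$resolution, x$resolution, x$dir))
  invisible(x)
}

# simple binary dilation by one 4-neighbour step, applied `steps` times
dilate_binary <- function(m, steps = 1L) {
  for (k in seq_len(steps)) {
    h <- nrow(m); w <- ncol(m)
    out <- m
    out[-1, ] <- out[-1, ] | m[-h, ]
    out[-h, ] <- out[-h, ] | m[-1, ]
    out[, -1] <- out[, -1] | m[, -w]
    out[, -w] <- out[, -w] | m[, -1]
    m <- out
  }
  m
}
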