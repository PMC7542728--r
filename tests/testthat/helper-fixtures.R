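# Shared fixture builders: all test data is generated in code at run time.

phantom_pairs <- function(seeds, res = 32, view = "SAX", variability = 0.2) {
  lapply(seeds, function(i) {
    p <- make_phantom_params(view, i, variability)
    r <- render_phantom(p, res)
    list(frame = r$frame, mask = r$mask, view = view, seed = i)
  })
}

phantom_frames <- function(seeds, res = 32, view = "SAX") {
  lapply(phantom_pairs(seeds, res, view), `[[`, "frame")
}

median_dice_by_chamber <- function(model, test_pairs, view = "SAX") {
  ch <- chamber_masks(test_pairs[[1]]$mask, view)
  vals <- sapply(test_pairs, function(tp) {
    pred <- predict_segmentation(model, tp$frame)
    truth <- chamber_masks(tp$mask, view)
    vapply(names(truth), function(nm)
      dice_coefficient(pred[[nm]], truth[[nm]]), numeric(1))
  })
  apply(matrix(vals, nrow = length(ch)), 1, stats::median) |>
    stats::setNames(names(ch))
}

# brute-force sliced Wasserstein oracle: explicit per-direction loop of
# project -> sort -> mean absolute difference
swd_oracle <- function(a, b, dirs) {
  tot <- 0
  for (j in seq_len(ncol(dirs))) {
    pa <- sort(as.vector(a %*% dirs[, j]))
    pb <- sort(as.vector(b %*% dirs[, j]))
    tot <- tot + mean(abs(pa - pb))
  }
  tot / ncol(dirs)
}

# the package's direction-draw, reproduced independently for oracle tests
swd_directions <- function(d, n_proj, seed) {
  cardiosynth:::with_seed(seed, {
    m <- matrix(stats::rnorm(d * n_proj), d, n_proj)
    sweep(m, 2, sqrt(colSums(m^2)), "/")
  })
}
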