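test_that("parameter draws are seeded, midpoint-exact at zero variability, and view-consistent", {
  expect_identical(make_phantom_params("SAX", 7, 0.2),
                   make_phantom_params("SAX", 7, 0.2))
  mids <- cardiosynth:::phantom_midpoints("SAX")
  p0 <- make_phantom_params("SAX", 123, 0)
  expect_equal(p0$chambers$LV$center, mids$LV$center)
  expect_equal(p0$chambers$RV$semi, mids$RV$semi)
  expect_equal(p0$intensities$blood_pool_mean, 0.85)
  expect_setequal(names(make_phantom_params("LAX", 1, 0.2)$chambers),
                  c("LV", "RV", "RA"))
  expect_setequal(names(make_phantom_params("SAX", 1, 0.2)$chambers),
                  c("LV", "RV"))
  expect_error(make_phantom_params("APICAL", 1, 0.2), class = "cs_view_error")
})

test_that("every draw keeps contrast ordering and in-frame geometry, even at maximal variability", {
  for (seed in 1:50) {
    p <- make_phantom_params(if (seed %% 2) "SAX" else "LAX", seed, 1)
    expect_no_error(cardiosynth:::validate_phantom_params(p))
  }
})

test_that("rendering is deterministic, label-complete and intensity-ordered", {
  p <- make_phantom_params("SAX", 11, 0.2)
  p$noise_sd <- 0
  r1 <- render_phantom(p, 32)
  r2 <- render_phantom(p, 32)
  expect_identical(r1, r2)
  expect_true(all(r1$frame >= 0 & r1$frame <= 1))
  expect_setequal(unique(as.vector(r1$mask)), c(0L, 1L, 2L))
  lax <- render_phantom(make_phantom_params("LAX", 5, 0.2), 32)
  expect_setequal(unique(as.vector(lax$mask)), c(0L, 1L, 2L, 3L))
  expect_error(render_phantom(p, 48), class = "cs_resolution_error")
  expect_error(render_phantom(p, 512), class = "cs_resolution_error")
})

test_that("mask areas scale with resolution and pools exceed the myocardial ring by 2 sd", {
  for (seed in c(3, 17, 42)) {
    p <- make_phantom_params("SAX", seed, 0.2)
    r32 <- render_phantom(p, 32)
    r64 <- render_phantom(p, 64)
    for (lab in 1:2) {
      ratio <- sum(r64$mask == lab) / sum(r32$mask == lab)
      expect_gt(ratio, 4 * 0.9)
      expect_lt(ratio, 4 * 1.1)
    }
    cm <- chamber_masks(r64$mask, "SAX")
    for (nm in names(cm)) {
      ring <- cardiosynth:::dilate_binary(cm[[nm]], 2) &
        !cardiosynth:::dilate_binary(cm[[nm]], 1)
      expect_gt(mean(r64$frame[cm[[nm]]]),
                mean(r64$frame[ring]) + 2 * p$noise_sd)
    }
  }
})

test_that("chamber masks are pairwise disjoint", {
  r <- render_phantom(make_phantom_params("LAX", 9, 0.5), 64)
  cm <- chamber_masks(r$mask, "LAX")
  n_union <- sum(Reduce(`|`, cm))
  expect_identical(sum(vapply(cm, sum, numeric(1))), as.numeric(n_union))
})

test_that("dataset generation is bitwise reproducible with distinct entries and a lossless manifest", {
  d1 <- file.path(tempdir(), "ph_a"); d2 <- file.path(tempdir(), "ph_b")
  unlink(c(d1, d2), recursive = TRUE)
  ds1 <- generate_phantom_dataset(10, "SAX", 32, 3, d1)
  ds2 <- generate_phantom_dataset(10, "SAX", 32, 3, d2)
  f1 <- list.files(d1); f2 <- list.files(d2)
  expect_identical(f1, f2)
  for (f in f1)
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  expect_identical(nrow(generate_phantom_dataset(
    1, "SAX", 16, 5, file.path(tempdir(), "ph_one"))$manifest), 1L)
  # all frames distinct
  hashes <- vapply(ds1$manifest$frame, function(f)
    paste(readBin(file.path(d1, f), "raw", 1e6), collapse = ""), character(1))
  expect_identical(anyDuplicated(hashes), 0L)
  # manifest round-trip
  man <- read_manifest(ds1$manifest_path)
  expect_equal(as.data.frame(man), as.data.frame(ds1$manifest))
  # unwritable output location
  blocker <- tempfile(); file.create(blocker)
  expect_error(generate_phantom_dataset(1, "SAX", 16, 1,
                                        file.path(blocker, "sub")),
               class = "cs_io_error")
})
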