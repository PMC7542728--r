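# End-to-end study pipeline: phantom dataset -> progressive GAN -> synthetic
# sampling -> SWD audit (including nearest-reference memorization lookup) ->
# two U-Net trainings (synthetic-trained vs directly trained) -> held-out
# comparison report. Every stage receives a seed derived from the master seed;
# a rerun with the same config reproduces the report bitwise.

#' Fit phantom parameters to an image (annotation stand-in)
#'
#' Two-stage random search over phantom parameters minimizing the squared
#' intensity difference between the noiseless phantom render and the target
#' image. Plays the role of the human annotator for synthetic frames: the
#' fitted phantom's ground-truth mask becomes the frame's label map.
#'
#' @param image Square frame matrix in `[0, 1]` at a supported resolution.
#' @param view `"SAX"` or `"LAX"`.
#' @param rng_seed Integer seed.
#' @param n_coarse Candidates in the global search stage.
#' @param n_refine Candidates in the local refinement stage.
#' @param variability Search breadth for the global stage.
#' @return List with `mask` (label matrix), `params` (fitted
#'   `phantom_params`) and `rss` (residual sum of squares).
#' @export
annotate_frame <- function(image, view, rng_seed = 1L, n_coarse = 150,
                           n_refine = 80, variability = 0.3) {
  res <- nrow(image)
  best <- NULL
  score <- function(p) {
    p$noise_sd <- 0
    r <- render_phantom(p, res)
    list(rss = sum((r$frame - image)^2), mask = r$mask, params = p)
  }
  for (i in seq_len(n_coarse)) {
    p <- make_phantom_params(view, derive_seed(rng_seed, "annot_coarse", i),
                             variability)
    s <- score(p)
    if (is.null(best) || s$rss < best$rss) best <- s
  }
  for (i in seq_len(n_refine)) {
    p <- jitter_params(best$params, derive_seed(rng_seed, "annot_refine", i))
    s <- score(p)
    if (s$rss < best$rss) best <- s
  }
  best
}

# local perturbation of phantom parameters for refinement search
jitter_params <- function(params, rng_seed) {
  with_seed(rng_seed, {
    p <- params
    u <- function() runif(1, -1, 1)
    for (nm in names(p$chambers)) {
      ch <- p$chambers[[nm]]
      ch$center <- ch$center + c(u(), u()) * 0.02
      ch$semi <- ch$semi * (1 + c(u(), u()) * 0.06)
      ch$orientation <- ch$orientation + u() * 4
      ext <- max(ch$semi) * ch$wall_ratio + 0.02
      ch$center <- pmin(pmax(ch$center, ext), 1 - ext)
      p$chambers[[nm]] <- ch
    }
    p$intensities$blood_pool_mean <- min(1, max(p$intensities$myocardium_mean + 0.05,
      p$intensities$blood_pool_mean + u() * 0.03))
    p$intensities$myocardium_mean <- min(p$intensities$blood_pool_mean - 0.05,
      max(p$intensities$background_mean + 0.05,
          p$intensities$myocardium_mean + u() * 0.03))
    p$global_rotation <- p$global_rotation + u() * 3
    p
  })
}

#' Pipeline configuration
#'
#' Bundles every stage's settings plus the master seed from which all stage
#' seeds are derived. Defaults are the desk-scale study conditions: 32 px
#' frames, 200 GAN training phantoms, 100 synthetic frames, 100 directly
#' rendered training frames and a 50-frame held-out test set.
#'
#' @param out_dir Run directory (created).
#' @param view `"SAX"` or `"LAX"`.
#' @param resolution Working resolution (power of two in `[4, 256]`).
#' @param master_seed Integer master seed.
#' @param n_gan_train,n_synthetic,n_direct_train,n_test Stage sample sizes.
#' @param phantom_variability Anatomical variability of the phantom draws.
#' @param gan_filters,gan_steps,gan_batch,fade_fraction Progressive GAN
#'   settings (per-stage vectors recycled as needed).
#' @param gan_stabilizer,gan_clip,gan_n_critic,gan_lr Critic stabilization and
#'   optimization. The desk-scale default is weight clipping with three critic
#'   steps per generator step: at these small step counts the gradient-penalty
#'   estimator's noise dominates the small Wasserstein gap, while clipping
#'   trains the two-pool anatomy reliably.
#' @param augment_factor Augmented copies per training pair.
#' @param augmentation An [augmentation_spec()].
#' @param unet_depth,unet_base,unet_epochs,unet_lr,unet_batch,validation_split
#'   Segmentation settings.
#' @param swd An [swd_config()] (its seed is overridden by a derived seed).
#' @param n_swd_ref Images per side for the set-level SWD audit.
#' @param n_rank_ref References for the per-image nearest lookup.
#' @param nearest_top Retained nearest references per synthetic image.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, view = "SAX", resolution = 32,
                            master_seed = 1L,
                            n_gan_train = 200, n_synthetic = 100,
                            n_direct_train = 100, n_test = 50,
                            phantom_variability = 0.2,
                            gan_filters = c(32, 24, 16, 12),
                            gan_steps = c(100, 100, 150, 200),
                            gan_batch = c(32, 32, 16, 16),
                            fade_fraction = 0.5,
                            gan_stabilizer = "weight_clip",
                            gan_clip = 0.05, gan_n_critic = 3, gan_lr = 5e-4,
                            augment_factor = 2,
                            augmentation = augmentation_spec(),
                            unet_depth = 3, unet_base = 8, unet_epochs = 10,
                            unet_lr = 2e-3, unet_batch = 8,
                            validation_split = 0.05,
                            swd = swd_config(), n_swd_ref = 30,
                            n_rank_ref = 40, nearest_top = 5) {
  n_st <- as.integer(log2(resolution) - 1)
  cfg <- list(out_dir = out_dir, view = toupper(view),
              resolution = as.integer(resolution),
              master_seed = as.integer(master_seed),
              n_gan_train = n_gan_train, n_synthetic = n_synthetic,
              n_direct_train = n_direct_train, n_test = n_test,
              phantom_variability = phantom_variability,
              gan_filters = rep_len(as.integer(gan_filters), n_st),
              gan_steps = rep_len(as.integer(gan_steps), n_st),
              gan_batch = rep_len(as.integer(gan_batch), n_st),
              fade_fraction = fade_fraction,
              gan_stabilizer = gan_stabilizer, gan_clip = gan_clip,
              gan_n_critic = as.integer(gan_n_critic), gan_lr = gan_lr,
              augment_factor = as.integer(augment_factor),
              augmentation = augmentation,
              unet_depth = as.integer(unet_depth),
              unet_base = as.integer(unet_base),
              unet_epochs = as.integer(unet_epochs),
              unet_lr = unet_lr, unet_batch = as.integer(unet_batch),
              validation_split = validation_split,
              swd = swd, n_swd_ref = n_swd_ref, n_rank_ref = n_rank_ref,
              nearest_top = nearest_top)
  class(cfg) <- "pipeline_config"
  chambers_for_view(cfg$view)
  if (!is_pow2(cfg$resolution) || cfg$resolution < 4 || cfg$resolution > 256)
    cs_abort("resolution must be a power of two in [4, 256]", "cs_config_error")
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Field names mirror [pipeline_config()] arguments; the nested
#' `augmentation:` and `swd:` maps mirror [augmentation_spec()] and
#' [swd_config()]. Unknown keys are rejected.
#'
#' @param path YAML file.
#' @param out_dir Optional override of the config's `out_dir`.
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(y), known)
  if (length(bad))
    cs_abort(paste0("unknown config keys: ", paste(bad, collapse = ", ")),
             "cs_config_error")
  if (!is.null(y$augmentation)) y$augmentation <- do.call(augmentation_spec, y$augmentation)
  if (!is.null(y$swd)) y$swd <- do.call(swd_config, y$swd)
  if (!is.null(out_dir)) y$out_dir <- out_dir
  do.call(pipeline_config, y)
}

# batched nearest-reference ranking: precomputes per-level sorted projections
# per image once, then pairwise distances are mean |sorted difference|
rank_synthetic_batch <- function(queries, references, config, top = 5) {
  proj_of <- function(img) {
    lev <- image_level_descriptors(img, config, 1L)
    lapply(seq_along(lev), function(l) {
      d <- ncol(lev[[l]]$patches)
      dirs <- with_seed(derive_seed(config$seed, "proj_L", l - 1L), {
        m <- matrix(rnorm(d * config$n_projections), d, config$n_projections)
        sweep(m, 2, sqrt(colSums(m^2)), "/")
      })
      apply(lev[[l]]$patches %*% dirs, 2, sort, method = "quick")
    })
  }
  qp <- lapply(queries, proj_of)
  rp <- lapply(references, proj_of)
  lapply(qp, function(q) {
    d <- vapply(rp, function(r)
      mean(vapply(seq_along(q), function(l) mean(abs(q[[l]] - r[[l]])), numeric(1))),
      numeric(1))
    ord <- order(d)[seq_len(min(top, length(d)))]
    tibble::tibble(rank = seq_along(ord), index = ord, distance = d[ord])
  })
}

#' Run the full synthetic-training study pipeline
#'
#' Executes, under one run directory: phantom training-set generation,
#' progressive GAN training, synthetic frame sampling, the annotation
#' stand-in, the SWD audit (set-level distance for generated frames and for a
#' uniform-noise baseline, plus a nearest-reference ranking per synthetic
#' frame), training of a synthetic-trained and a directly trained U-Net, and
#' the held-out comparison report. Writes `report.json`, `comparison.csv` and
#' an artifact manifest; returns the run as a `pipeline_run`.
#'
#' @param config A [pipeline_config()].
#' @param verbose Print stage progress.
#' @return A `pipeline_run`: `dir`, `report` (the report as an R list),
#'   `comparison` (a `comparison_report`), and both `seg_model` objects.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed_of <- function(label) derive_seed(config$master_seed, label)
  say <- function(...) if (verbose) message(sprintf(...))
  res <- config$resolution
  view <- config$view
  chambers <- chambers_for_view(view)

  say("[1/7] phantom GAN training set (n=%d, %dpx)", config$n_gan_train, res)
  ds_gan <- generate_phantom_dataset(config$n_gan_train, view, res,
                                     seed_of("phantom_gan_train"),
                                     file.path(config$out_dir, "gan_train"),
                                     config$phantom_variability)
  train_frames <- lapply(file.path(ds_gan$dir, ds_gan$manifest$frame), read_frame)

  say("[2/7] progressive GAN training")
  gcfg <- gan_config(max_resolution = res, filters_per_stage = config$gan_filters,
                     stabilizer = config$gan_stabilizer,
                     clip_value = config$gan_clip,
                     n_critic = config$gan_n_critic,
                     learning_rate = config$gan_lr)
  sch <- growth_schedule(max_resolution = res,
                         steps_per_stage = config$gan_steps,
                         batch_per_stage = config$gan_batch,
                         fade_fraction = config$fade_fraction)
  gan <- train_pggan(ds_gan, gcfg, sch, seed_of("gan_train"))
  save_model(gan, file.path(config$out_dir, "pggan.rds"))

  say("[3/7] sampling %d synthetic frames", config$n_synthetic)
  syn <- sample_synthetic(gan, config$n_synthetic, seed_of("gan_sample"))
  syn_dir <- file.path(config$out_dir, "synthetic")
  dir.create(syn_dir, showWarnings = FALSE)
  for (i in seq_along(syn))
    write_frame(syn[[i]], file.path(syn_dir, sprintf("synthetic_%04d.png", i)))

  say("[4/7] annotation stand-in on synthetic frames")
  syn_pairs <- lapply(seq_along(syn), function(i) {
    a <- annotate_frame(syn[[i]], view, derive_seed(seed_of("annotate"), "frame", i))
    write_mask(a$mask, file.path(syn_dir, sprintf("synthetic_mask_%04d.png", i)))
    list(frame = syn[[i]], mask = a$mask, view = view, rss = a$rss)
  })

  say("[5/7] SWD audit")
  swcfg <- config$swd
  swcfg$seed <- seed_of("swd")
  n_ref <- min(config$n_swd_ref, length(syn), length(train_frames))
  swd_gen <- multiscale_swd(syn[seq_len(n_ref)], train_frames[seq_len(n_ref)], swcfg)
  noise <- with_seed(seed_of("swd_noise"),
                     lapply(seq_len(n_ref), function(i) matrix(runif(res * res), res, res)))
  swd_noise <- multiscale_swd(noise, train_frames[seq_len(n_ref)], swcfg)
  nearest <- rank_synthetic_batch(syn,
                                  train_frames[seq_len(min(config$n_rank_ref,
                                                           length(train_frames)))],
                                  swcfg, config$nearest_top)

  say("[6/7] U-Net training (synthetic-trained and phantom-trained)")
  n_classes <- length(chambers) + 1L
  ucfg <- unet_config(res, n_classes, config$unet_depth, config$unet_base)
  aug <- config$augmentation
  syn_aug <- expand_dataset(syn_pairs, aug, config$augment_factor,
                            seed_of("augment_synthetic"))
  model_syn <- train_unet(syn_aug, ucfg,
                          seg_train_config(config$unet_epochs, config$unet_batch,
                                           config$validation_split, config$unet_lr,
                                           rng_seed = seed_of("unet_synthetic")))
  save_model(model_syn, file.path(config$out_dir, "unet_synthetic.rds"))

  ds_direct <- generate_phantom_dataset(config$n_direct_train, view, res,
                                        seed_of("phantom_direct_train"),
                                        file.path(config$out_dir, "direct_train"),
                                        config$phantom_variability)
  direct_pairs <- load_pairs(ds_direct$manifest_path)
  direct_aug <- expand_dataset(direct_pairs, aug, config$augment_factor,
                               seed_of("augment_direct"))
  model_dir <- train_unet(direct_aug, ucfg,
                          seg_train_config(config$unet_epochs, config$unet_batch,
                                           config$validation_split, config$unet_lr,
                                           rng_seed = seed_of("unet_direct")))
  save_model(model_dir, file.path(config$out_dir, "unet_direct.rds"))

  say("[7/7] held-out comparison (n=%d)", config$n_test)
  ds_test <- generate_phantom_dataset(config$n_test, view, res,
                                      seed_of("phantom_test"),
                                      file.path(config$out_dir, "test"),
                                      config$phantom_variability)
  test_pairs <- load_pairs(ds_test$manifest_path)
  comparison <- compare_training_sources(model_syn, model_dir, test_pairs,
                                         c("synthetic_trained", "phantom_trained"))

  report <- list(
    view = view, resolution = res, master_seed = config$master_seed,
    sample_sizes = list(gan_train = config$n_gan_train,
                        synthetic = config$n_synthetic,
                        direct_train = config$n_direct_train,
                        test = config$n_test),
    gan = list(steps = sum(gan$log$step > 0),
               final_critic_loss = gan$log$critic_loss[nrow(gan$log)],
               all_losses_finite = all(is.finite(gan$log$critic_loss)) &&
                 all(is.finite(gan$log$generator_loss))),
    swd_audit = list(
      generated_vs_train = list(average = swd_gen$average,
                                per_level = as.list(swd_gen$per_level$distance)),
      noise_vs_train = list(average = swd_noise$average),
      nearest_references = lapply(nearest, function(t)
        list(index = t$index, distance = t$distance))
    ),
    annotation_rss = vapply(syn_pairs, function(p) p$rss, numeric(1)),
    comparison = lapply(seq_len(nrow(comparison$table)), function(i)
      as.list(comparison$table[i, ]))
  )
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(as.data.frame(comparison$table),
                   file.path(config$out_dir, "comparison.csv"), row.names = FALSE)
  arts <- list.files(config$out_dir, recursive = TRUE)
  writeLines(sort(arts), file.path(config$out_dir, "artifacts.txt"))
  structure(list(dir = config$out_dir, report = report, comparison = comparison,
                 model_synthetic = model_syn, model_direct = model_dir,
                 gan = gan),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> %s\n", x$dir))
  print(x$comparison)
  invisible(x)
}
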