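# cardiosynth

Training data for cardiac chamber segmentation is scarce in rare disease:
few patients, strict privacy rules, and labels that only experts can draw.
One way out is to train a generative model on the real frames, share only
*synthetic* images, and train segmentation networks on those. `cardiosynth`
implements that full study design in R for grayscale cardiac MR frames, and
makes every stage testable on a built-in cardiac phantom so no patient data
or downloads are needed:

1. **Phantom generator** — seeded short-axis (SAX: LV, RV) and 4-chamber
   long-axis (LAX: LV, RV, RA) frames with ground-truth blood-pool masks,
   randomized anatomy, blood/myocardium/background contrast, and additive
   noise.
2. **Progressive GAN** — a Wasserstein GAN grown from 4×4 to 256×256 (desk
   runs use 32×32) by fading in one resolution block at a time
   (`(1−α)·upscale(coarse) + α·fine`), with pixelwise feature normalization
   in the generator, a minibatch-standard-deviation channel in the critic,
   leaky-ReLU (0.2) convolutions, latent dimension 64, and per-stage filter
   counts 48/32/24/16/16/16/16.
3. **Similarity audit** — the multi-scale sliced Wasserstein distance
   (SWD): normalized 7×7 patch descriptors per Laplacian-pyramid level,
   compared by the average over random 1-D projections of the exact
   Wasserstein-1 distance `mean |sort(u·X) − sort(u·Y)|`; also used to rank
   the nearest real frame for each synthetic one (memorization audit).
4. **U-Net segmentation** — encoder/decoder with channel doubling per 2×2
   max-pool step, concatenation skips, same-size output maps, paired affine
   augmentation (rotation ±20°, shifts 5%, shear ≤20%, zoom ≤10%, no
   flips), 5% validation split.
5. **Evaluation** — per-chamber Dice `2|A∩B|/(|A|+|B|)` and percent area
   variation `|area(pred)−area(truth)|/area(truth)`, summarized as median
   [IQR] and compared between the two training arms with paired Wilcoxon
   signed-rank tests.

All network numerics (convolutions, backprop, Adam) are implemented in the
package with an RcppArmadillo back-end and verified against
finite-difference oracles in the test suite.

## Worked example

The whole two-arm study at desk scale (32 px, seeded):

```r
library(cardiosynth)

cfg <- pipeline_config(out_dir = "run1", view = "SAX", resolution = 32,
                       master_seed = 1)
run <- run_pipeline(cfg, verbose = TRUE)
print(as.data.frame(run$comparison$table), digits = 3)
```

```
  view chamber            metric median_a   q1_a  q3_a median_b  q1_b   q3_b  p_value  n degenerate
1  SAX      LV              dice   0.9023 0.8942 0.910        1 1.000 1.0000 7.77e-10 50      FALSE
2  SAX      RV              dice   0.9392 0.9333 0.948        1 0.994 1.0000 7.77e-10 50      FALSE
3  SAX      LV percent_variation   0.2126 0.1771 0.234        0 0.000 0.0000 7.76e-10 50      FALSE
4  SAX      RV percent_variation   0.0824 0.0568 0.108        0 0.000 0.0116 1.14e-09 50      FALSE
```

Column `a` is the U-Net trained purely on GAN-generated frames (labels from
the package's annotation stand-in, which fits phantom parameters to each
synthetic frame); column `b` is the U-Net trained directly on rendered
phantoms; both are evaluated on the same 50 held-out phantoms neither saw.
Reading: both arms segment the held-out set well (median Dice ≥ 0.90), the
directly trained arm is significantly better (paired signed-rank p < 1e-9),
and the synthetic arm's ~0.10 Dice gap and larger LV area error quantify
what is lost to generator blur at this tiny training scale. The report also
contains the SWD audit — here generated-vs-train 0.093 versus a
uniform-noise baseline of 0.167, so the generator sits well inside the
noise floor — and a nearest-real-frame ranking per synthetic image:

```r
run$report$swd_audit$generated_vs_train$average  # 0.0930
run$report$swd_audit$noise_vs_train$average      # 0.1674
```

Individual stages are exported (`generate_phantom_dataset()`,
`train_pggan()`, `sample_synthetic()`, `multiscale_swd()`,
`rank_most_similar()`, `augment_pair()`, `train_unet()`,
`predict_segmentation()`, `compare_training_sources()`), and
`inst/cli/cardiosynth.R` wraps them as shell subcommands
(`phantom`, `gan-train`, `gan-sample`, `swd`, `nearest`, `unet-train`,
`unet-predict`, `compare`, `run`).

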