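# cryptflow

Deep-learning morphometry of intestinal crypts for preclinical colitis
studies, in R.

In DSS-colitis models, the crypts of Lieberkühn are lost, atrophy, and lose
their goblet-cell texture; successful treatment partially restores them.
`cryptflow` quantifies this continuum from H&E histology images with a
staged workflow aimed at preclinical efficacy readouts:

1. **Segmentation** — a U-Net (encoder–decoder with skip connections,
   pixelwise binary cross-entropy) trained on randomly tiled annotation
   windows (window side 256–768 px, stride 256–512 px, resized to the
   512×512 input; 5× augmentation by random-resized crop, Gaussian blur and
   rotation), applied at slide scale with the overlap-tile strategy (predict
   512-tiles, keep each tile's central 480×480). Evaluated by pixel Dice and
   object-level F1 (greedy IoU ≥ 0.5 matching).
2. **Latent crypt morphology** — per crypt, 24 RGB patches of 24×24 px are
   sampled from the central region and peripheral border (24×24×72 stack)
   and encoded by a dual-stream convolutional autoencoder (stride-2
   encoder filters 96-64-32-24, mirrored decoder, ReLU/sigmoid, BCE + Adam);
   bottlenecks are concatenated to a 192-dim code and mapped to 2D by t-SNE.
3. **Features** — masked GLCM (Haralick) statistics
   (contrast = Σ(i−j)²P, dissimilarity, homogeneity, ASM, energy, entropy,
   correlation), first-order entropy in bits, Canny edge density,
   nearest-neighbour distance and folded orientation difference, crypt
   count, and the gland/mucosa area ratio.
4. **Cohort statistics** — Welch t-tests between groups, Pearson
   correlation with pathologist scores, PCA, and z-scored average-linkage
   hierarchical clustering.

Since no deep-learning framework is a dependency, the networks run on a
compact CPU engine included in the package (im2col + BLAS convolutions with
analytically derived, finite-difference-verified backward passes).

A built-in generator renders H&E-like mucosa with exact ground truth in
three archetypes (normal / colitis / treated), so the entire pipeline is
testable end to end without any whole-slide image.

## Worked example

```r
library(cryptflow)

# a synthetic cohort: 3 groups x 2 animals x 2 slides with ground truth
slides <- render_cohort(n_animals_per_group = 2, slides_per_animal = 2,
                        seed = 11, height = 384, width = 384)

# train the reduced U-Net (128-px tiles) on a few slides
tiles <- unlist(lapply(seq_along(slides), function(i)
  generate_tiles(slides[[i]], seed = i, n_target = 8,
                 win_range = c(96, 192), stride_range = c(64, 96),
                 out_size = 128, n_classes = 1)), recursive = FALSE)
model <- build_unet(seg_config(128, n_classes = 1, depth = 3,
                               base_filters = 8), seed = 0)
model <- train_seg(model, tiles, split_seed = 1, epochs = 10)
tail(model$history, 1)
#>    epoch train_loss   val_loss  val_dice val_accuracy
#> 10    10  0.1467851 0.05150969 0.9806114    0.9970703

# slide-scale prediction and instance extraction
held <- render_slide(archetype_params("treated"), 384, 384, seed = 99)
pm   <- predict_slide(model, held$image)
dice(pm$prob[, , 1] >= 0.5, held$gland_mask)
#> [1] 0.9665789
inst <- extract_instances(pm, threshold = 0.5, min_area = 30)
object_f1(attr(inst, "labels"), held$instance_labels)$f1
#> [1] 1

# features and group statistics on ground-truth masks
ft <- featurize_cohort(slides)
welch_t(ft$slides$gland_mucosa_ratio[ft$slides$group == "normal"],
        ft$slides$gland_mucosa_ratio[ft$slides$group == "dss"])
#>   feature group_a group_b  mean_a     mean_b        t       df           p
#> 1    <NA>       a       b 0.14137 0.01133747 12.45385 3.135885 0.000895782
```

The history line shows the model reaching validation Dice ≈ 0.98 after 10
epochs on one CPU; the held-out slide is segmented at pixel Dice ≈ 0.97 and
all planted crypts are recovered one-to-one (object F1 = 1). Typical
slide-level readouts on the fixture cohort: the gland/mucosa ratio and
masked GLCM contrast are ordered normal > treated > dss, mirroring crypt
loss and texture loss under colitis with partial recovery under treatment.

`run_all(run_config("out_dir", seed = 0))` orchestrates every stage
(fixtures → tiles → training → prediction → crypts → embedding → features →
statistics) with a content-hash manifest, so reruns skip completed stages.
A thin CLI is installed at `inst/cli/cryptflow`
(`cryptflow {make-fixtures|tile|run-all} ...`).

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "cryptflow",
                               load_package = "installed")'
```

The suite verifies the conv-net engine against finite differences, the
masked GLCM against brute-force pair enumeration, overlap-tile stitching
against whole-image application (bit-identical), the patch-region
partition against a distance-transform oracle, the statistics against
hand-computed closed forms, and the end-to-end behaviour of the pipeline
on the synthetic study conditions.
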