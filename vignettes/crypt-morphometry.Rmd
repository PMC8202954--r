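---
title: "Quantifying crypt injury and recovery: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying crypt injury and recovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In murine colitis models (typically DSS-induced), the density, size and
internal texture of the crypts of Lieberkühn track epithelial injury and
healing. Manual histology scoring of whole-slide images (WSIs) is slow and
coarse. `cryptflow` implements a staged computational alternative:

1. **Supervised segmentation** of glands (and optionally the mucosa band)
   with a U-Net trained on randomly tiled annotation windows;
2. **Unsupervised representation** of each segmented crypt with a
   dual-stream convolutional autoencoder over sampled interior/border
   patches, visualized by t-SNE;
3. **Feature extraction**: masked first-order entropy, gray-level
   co-occurrence (Haralick) statistics, Canny edge density, and
   nearest-neighbour morphometrics;
4. **Cohort statistics**: Welch t-tests, Pearson correlations with
   pathologist scores, PCA, and z-scored average-linkage clustering.

Because real WSI cohorts are large and proprietary, the package ships a
synthetic mucosa generator with exact ground truth; every stage of the
pipeline is tested against it.

## Synthetic study conditions

`render_slide()` draws non-overlapping elliptical crypts (axis ratio
uniform in [1, 2], orientation uniform in [0, 180)) inside a wavy mucosa
band on a pale background, with an epithelial ring and a lumen mottled by
"goblet" speckles, then adds Gaussian pixel noise (default sd 4/255).
Three archetypes emulate the study conditions:

| parameter                  | normal | treated | dss  |
|----------------------------|--------|---------|------|
| crypt density (per Mpx)    | 70     | 45      | 20   |
| radius mean (px)           | 18     | 15      | 10   |
| goblet speckle density     | 0.35   | 0.18    | 0.04 |

The orderings `normal > treated > dss` in density and speckle fraction
encode crypt loss under colitis, goblet/mucin depletion, and partial
recovery under treatment; the shrinking radius encodes atrophy. No public
quantitative morphology distributions exist for these conditions, so the
numbers are package defaults chosen once to give plausible per-slide crypt
counts at a few hundred pixels per slide; they are deliberately simple and
are documented as such. `render_cohort()` adds per-animal log-normal
parameter jitter (sd 0.08) so the animal is a genuine random-effect level.

What the generator does **not** emulate: inflammatory infiltrates, muscle
layers, stain variability, touching or distorted glands, scanner artifacts.
Passing tests on fixtures therefore demonstrate the correctness of the
machinery and the sensitivity of the features to the built-in effects, not
segmentation performance on real tissue.

## Tiling and augmentation

Training tiles are cut by a randomized sliding window (side uniform in
256–768 px, stride uniform in 256–512 px at slide scale) and resized to the
network input (512×512, or 128×128 in the reduced configuration). Windows
near the border are clamped inside the image rather than padded or
discarded, avoiding synthetic border content in training data. Randomized
scan passes repeat until roughly `n_target` tiles (default 100) exist; a
fully degenerate window/stride setting makes the scan deterministic, and
exactly one pass is performed — this keeps "window = image, stride = image"
configurations exact (one tile) while the default randomized setting hits
its target count.

Augmentation composes a random-resized crop (aspect ratio in [3/4, 4/3]),
Gaussian blur (sigma uniform in [0, 2], image only), and rotation by a
uniform random angle. The mask receives the identical spatial transforms
with nearest-neighbour interpolation; rotation fills exposed image corners
by reflection and mask corners with 0 (a visible, testable convention).
Color augmentation is intentionally omitted from the default pipeline.
`expand_dataset()` produces the originals plus (factor − 1) augmented
copies; augmentation is applied to the training split only.

## Segmentation

The U-Net is an encoder–decoder with skip connections: per level two 3×3
convolutions + ReLU and a 2×2 max pool, filters doubling per level; the
decoder mirrors it with nearest-neighbour upsampling + convolution and skip
concatenation; a 1×1 convolution with one sigmoid unit per class ends the
network. Gland and mucosa are two independent sigmoid channels of a single
model. The loss is pixelwise binary cross-entropy under Adam.

Two configurations are provided: the slide-scale 512-input / depth-4-style
setting, and a **reduced configuration** (128×128 tiles, depth 3, 8 base
filters, 120-px stitching center) used throughout the test suite so that
training runs in about a minute on one CPU. The networks run on a compact
conv-net engine written for this package (im2col + BLAS GEMM with
hand-derived backward passes); every backward pass is validated against
finite differences in the test suite.

Slide-scale prediction uses the overlap-tile strategy: the image is
reflect-padded, tiles of side `t` are predicted on a grid of stride
`c = 15/16 t` (480 for 512-tiles), and only each tile's central `c × c`
area is kept, so every pixel is predicted exactly once with full context.
For any per-pixel model this stitching is bit-identical to whole-image
application, which is the oracle the tests use.

Evaluation: pixel Dice (`2|A∩B|/(|A|+|B|)`, 1 for two empty masks) and
object-level F1 with greedy one-to-one IoU matching at threshold 0.5 — the
GlaS-challenge convention, adopted because the matching rule is otherwise
underdetermined.

## Crypt instances and patch stacks

Instances are 8-connected components of the thresholded probability map
(default 0.5), filtered by `min_area` (default 30 px at fixture scale) and
relabelled by decreasing area. Orientation comes from the mask's second
central moments (image-moment ellipse), measured from the column axis in
[0, 180). Coordinates are (row, col).

For the autoencoder, each crypt contributes 24 patches of 24×24 RGB pixels
(72 channels): 12 sampled uniformly **with replacement** from the central
region and 12 from the peripheral border. The split into 12+12 is a design
choice — the channel arithmetic (3 × 24 = 72) fixes only the total. The
border is the set of mask pixels within `border_depth` of the background
(Euclidean distance transform), with
`border_depth = max(2, 0.25 × equivalent radius)` so the band scales with
crypt size. Masks too thin to have an interior are flagged and sampled
entirely from the border. Sampling with replacement means small crypts
never fail; the seed is stored in the stack for reproducibility.

## Autoencoder and embedding

Each 36-channel sub-stack (central / peripheral) is encoded by its own
branch: four stride-2 3×3 convolutions with filters 96, 64, 32, 24 and
ReLU, giving spatial sizes 24 → 12 → 6 → 3 → 2 (ceil-mode halving). The
2×2×24 bottlenecks are flattened (96 dims per branch) and concatenated to a
192-dim latent code. Mirrored decoders (nearest upsampling + convolution,
filters 24, 32, 64, 96) reconstruct each 36-channel sub-stack through a
sigmoid output; the loss is pixel/channel-wise binary cross-entropy against
the input (RGB already in [0, 1], which makes the BCE target well-posed)
under Adam. A single-stream variant (72 channels in one branch) is kept
behind `ae_config(dual_stream = FALSE)`.

The 2D map is an exact t-SNE (perplexity 30 by default, PCA
initialization, early exaggeration, momentum gradient descent) implemented
in the package; at cohort scale (hundreds to a few thousand crypts) the
O(N²) exact formulation is fast and has no approximation parameter. An
optional k-means on the latent codes (`latent_zones()`) provides post-hoc
zone labels for reading the map; zones are not an algorithmic output.

## Features

* **Masked GLCM**: pairs are counted only when *both* pixels lie in the
  mask, accumulated over distance 1 and angles {0°, 45°, 90°, 135°},
  symmetrized and normalized. Gray levels: ITU-R 601 luma quantized
  uniformly to G = 32 levels over [0, 1]. The offset set and G are
  conventional Haralick defaults (the source values being
  underdetermined) and are configurable.
* **Derived features**: contrast, dissimilarity, homogeneity, ASM, energy
  (√ASM), entropy (natural log, 0·ln 0 := 0) and correlation (:= 1 for a
  zero-variance matrix, the continuity limit of a constant region).
* **First-order entropy** uses log₂ (bits) over a 256-bin histogram —
  deliberately a different logarithm convention than the GLCM entropy,
  kept distinct and documented.
* **Canny density**: fraction of mask pixels on Canny edges (Gaussian
  smoothing σ = 1.4, Sobel, non-maximum suppression, hysteresis at
  0.1/0.2 of the max gradient).
* **Morphometrics**: nearest-neighbour centroid distance; the absolute
  difference of the two crypts' major-axis orientations folded into
  [0, 90]°. The phrase "angle difference between nearest glands" is
  ambiguous; orientation difference is the default reading and the one
  implemented.
* **Slide level**: crypt count, gland and mucosa areas, gland/mucosa
  ratio (undefined and flagged when the mucosa mask is empty), unweighted
  means of crypt features, and whole-slide vs masked entropy.

## Statistics

Group comparisons are unpaired two-sided Welch t-tests (unequal
variances); correlations are Pearson with the t-based two-sided p. No
multiple-testing correction is applied by default (Benjamini–Hochberg is
available behind `adjust = TRUE`). Slides are treated as independent units
at slide level and averaged per animal (unweighted) at animal level; the
slide-within-animal hierarchy is deliberately not modelled with mixed
effects, matching common practice in this setting — a caveat users should
keep in mind when slide counts differ per animal. Clustering z-scores each
feature, then uses Euclidean distance with average linkage (the common
heatmap default; both are configurable); constant features are dropped
with a warning.

## Numerical choices and degenerate inputs

* Probability→binary threshold 0.5 (configurable).
* The segmentation cross-entropy up-weights foreground pixels
  (`pos_weight = 3` by default): glands cover roughly a tenth of a slide,
  and unweighted BCE can settle in the all-background optimum on short
  training runs.
* Single-pixel or empty masks raise informative errors in the GLCM and
  entropy paths rather than returning NaN.
* A slide with fewer than 2 crypts records missing nearest-neighbour
  features; group comparisons skip pairs with fewer than 2 usable values.
* All randomness is routed through named per-stage seeds derived from one
  master seed; `with_seed()` restores the caller's RNG state.
* Reflect padding uses the no-edge-duplication convention (period 2n−2).

## Problem sizes in the test suite

The suite exercises the full pipeline at reduced scale, chosen as the
package's own test conditions: 384×384 fixture slides; 48 tiles of 128×128
and 10 epochs for segmentation; 150 crypts per archetype and 6 epochs for
the autoencoder at the full filter schedule; a 3-group × 6-animal ×
2-slide cohort for the treatment-effect statistics. With these sizes the
segmentation model reaches held-out Dice above 0.9 and the latent map
separates the archetypes with 10-NN purity above 0.9 — comfortable margins
over the package's acceptance thresholds (0.85 / 0.7).

## Known limitations

* The fixtures are far easier than real H&E tissue; real-data performance
  requires real annotations and likely the 512-scale configuration.
* Touching glands are not split (no watershed); the generator enforces
  separation, so object F1 on fixtures does not probe under-segmentation.
* The CPU engine is single-threaded per GEMM call and intended for
  reduced-scale training, not for training the full 512-scale model on
  large cohorts.
* t-SNE is exact O(N²); for >10⁴ crypts subsample or use the latent codes
  directly.
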