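# mpquant

Segmentation and quantification of Nile-red-stained microplastics (MP) in
fluorescence microscopy images.

Monitoring MP contamination — in bivalves, water, sediments — ends with a
counting problem: a micrograph of bright, dye-stained plastic debris on a
dark filter background, from which one needs the number of MP pieces, their
shape class and their size. The field's established tools binarize the
image with a single global threshold (maximum-entropy, Rényi-entropy or a
fixed cutoff) and hand the mask to a particle analyzer. Global thresholds,
however, are baited by fluorescence halos around bright objects (false
positives) and by thick particles photographed dark at the centre (false
negatives), and they systematically overcount. `mpquant` implements both
that classical stack and its replacement — a trainable encoder–decoder
segmenter — together with the morphometry, evaluation and
recovery-assessment machinery to compare them, and a synthetic scene
generator that makes the whole pipeline testable without any external
data.

## What is inside

* **Classical segmenters** (`run_tr_model()`): the four published
  threshold pipelines — grayscale + Kapur maximum-entropy, red-channel +
  three-order Rényi entropy ($H_\alpha = \frac{1}{1-\alpha}\log\sum_k
  q_k^\alpha$ at $\alpha = 0.5, 1, 2$, Sahoo-weighted), grayscale +
  despeckle + fixed threshold 222 + outlier removal, and a user-supplied
  fixed threshold. A pixel is MP iff its intensity strictly exceeds the
  threshold.
* **Trainable segmenter** (`build_model()`, `train()`, `predict_mask()`,
  `tta_predict()`): U-Net-style encoder–decoder with skip connections,
  soft-Dice / BCE / Dice+BCE losses, SGD and Adam, sliding-window patch
  inference with averaged overlaps, and photometric test-time
  augmentation. Convolutions are compiled code; everything is seeded and
  deterministic on one CPU.
* **Morphometry** (`quantify_mask()`): 8-connected counting,
  corner-corrected perimeter, circularity $4\pi A/P^2$ with the shape
  bands fiber < 0.3 ≤ fragment < 0.6 ≤ particle, and maximum Feret
  diameter over the pixel-corner convex hull.
* **Evaluation** (`seg_metrics()`, `majority_vote()`,
  `recovery_report()`): balanced accuracy, recall, precision, F1, IoU;
  pixel-wise majority-vote fusion of annotator masks; percentage recovery
  (100 × predicted / true count, rounded half away from zero) with
  mean ± sample SD. The published benchmark count pairs for five spiked
  and fifteen clam-sample images ship with the package
  (`benchmark_counts()`).
* **Synthetic scenes** (`generate_scene()`, `generate_dataset()`):
  seeded Nile-red-style images with exact ground-truth masks, three shape
  archetypes, and optional halo / dark-core artefacts that reproduce the
  failure modes of global thresholding.
* **Dataset preparation** (`assign_folds()`, `extract_patches()`,
  `merge_patches()`): serpentine fold assignment balanced by MP-pixel
  count, 256×256 (or any size) sliding windows, empty-patch filtering.

## Worked example

```r
library(mpquant)

# a synthetic scene with halos and dark cores, plus its exact ground truth
sc <- generate_scene(sample_scene_spec(c(128, 128), 6, seed = 42,
                                       halo_strength = 0.5,
                                       dark_core_fraction = 0.4))
truth <- quantify_mask(sc$mask, scale = 1.4, id = "demo")
truth
#> <quant_summary 'demo'> 6 MP objects (fiber: 0, fragment: 0, particle: 6)

# classical maximum-entropy segmentation of the same scene
mask <- run_tr_model(sc$image, "mp_vat")
est <- quantify_mask(mask, scale = 1.4, id = "demo")
est
#> <quant_summary 'demo'> 7 MP objects (fiber: 0, fragment: 0, particle: 7)
recovery(est$mp_count, truth$mp_count)
#> [1] 117

head(truth$objects[, c("area_px2", "circularity", "feret_px", "shape_class")], 3)
#>   area_px2 circularity  feret_px shape_class
#> 1      220   1.0000000 18.027756    particle
#> 2       22   0.6006984 10.770330    particle
#> 3       13   0.6252526  8.944272    particle
```

The halo around the brightest object costs the entropy threshold an extra
(spurious) component: 7 counted against 6 true pieces, a 117 % recovery.
On the published spiked-sample benchmark the same arithmetic gives, for
the learned segmenter:

```r
counts <- benchmark_counts("spiked")
recovery_report(counts$ground_truth, counts$mp_net)
#> <recovery_report> 5 samples, mean 107.8% (SD 9.2%)
```

i.e. a mean recovery of 107.8 % with a sample SD of 9.2 % — close to the
perfect 100 % — whereas the three global-thresholding tools land at
206–268 % on the same images.

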