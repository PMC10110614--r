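# octava

Differential artery–vein analysis of en face OCTA (optical coherence
tomography angiography) images, built around dense **arterial–venous area
(AVA) maps** and **intensity-preserving quantification**.

Conventional OCTA metrics binarise the angiogram and report vessel density,
discarding both the perfusion-intensity signal and the artery/vein
distinction. Early diabetic retinopathy affects the two circulations
differently, so this package quantifies them separately and without
binarisation:

* Sparse manual artery/vein vessel gradings become dense AVA maps by
  distance-weighted k-nearest-neighbour label propagation
  (`classify_background()`): every background pixel joins the territory of
  the vessels nearest to it, and graded vessels keep their class.
* **AVA-Net**, a U-Net-style encoder–decoder whose five encoder blocks each
  run two 3×3 conv–BN–ReLU units plus four parallel dilated convolutions
  (rates 2–5), learns to predict AVA maps directly from the grayscale OCTA
  image (`avanet_train()`, `predict()`), trained with Adam on the soft
  Jaccard loss `L = 1 − Σgs / Σ(g + s − gs)`.
* Multiplying the OCTA image into the two territories gives the OCTA-AV
  map, from which seven whole-image biomarkers are computed
  (`quantify_image()`): with `A_A`, `A_V`, `A_T` the arterial/venous/total
  pixel counts and `I` the 8-bit intensities,

  | feature | definition |
  |---|---|
  | AA, VA | `100·A_A/A_T`, `100·A_V/A_T` (so `AA + VA = 100`) |
  | AVAR | `A_A / A_V` |
  | T-PID, A-PID, V-PID | `(100/255)·mean(I)` over total / arterial / venous area |
  | AV-PIDR | `A_PID / V_PID` |

  PID = perfusion intensity density. A central 1 mm fovea disk and the
  vendor layer-indicator rectangle are excluded before quantification.
* Group comparisons (`compare_groups()`): Shapiro–Wilk screening, unpaired
  two-sided Student's t tests, stars at 0.05/0.01/0.001, Bonferroni dagger
  at 0.05/3 = 0.0167 for three groups.
* A seedable synthetic OCTA simulator (`simulate_scene()`,
  `simulate_cohort()`) provides ground-truth-known scenes — alternating
  arterial/venous vessel trees, foveal avascular zone, capillary-free zones
  flanking arteries, multiplicative speckle — so the whole chain is
  testable without clinical data.

## Worked example

```r
library(octava)

# a 256x256 synthetic scene with known ground truth
scn <- simulate_scene(scene_config(size = 256, seed = 42))

# sparse manual-style grading -> dense AVA map (k = 5, distance-weighted)
ava <- classify_background(scn$av, knn_config(k = 5))
validate_partition(ava, scn$av)$ok
#> [1] TRUE

# seven biomarkers, fovea + indicator excluded
quantify_image(scn$octa, ava)
#>             id   AA   VA   AVAR T_PID A_PID V_PID AV_PIDR
#> 1 scene_seed42 49.5 50.5 0.9801 50.49 46.33 54.56  0.8492

# agreement with the generator's own territory partition
metrics_report(list(ava), list(scn$ava_ref))
#> <metrics_report> n=1 (per_image_mean)
#>   IoU arterial 96.25%, venous 96.27%, mean 96.26%
#>   Dice 98.09%, accuracy 98.09%
```

The scene was built with an even territory split, and the pipeline reads
back `AA ≈ 49.5%`; arterial PID is below venous here because arteries sit
inside capillary-free zones, which thin the surrounding signal. Training
the network on such scenes and predicting is analogous:

```r
fix <- lapply(1:2, function(s) simulate_scene(scene_config(size = 96, seed = s)))
fit <- avanet_train(
  x = lapply(fix, `[[`, "octa"),
  y = lapply(fix, function(s) classify_background(s$av, knn_config(5))),
  net = network_config(base_filters = 8),
  train = train_config(batch_size = 2, batches_per_epoch = 1,
                       max_epochs = 2000, early_stop_patience = 1999,
                       stop_at_train_iou = 0.90, seed = 0))
predict(fit, fix[[1]]$octa)   # an ava_map
```

A thin command-line wrapper for the file-based workflow is at
`inst/scripts/ava-oct.R` (subcommands `groundtruth`, `quantify`,
`simulate`, `evaluate`, `stats`).

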