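---
title: "Arterial-venous area mapping and perfusion intensity analysis: methods"
author: "octava"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Arterial-venous area mapping and perfusion intensity analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octava)
```

## The problem

Optical coherence tomography angiography (OCTA) resolves retinal blood flow
down to the capillary level, but conventional quantification binarises the
angiogram and reports vessel density, discarding both the perfusion
intensity signal and the distinction between arterial and venous
circulation. Early diabetic retinopathy affects arteries and veins
differently, so a *differential* artery-vein analysis that preserves
intensity can detect changes that binarised whole-image metrics miss.

`octava` implements the full analysis chain around that idea:

1. **Dense territory maps.** A sparse manual grading of the large vessels
   (artery / vein / background) is converted into a *dense* arterial-venous
   area (AVA) map: every background pixel is assigned to the territory of
   the vessels that perfuse or drain it, by k-nearest-neighbour label
   propagation ([`classify_background()`]).
2. **A segmentation network.** A U-Net-style encoder-decoder (AVA-Net)
   learns to predict the AVA map directly from the grayscale OCTA image, so
   the manual grading step can be automated ([`avanet_train()`],
   [`predict.avanet_fit()`]).
3. **Intensity-preserving quantification.** Multiplying the OCTA image into
   the two territories yields the OCTA-AV map, from which seven biomarkers
   are computed ([`quantify_image()`]).
4. **Group statistics.** Shapiro-Wilk screening, pairwise Student's t tests,
   Bonferroni correction and significance flagging over per-eye feature
   tables ([`compare_groups()`]).
5. **A synthetic scene simulator** providing ground-truth-known inputs for
   all of the above ([`simulate_scene()`], [`simulate_cohort()`]).

## The seven biomarkers

With `A_A`, `A_V` the arterial and venous pixel counts over the analysed
region and `A_T = A_A + A_V`:

* arterial area `AA = 100 A_A / A_T` and venous area `VA = 100 A_V / A_T`
  (percent; `AA + VA = 100` identically), and their ratio `AVAR = A_A/A_V`;
* perfusion intensity densities: the mean 8-bit intensity scaled to percent
  of full scale, `PID = (100/255) * mean(I)`, over the total region
  (`T_PID`), the arterial territory (`A_PID`) and the venous territory
  (`V_PID`), plus the ratio `AV_PIDR = A_PID / V_PID`.

The identity `A_T * T_PID = A_A * A_PID + A_V * V_PID` holds by
construction and is enforced by the test suite to 1e-9 relative. Ratios
with empty denominators (no venous pixels, zero venous intensity) are
returned as flagged missing values, never as infinities, so downstream
statistics stay honest; missing values are dropped pairwise with a count.

Quantification excludes two regions by default
([`analysis_mask()`]): a central disk of 1 mm diameter covering the fovea,
where the avascular zone makes any territory assignment artificial (scanners
centre the macular scan on the fovea, so the disk is placed at the image
centre), and the rectangle at the bottom-left corner where the vendor
export stamps its retinal-layer indicator. The indicator's true size is
vendor-specific; the default (25% of the width, 5% of the height) covers
typical overlay footprints and both parameters are configurable. Disk
membership uses strict pixel-centre distance, which is deterministic and
resolution-stable. The exclusion is an analysis-time concept only: network
training targets the full field.

## Dense ground truth by kNN label propagation

Manual graders label the visible vessels; the propagation step classifies
each remaining background pixel by its k nearest graded vessel pixels
(Euclidean distance in pixel coordinates, distance-weighted 1/d voting).
Graded pixels keep their own class, so the dense map is the union of
vessels with their territories. The default neighbourhood is k = 5:
neighbourhood sizes from roughly 4 to 25 give near-identical smooth maps
(a property the test suite checks on simulated scenes at ≤ 5% pairwise
pixel disagreement), and small k is cheapest.

Determinism demanded two tie-break rules, both documented in
[`classify_background()`]: equidistant k-th neighbours resolve to the
earlier row-major scan position, and an exactly balanced weighted vote goes
to the arterial class. The feature space is pixel coordinates only — the
procedure assigns territory purely by proximity, never by image intensity.

The implementation buckets labelled pixels on a uniform grid and expands
Chebyshev rings per query until no unexplored cell can hold a closer (or
equidistant) neighbour, which makes it exactly equivalent to the
brute-force search — the suite asserts bit-identical output against an
independent exhaustive implementation — while scaling to full-resolution
scans.

## AVA-Net

The network maps a 1-channel OCTA image to a same-size arterial probability
map. Each of the five encoder blocks applies two 3×3
convolution - batch-norm - ReLU (CBR) units, then four parallel dilated 3×3
CBR branches with dilation rates 2-5; the plain-conv output and the four
dilated outputs are concatenated (this concatenation is also the skip tap)
and 2×2 max-pooled. The parallel dilations widen the receptive field at
full resolution, which suits vasculature whose calibre spans an order of
magnitude. Each of the five decoder blocks applies two CBR units, 2×
nearest-neighbour up-sampling, and concatenation with the matching skip.
Two CBR units and a 1×1 convolution with a sigmoid produce the output;
probabilities are thresholded at 0.5.

Choices the architecture description leaves open, fixed here and
configurable in [`network_config()`]:

* filter counts per level default to doubling from `base_filters`
  (32 → 512; the bundled experiments use 8 → 128 to fit a CPU);
* each dilated branch carries the full per-level filter count, so the
  concatenation has 5× the level's filters;
* up-sampling is nearest-neighbour resize (not transposed convolution);
* the final convolution is 1×1.

Training ([`train_config()`]) uses Adam (learning rate 1e-4, beta1 0.9,
beta2 0.999, epsilon 1e-7) on the soft Jaccard loss
`L = 1 - sum(g s) / sum(g + s - g s)`, the differentiable surrogate of the
IoU evaluation metric. A smoothing epsilon of 1e-6 stabilises the
denominator, and the empty/empty case is defined as loss 0. The default
epoch is 3 mini-batches of 28 with per-epoch reshuffling; early stopping
watches the validation score with a default patience of 500 epochs
(no patience value is canonical; 500 is conservative for curves this
noisy). Augmentation (random flips, rotation, zoom, shift, shear,
brightness) is applied on the fly, geometric transforms identically to
image and label with the label re-binarised, brightness to the image only.
Cross-validation splits are grouped by eye ([`make_folds()`]), the unit of
observation; a patient-level grouping can be had by passing patient
identifiers instead, which is the stricter choice when both eyes of a
patient are present.

Because this package targets reproducible CPU execution, the network engine
is implemented in compiled code within the package (im2col + GEMM
convolutions, exact analytic gradients verified against finite differences
in the test suite) rather than on a GPU framework. Five pooling stages
require input sides divisible by 32; [`pad_to_grid()`] reflection-pads and
records the exact inverse crop.

Clinical-scale training (a hundred scans for thousands of epochs) is out
of reach on a single CPU, so the suite validates the optimisation path by
an overfit experiment: two simulated 96×96 scenes, `base_filters = 8`, the
Adam settings above, batch = the 2 scenes with one batch per epoch (the
28×3 epoch definition presumes a much larger dataset). The network must
reach a training mean IoU of at least 0.90 within 2000 epochs; in practice
it does so within a few hundred. Passing this says the architecture, loss,
gradients and optimiser work — it says nothing about generalisation to
clinical OCTA, which only real data can establish.

## Evaluation metrics

Per-class IoU (with the empty-union case defined as 100), the unweighted
two-class mean IoU, per-class and mean Dice, and pixel accuracy — all in
percent, computed over the full field with no exclusion mask (consistent
with the training targets). Whether a published mean is per-image or
pooled over pixels is often ambiguous, so [`metrics_report()`] offers both
aggregations, defaulting to per-image means. Fold summaries report the
unweighted mean and sample standard deviation.

## Statistics

Each eye is one observation. Features are screened with Shapiro-Wilk;
group pairs are compared with the unpaired two-sided *pooled-variance*
Student's t test (Welch's correction available behind a flag, since the
equal-variance assumption is a choice, not a given). Pearson's chi-squared
(uncorrected by default; Yates behind a flag) serves categorical
demographics and one-way ANOVA the continuous ones. Significance is
flagged at 0.05/0.01/0.001 and, for the three group pairs, at the
Bonferroni-corrected threshold 0.05/3 = 0.0167. The suite verifies type-I
calibration empirically: under a null cohort the pairwise flag rate at
0.05 stays within [0.03, 0.07].

## The synthetic scene simulator

[`simulate_scene()`] emulates the graders' cues rather than retinal
physics. Territories are alternating vertical bands whose arterial widths
are scaled by `territory_share`; each band holds one midpoint-displaced
branching tree entering from the top border. This construction enforces
the grading heuristics directly: arteries and veins alternate; same-type
trees never cross (each is confined to its own band); every vessel routes
around the central avascular zone (0.6 mm by default, a typical foveal
avascular diameter), with any clamping residue at its rim erased; arteries
carry a capillary-thinned flanking band (the capillary-free zone cue);
capillaries fill the remaining tissue; and clipped multiplicative Gaussian
speckle (sigma 0.15) degrades the signal. Branches spawn at a physical
spacing of ~0.25 mm of parent vessel with band-width-proportional reach,
which keeps vessel pixel density comparable across band widths and
resolutions — without this, the kNN boundary drifts systematically toward
the sparser side. The generative band partition is returned as a reference
AVA map, so the propagation module can be validated against a truth it had
no part in creating; on default scenes the two agree on ≥ 97% of pixels,
and pushing a 60% territory share through scene → kNN → masked
quantification recovers AA within 3 percentage points.

What the simulator does *not* model: real decorrelation noise statistics,
projection artifacts, pathology (microaneurysms, non-perfusion), vessel
calibre-flow relations, or curved territory boundaries. Tests passing on
these scenes therefore validate the *machinery* — propagation, training,
quantification, statistics — not clinical performance.

[`simulate_cohort()`] generates per-eye feature tables for the statistics
pipeline. Each eye draws latent parameters — arterial territory share
(mean 0.526, i.e. a healthy mean arterial area of 52.6%, with between-eye
SD 0.03), and arterial/venous territory intensities (venous mean 92 of
255, arterial/venous ratio 0.944 as in healthy eyes, between-eye CV 7%,
values chosen once as realistic for healthy-cohort spreads) — applies the
group's multiplicative effects, and computes the seven features through
the same formulas the image pipeline uses (the total PID as the
area-weighted mixture), plus a 0.5-point measurement noise on AA. By
default no images are rendered: a thousand cohorts are needed for
calibration experiments, and the feature-level abstraction is exact for
that purpose. With `render = TRUE` every eye is rendered as a full scene
and pushed through kNN propagation, masking and quantification; a suite
test confirms the two modes agree at the abstraction's accuracy.

## Numerical and scale choices

* All feature computation is double precision over integer 8-bit inputs;
  CSV output rounds to 4 decimals (far beyond measurement precision).
* Problem sizes in the bundled tests — 96×96 overfit scenes, 256×256
  recovery scenes, 20 eyes per simulated group, 1000 null cohorts — were
  chosen as the smallest sizes at which each property is cleanly
  observable.
* Seeds: every stochastic component (scenes, cohorts, initialisation,
  shuffling, augmentation) takes an explicit seed and restores the
  caller's RNG state.

## Known limitations

* The band-territory model makes boundaries vertical; real inter-vascular
  watersheds curve. Recovery accuracy is validated only for the band
  geometry.
* Whole-model translation covariance is limited by zero padding; the suite
  asserts exact equivariance of the convolution units instead.
* The rendered cohort mode rescales territory intensities to per-eye
  latents after speckle, so its speckle amplitude is not exactly
  stationary across effect sizes.
* Mixed-effects modelling of inter-eye correlation is intentionally out of
  scope; each eye is treated as independent, as the statistics module
  documents.
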