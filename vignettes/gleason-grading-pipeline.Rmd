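---
title: "Weakly supervised grade-group prediction: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly supervised grade-group prediction: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

gleasonmil implements a two-stage, weakly supervised pipeline that assigns
ISUP grade groups to prostate biopsy slide images using only slide-level
labels — no region-level pattern annotations. This vignette explains the
model, the grading rules it encodes, the synthetic data it is developed and
tested on, and the design decisions taken where the method description left
the choice open.

## The two-stage model

**Stage 1 — patch-level cancer detection by multiple-instance learning.**
A slide is tiled into non-overlapping square patches covering its whole
area. A small CNN scores each patch with a probability of containing
cancer. Because only slide-level labels exist, training uses max-pooling
MIL: each epoch, every candidate patch of every training slide is scored;
the single most suspicious patch per slide is selected and trained with the
slide's binary label (cancer = grade group 1 or higher). For benign slides
this is a hard-negative: the patch the model currently finds most
suspicious is pushed toward benign. Model selection keeps the epoch
checkpoint with the best slide-level PR AUC on the tuning split, where the
slide probability is the max over its patch probabilities. The assumption
under test is that a detector trained this way learns *pattern-specific*
features as a side effect, not just a cancer/benign axis — the mechanism
analyses below probe exactly that.

**Stage 2 — grade grouping from the assembled feature map.** The
penultimate-layer (global-average-pooled) feature vector of every patch is
placed at its grid position, producing a C-channel 2-D feature map: the
slide resized by 1/patch_size with morphology summarized per position.
Off-tissue and padding positions hold zeros, the neutral element for the
convolutional classifier. The grader is five 1x1-convolution + batch-norm +
ReLU layers (mixing each position's features before any spatial context),
a trunk of 16 residual 3x3 blocks (conv-BN-ReLU-conv-BN plus identity,
ReLU after the addition), and a global-average-pool + linear head over six
classes (benign, grade groups 1–5). It minimizes class-weighted
cross-entropy (weights 1, 1, 1.5, 1.4, 1.7, 1.6 from benign to grade group
5) and keeps the checkpoint with the best tune-split quadratic-weighted
kappa.

The full-scale default training recipes: stage 1 uses SGD at
0.01 (x0.1 every 25 epochs), momentum 0.9, weight decay 1e-5, batch 128,
horizontal flips, 90° rotations and brightness/contrast/saturation/hue
jitter of ±0.1/±0.3/±0.3/±0.05; stage 2 uses SGD at 0.1 (x0.1 every 40
epochs), the same momentum and decay, batch 256, random ±5-position shifts,
vertical flips and 90° rotations of the map. Both stages derive every
random draw from one global seed, so a run is a pure function of its
configuration.

## The grading rule engine

A Gleason score is the sum of the primary (most prevalent) and secondary
pattern numbers; grade groups are 1 = score ≤ 6, 2 = 3+4, 3 = 4+3,
4 = score 8, 5 = scores 9–10, with group 0 reserved for benign slides.
`composition_to_grade_group()` derives a slide's group from per-pattern
area fractions the way a pixel-counting ground-truth algorithm does:

1. any pattern under **1% of total slide area** is ignored (noise floor for
   label voting);
2. the primary is the surviving pattern with the largest area — on an exact
   tie the worse pattern wins (our declared, clinically conservative
   tie-break; pathology reporting conventions for exact ties vary);
3. a surviving pattern *worse* than the primary is always the secondary,
   in any amount — even a small focus of pattern 5 raises the score;
4. otherwise the secondary is the **worst** remaining pattern whose share
   of the *cancer* area exceeds **5%**; lower-grade patterns under that
   share are ignored. Note the two thresholds deliberately use different
   denominators (total area vs cancer area), following the two rules'
   separate phrasings.

We chose the *worst*-eligible (not largest-area) lower-grade secondary:
it is the natural reading of "primary plus the worst non-ignored pattern",
and it makes grading monotone under severity upgrades whenever at most two
cancer patterns are present. With three patterns the grade-group system is
inherently non-monotone — shifting area from pattern 4 to 5 can demote the
most-common pattern so that 4+5 (score 9, group 5) becomes 3+5 or 5+3
(score 8, group 4). That is score-table arithmetic, not an implementation
choice; the test suite freezes a worked example of it.

## Synthetic histology

Real WSIs are out of scope; the generator produces procedural textures
whose point is *separability and exact controllability*, not realism:

- **benign** tissue: a few large ring-shaped "glands" (dark rim, bright
  lumen) on pink stroma;
- **pattern 3**: many small discrete rings;
- **pattern 4**: fused solid blobs without lumina;
- **pattern 5**: near-confluent dark sheets (55–70% coverage).

Classes differ in structure count, size and foreground coverage, so a
nearest-centroid classifier on three hand-crafted statistics (foreground
fraction, component count, mean component size) exceeds 90% patch accuracy
— the learning problem is guaranteed solvable before any CNN enters. Colors
sit away from the [0, 1] boundaries so the color jitter cannot clip.

Slides are grids of patches; per-patch labels stand in for pixel masks
(the rule engine is denominated in area units, so either works). Cancer
patches form one contiguous run in scan order — cancer in a biopsy core is
focal, not salt-and-pepper. Patch-label counts follow the requested area
fractions by largest-remainder rounding, and the stored grade group is
always derived from the *realized* composition, so label consistency holds
by construction. When a coarse grid cannot realize a requested group (a
small secondary rounding to zero patches), the composition is resampled
up to 25 times before accepting the realized label.

Per grade group, compositions draw a cancer fraction of 30–70% of the
slide; group 2 gives pattern 4 a 15–45% share of the cancer, group 3 a
55–85% share; group 4 is pure pattern 4; group 5 is pure pattern 5 or
pattern 4 with a 20–45% pattern-5 share. The margins keep compositions
clear of the 1% and 5% rule boundaries so grid rounding cannot flip labels.

What passing tests on this data do **not** show: robustness to stain
variation between institutions, to sub-patch pattern mixing, to tissue
artefacts, or to the morphological ambiguity that drives inter-observer
disagreement on real slides. The synthetic setting isolates the pipeline's
*mechanics* — MIL instance selection, feature-map assembly, proportion
sensitivity — from image realism.

## Desk-scale geometry and problem sizes

The package's own experiments (tests, worked examples) use: 64-pixel
patches on 4x8 grids (32 patches per slide), 160 slides with a uniform
grade-group mix (about 19 training slides per class — below that the
benign / grade-group-1 / grade-group-2 axis, whose textures differ least,
is the first to blur), splits stratified per class with 20% validation and
the
remainder 6:1 train:tune; the stage-1 backbone is a 4-block small CNN
(feature dimension 64, stride-2 convolutions, 20 epochs, batch 32); the
stage-2 trunk keeps its 16 residual blocks at width 32 on an 8x16 canvas
(36 epochs, batch 16, the learning-rate decay interval scaled
proportionally to x0.1 every 12 epochs — a short run that never decays
stays noisy in its late epochs). These sizes train in minutes on one CPU
while
leaving every structural element of the method in place. The full-scale
configuration (DenseNet-121 features at dimension 1024, 64x64 canvases,
the long schedules) remains expressible through the same configuration
objects for users with real data and GPU resources.

## Numerical and design choices

- **Residual initialization.** The second batch-norm gain in every
  residual block starts at zero, so each block is initially the identity.
  Without this, the 16-block trunk's activations inflate with depth and
  SGD at the stated learning rate 0.1 stalls near chance; with it the
  trunk trains reliably. This is the package's initialization choice for
  the reconstruction (exact original layer configuration unpublished).
- **Front widths.** The five 1x1 layers taper geometrically from the
  feature dimension to the trunk width; all widths are overridable.
- **Map-unit shifts.** The ±5 shift augmentation operates in feature-map
  positions: at slide scale 5 *pixels* would be sub-patch and inert.
  Shifts that push content past the canvas edge crop it, as a real
  translation would.
- **MIL details.** Top-1 instance selection per slide per epoch (top-k is
  a config knob); candidate pool defaults to tissue patches only;
  benign-slide instances are hard negatives (most suspicious patch), with
  a random-patch alternative behind a flag.
- **Normalization.** Patches are standardized per channel with constants
  estimated from training patches and stored with the model.
- **Checkpoint ties** resolve to the earliest epoch.
- **PR AUC** uses step-wise average-precision summation (not trapezoids);
  ROC AUC uses midrank ties (0.5 credit per tied pair).
- **Kappa intervals** use the large-sample standard error
  sqrt(p_o(1−p_o)/n)/(1−p_e); for weighted kappa the same form with
  weighted p_o and p_e — a documented choice, flagged in the JSON report,
  no single canonical weighted-interval formula exists, so the choice is
  stated explicitly.
- **Tissue detection** is a background-luminance threshold — adequate for
  synthetic slides on bright "glass"; real-WSI tissue segmentation is out
  of scope.
- **Degenerate inputs.** Empty label grids, one-class label vectors,
  empty confusion matrices, all-background slides and identical feature
  vectors (undefined embedding) raise informative errors rather than
  returning quietly wrong numbers.

## Mechanism analyses

**Feature-space separability.** Cancer patches of patterns 3/4/5 are
sampled, their stage-1 features embedded in 2-D by exact t-SNE (perplexity
50, 1000 iterations, learning rate 200 — implemented in the package since
no t-SNE implementation ships with the environment's R libraries), and
class structure scored by the mean silhouette. The check is comparative:
the trained detector's silhouette must exceed an untrained copy's, showing
that pattern separation was *learned* from binary labels.

**Proportion sensitivity.** Pairs of pure 3+3 and pure 4+4 slides are
horizontally concatenated at width ratios 100:0 … 0:100 (crops snap to
whole patch columns so no patch straddles the junction; unequal heights
would be background-padded) and run through the full pipeline. A
proportion-sensitive grader shows the grade-group-1 probability falling,
groups 4+5 rising, and groups 2 and 3 rising then falling along the
series. These are asserted as trend properties with one standard deviation
of slack; absolute probability values depend on the trained weights and
are deliberately not targets — only the trends are. A pattern-5 series is
omitted: any visible amount of pattern 5 already forces a high group, so
the series would be insensitive.

## Known limitations

- The synthetic textures make stage 1's binary task easy; real slides
  would demand the full-scale backbone and many more slides.
- Grade-group classes whose distinction rests on fine proportion
  boundaries (2 vs 3) are the first to blur when the grid is coarse,
  because the grader sees composition quantized to 1/32 steps.
- The grader's exact layer widths are a declared reconstruction of a
  configuration whose details are not fully specified; all are
  configurable.
- The kappa confidence intervals are large-sample approximations; no
  bootstrap is provided.
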