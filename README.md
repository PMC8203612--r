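# gleasonmil

Weakly supervised, two-stage prediction of ISUP grade groups for prostate
biopsy slide images — trained from **slide-level labels only**, with no
region-level pattern annotations.

Manual Gleason grading assigns each biopsy a score: the sum of the primary
(most prevalent) and secondary Gleason pattern numbers, mapped to five
prognostic grade groups (1 = score ≤ 6, 2 = 3+4, 3 = 4+3, 4 = score 8,
5 = scores 9–10; this package uses group 0 for benign slides). Training a
model to reproduce that grading normally requires costly region-level
annotations. The pipeline implemented here avoids them:

1. **Stage 1 — MIL cancer detector.** The slide is tiled into
   non-overlapping patches; a CNN is trained by max-pooling
   multiple-instance learning: each epoch the highest-probability patch of
   every training slide is selected and trained with the slide's binary
   label (cancer = grade group ≥ 1). Model selection keeps the checkpoint
   with the best slide-level PR AUC on the tuning split, where the slide
   probability is the max over patch probabilities.
2. **Stage 2 — feature-map grader.** The detector's penultimate-layer
   feature vector of every patch is placed at its grid position, giving a
   C-channel 2-D feature map (the slide resized by 1/patch_size). A
   residual CNN — five 1×1 conv+BN+ReLU layers, sixteen residual 3×3
   blocks, global pooling and a 6-class head — is trained on these maps
   with class-weighted cross-entropy (weights 1, 1, 1.5, 1.4, 1.7, 1.6),
   keeping the checkpoint with the best tune-split quadratic-weighted
   kappa.

The package also provides: the Gleason rule engine (1% total-area noise
floor, worst-pattern-any-amount secondary, 5% of-cancer-area rule for
lower-grade secondaries), a procedural synthetic-histology generator that
stands in for real whole-slide images, the evaluation statistics the
method is judged by (ROC/PR AUC, best-F1 operating point, Cohen's κ and
quadratic-weighted κ with confidence intervals), and the two mechanism
analyses (t-SNE separability of pattern features; the ratio-controlled
slide-concatenation proportion-sensitivity experiment). The neural-network
engine (conv/batch-norm/ReLU, SGD with momentum, im2col + BLAS) is
implemented in the package with Rcpp and is gradient-checked in the test
suite. See the vignette `vignettes/gleason-grading-pipeline.Rmd` for the
model, rules and design decisions in full.

## Worked example

```r
library(gleasonmil)

# the rule engine
score_to_grade_group(3, 4)                                   # 2
score_to_grade_group(4, 3)                                   # 3
composition_to_grade_group(c(benign = .5, gp3 = .3, gp4 = .2)) # 2

# end-to-end: 160 synthetic slides, both stages, validation report
res <- run_pipeline(run_config(seed = 42), mechanism = TRUE)
res$evaluation
```

The final call trains both stages (about 8 minutes on one CPU) and prints:

```
Grade-group agreement on 30 slides
  accuracy:    76.7% (95% CI 61.5-91.8%)
  kappa:      0.720 (95% CI 0.538-0.902)
  kappa_quad: 0.963 (95% CI 0.826-1.000)
  confusion matrix (rows = reference):
         predicted
reference 0 1 2 3 4 5
        0 5 0 0 0 0 0
        1 1 4 0 0 0 0
        2 0 0 4 1 0 0
        3 0 0 0 0 5 0
        4 0 0 0 0 5 0
        5 0 0 0 0 0 5
```

Interpretation: on the held-out validation split the grader's ordinal
agreement is high (κ_quad 0.963 — near-diagonal confusions such as grade
group 3 scored as 4 are penalized mildly), benign slides are all
recognized as benign, and the raw accuracy is 76.7%. The stage-1 detector
reached tune-split ROC AUC 1.0. `res$ratio_series` and `res$embedding`
hold the mechanism analyses: the grade-group-1 probability falls
monotonically (0.48 → 0.00) and the group-4 probability rises
(0.00 → 0.99) as the pattern-4 share of a concatenated slide grows, and
the trained detector's pattern features embed with mean silhouette 0.67
versus 0.55 for an untrained copy.

A command-line front end over the same functions is installed at
`inst/cli/gleasonmil.R` (commands: `synth`, `train-stage1`, `featurize`,
`train-stage2`, `grade`, `evaluate`, `mechanism`, `pipeline`).

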