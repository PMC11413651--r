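---
title: "Adversarial scanner unlearning in traveling-model training"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adversarial scanner unlearning in traveling-model training}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A disease classifier trained on brain volumes pooled from many imaging
centers can learn the wrong thing.  Each center acquires images on a
particular scanner, and scanner type correlates — through center-level case
mix — with diagnosis.  Gain, offset, smoothing and noise differences between
scanners are easy features for a convolutional network to pick up, so the
model may classify *scanners* rather than *patients* (shortcut learning).
The problem is acute in the **traveling model** (TM) setting, where a single
model is trained sequentially, one center at a time, precisely because that
setting exists to serve centers too small to support anything else: many
centers contribute fewer than five scans, some only one diagnostic class.

`harmonytm` implements an adversarial *unlearning* procedure embedded in TM
training.  The model carries a scanner-classification head next to its
disease head; harmonization alternates between teaching that head to read
scanner identity from the encoder's features and updating the encoder to
push the head's output toward the uniform distribution — chance level — so
that scanner information is scrubbed from the representation while disease
information is retained.

## Model

The encoder is a small fully convolutional 3D network of seven blocks:
five blocks of {3×3×3 convolution ("same" padding), batch normalization,
2×2×2 max pooling, ReLU}, one block of {1×1×1 convolution, batch
normalization, ReLU}, and a final block of {2×2×2 average pooling, dropout
(rate 0.2), flatten}.  Max pooling floor-divides odd extents and passes an
extent of 1 through unchanged; the average pool is skipped when any extent
is below 2, which is what makes desk-scale 24³ inputs work.  At the full
input size of 160×192×160 with channel widths (32, 64, 128, 256, 256, 64),
the pooling chain ends at 5×6×5 cells, average-pooled to 2×3×2, giving
2·3·2·64 = **768 features**:

```{r, eval = FALSE}
library(harmonytm)
feature_length(encoder_config(c(160, 192, 160)))  # 768
```

Two heads read the features: a dense layer with a sigmoid for the binary
disease output, and a dense layer with a softmax over the M scanner types.

## Losses and the three-step procedure

With batch size N (which varies with center size), disease labels
$y_n \in \{0,1\}$, predicted probabilities $\hat y_n$, one-hot scanner
labels $Y_{nj}$ and scanner-head outputs $P_{nj}$:

* disease loss (binary cross-entropy):
  $L_{pd} = -\tfrac1N \sum_n [y_n \log \hat y_n + (1-y_n)\log(1-\hat y_n)]$
* scanner loss (categorical cross-entropy):
  $L_{sc} = -\tfrac1N \sum_n \sum_j Y_{nj} \log P_{nj}$
* confusion loss (cross-entropy against the uniform distribution):
  $L_{conf} = -\tfrac{1}{NM} \sum_n \sum_j \log P_{nj}$
* total: $L_{total} = L_{pd} + L_{sc} + L_{conf}$.

By Gibbs' inequality $L_{conf} \ge \log M$, with equality exactly when every
row of $P$ is uniform; minimizing it with respect to the *encoder* (the
scanner head held fixed) therefore drives the scanner head toward
chance-level output.  All logs clip probabilities at $10^{-7}$.  Normalizing
every loss by N is what makes the procedure indifferent to the batch-size
variation inherent to TM training, and no scanner-balanced oversampling is
required — single-center batches cannot be balanced across scanners anyway.

Each batch receives three sequential sub-updates ([harmonization_step()]):

1. encoder + disease head minimize $L_{pd}$;
2. the scanner head minimizes $L_{sc}$ on features from the frozen encoder
   (the encoder is bitwise untouched);
3. the encoder minimizes $L_{conf}$ through the fixed scanner head (the
   scanner head is bitwise untouched).

Three independent optimizer states serve the three parameter groups.
`combined = TRUE` instead applies the total loss in a single update — one
forward pass, the encoder receiving the summed disease + confusion
gradient — which is the variant the end-to-end experiment driver uses (see
"Stabilizing the game" below).

Before harmonization the network is pre-trained in two phases: encoder +
disease head on the disease task, then the scanner head with the encoder
frozen.  "Until convergence" is realized as fixed cycle budgets (defaults:
6 and 6 desk-scale cycles), and phase B uses the same traveling schedule as
phase A.

## The traveling loop

One *cycle* draws a fresh random permutation of centers (cycle-to-cycle
variability standing in for batch shuffling), then trains one epoch at each
center in turn: shuffled local samples cut into batches of five plus a
remainder (a center with fewer than five samples trains on what it has).
Every batch is single-center by construction — the structural property that
makes TM training comparatively resistant to scanner shortcuts in the first
place.  Adam starts at `lr_initial` (default 1e-4; desk-scale experiments
use 1e-3) and decays by a factor `lr_decay = 0.95` per cycle; model state —
including batch-norm running statistics — and optimizer state travel across
centers and cycles without reset.  The centralized baseline is identical
except that batches are drawn from the shuffled pooled cohort (and so mix
centers); its epoch count equals the TM cycle count, which matches the
gradient-step budgets exactly.

## The synthetic cohort generator

The generator emulates the *statistical structure* of a large multi-center
neuroimaging database, not MRI physics: a shared smooth anatomy phantom
(superposition of Gaussian blobs), a disease effect that adds `disease_delta`
inside a central spherical mask, a scanner effect
`smooth(v, s·σ) · (1 + s·(gain−1)) + s·offset + noise` applied after the
disease effect (acquisition acting on anatomy), and additive observation
noise.  The default study conditions (`default_cohort_spec()`) are 16
centers, about 320 samples, 4 scanner types at full confound strength,
shard sizes from 2 to 80 with several centers below five samples, centers
with prevalence 0 or 1 (single-class centers), and several centers
operating two scanners.  Two calibration choices were made once and fixed:

* `disease_delta = 0.45`, at which a mask-mean threshold oracle classifies
  disease at roughly 80% accuracy under the full confound — a deliberately
  imperfect signal;
* scanner exposure is balanced across the pool (each scanner type images
  roughly a quarter of the cohort), so that chance level for scanner
  decoding is close to 1/M and an information-free classifier cannot sit
  far above it by majority-guessing.

What the generator does **not** emulate: real anatomical variability between
subjects (all subjects share one phantom), registration and skull-stripping
artifacts, pulse-sequence physics, or site effects beyond the four-parameter
acquisition model.  Passing tests on this cohort therefore demonstrate that
the machinery behaves as designed under controlled confounding — not that
the method reaches any particular performance on real data.

## Stabilizing the adversarial game

Plain alternation of the three updates is fragile at desk scale, and the
package's experiment driver ([harmonize_adaptive()]) wraps it in
convergence machinery driven entirely by training-side diagnostics:

* **Frozen-statistics fine-tuning.**  During harmonization, batch-norm
  layers use their running statistics (mode `"finetune"`) rather than batch
  statistics, and dropout is off.  With single-center batches, batch
  statistics silently normalize away each center's intensity shift, so the
  game would be played on a geometry in which the confound is invisible —
  while evaluation-mode features retain it.  Freezing the normalization
  makes the adversary, the confusion update and the deployed representation
  see the same geometry.
* **Trust-coupled confusion gradient.**  The confusion objective has a
  degenerate solution — a collapsed (all-zero or constant) representation —
  that is absorbing under frozen normalization.  In the combined update the
  adversarial component of the feature gradient is capped at a multiple
  (the *confusion weight*) of the task component's norm plus a small floor,
  so confusion pressure scales with, and cannot drown, the disease signal.
* **Optimal adversary refits.**  At every cycle boundary the scanner head
  is refitted to convergence on the current features (a convex
  ridge-logistic fit on standardized features, folded back into the head's
  affine parameters).  Confusion then pushes against the *best* linear
  scanner readout, which is the condition under which the alternation
  removes linearly decodable scanner information rather than merely
  rotating it out of a lagging head's view.
* **Balance controller with rollback.**  The confusion weight doubles while
  the validation scanner probe remains above chance and the disease
  accuracy holds; a single below-tolerance cycle is treated as a transient
  (the task update usually repairs it, and most productive unlearning
  happens during these excursions), but two consecutive crashed cycles
  trigger a rollback to the best checkpoint with the weight halved.
* **Checkpoint selection.**  Because the adversarial trajectory is not
  monotone, the returned model is the cycle checkpoint with the lowest
  validation scanner-probe accuracy among those whose validation disease
  accuracy stayed within 5 points of its pre-harmonization value.

## Evaluation and the representation audit

Disease performance is reported as accuracy (threshold 0.5), AUROC
(rank-based, ties counted one half — exactly the pairwise estimator),
sensitivity, specificity, precision and F1.  Scanner leakage is reported
two ways: the scanner head's weighted multiclass metrics (per-class
one-vs-rest, support-weighted; multiclass specificity is defined
one-vs-rest) with a rows-are-actual confusion matrix, and a *fresh* linear
probe — ridge-penalized multinomial logistic regression (λ = 1, L-BFGS from
a zero start, features standardized by training-set moments) fitted on
training-set features and scored on held-out features.  The PCA audit
centers the feature matrix, takes the first two principal modes, and fits
the same probe on mode 1, mode 2 and both, for scanner and disease labels,
on a seeded stratified 80/20 split of all samples (held-out probing avoids
the trivially optimistic in-sample separability of such probes).

The test split is stratified by center and class; centers (or within-center
classes) with a single sample stay in training.  The default held-out
fraction is 20%.

## Desk-scale problem sizes

The packaged experiments use 24³ volumes, encoder widths
(4, 8, 16, 16, 16, 8) — 8 features, pre-training budgets of 6 + 6 cycles,
8 harmonization cycles, Adam at 1e-3 (pre-training) and 2e-3
(harmonization) with 0.95 decay.  The unit tests use 6³–8³ volumes and
widths of 2–8.  These sizes keep a full before/after × centralized/TM
study around a minute or two on one CPU core while preserving all
structural properties of the full-scale setting.

## Known limitations

* Harmonization at desk scale reliably removes *most* but not *all*
  linearly decodable scanner information within 8 cycles: in the runs
  reproduced by `scripts/acceptance.R`, the held-out scanner probe falls
  from ≈0.99 to ≈0.40 against a chance level of 0.25, while disease
  accuracy is preserved or improved.  The residue reflects two mechanisms
  we observed directly: ReLU gating patterns (units dead for some scanner
  clusters carry information that gradients cannot reach from the dead
  side) and the entanglement of disease and scanner signal through the
  multiplicative gain (both load on mask-region intensity).  More cycles,
  larger cohorts, or disease effects orthogonal to the intensity axis all
  soften the problem; the 8-cycle desk-scale setting does not fully solve
  it.
* The adversary and the audit probe are linear.  Nonlinearly decodable
  scanner information is neither measured nor removed.
* Batch-norm running statistics are part of the traveling state; a
  zero-learning-rate step leaves the entire bundle bit-identical because
  statistic commits are gated on a nonzero learning rate.
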