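# harmonytm

Scanner-effect unlearning for traveling-model training of 3D neuroimaging
classifiers.

## The problem

When a disease classifier is trained on brain volumes collected at many
imaging centers, scanner type becomes a shortcut: acquisition differences
(gain, offset, smoothing, noise) correlate with center-level case mix, and a
convolutional network will happily classify scanners instead of patients.
The **traveling model** (TM) — a single model trained sequentially, one
center per epoch, designed for networks in which many centers hold fewer
than five scans — inherits this problem and rules out harmonization methods
that need large or paired local datasets.

`harmonytm` implements an adversarial harmonization procedure for the TM
setting.  The encoder (an SFCN-style 3D CNN: five blocks of 3×3×3 conv +
batch norm + 2×2×2 max pool + ReLU, one 1×1×1 conv block, then average
pool + dropout + flatten) feeds two heads: a sigmoid disease head and a
softmax head over the M scanner types.  Per batch of size N, three losses
drive three sequential updates:

- L_pd  = −(1/N) Σₙ [yₙ log ŷₙ + (1−yₙ) log(1−ŷₙ)]   (encoder + disease head)
- L_sc  = −(1/N) Σₙ Σⱼ Yₙⱼ log Pₙⱼ                    (scanner head, encoder frozen)
- L_conf = −(1/(N·M)) Σₙ Σⱼ log Pₙⱼ                    (encoder, scanner head frozen)

L_conf is the cross-entropy of the scanner head's output against the uniform
distribution; it is bounded below by log M, with equality exactly at
chance-level output, so minimizing it w.r.t. the encoder scrubs scanner
information from the representation.  L_total = L_pd + L_sc + L_conf is
logged per batch.  Normalizing by N makes the procedure robust to the
batch-size variation of TM training, and no scanner-balanced oversampling is
needed.

The package also provides: a seeded synthetic multi-center cohort generator
with injectable scanner confounds (so the whole pipeline can be studied
without restricted data), a centralized training baseline, task metrics and
scanner-leakage metrics (weighted multiclass + confusion matrices), a
PCA + linear-probe representation audit, an adaptive harmonization schedule
with rollback and checkpoint selection, and a small command-line driver
(`inst/cli/harmonytm.R`).

## Worked example

```r
library(harmonytm)

# architecture: the full-size encoder flattens to 768 features
feature_length(encoder_config(c(160, 192, 160)))
#> [1] 768

# confusion loss at uniform output over 23 scanner types equals log(23)
loss_confusion(matrix(1/23, 5, 23))
#> [1] 3.135494

# a desk-scale study: synthetic 16-center cohort (~320 samples, 4 scanner
# types, full confound), traveling-model pre-training + 8 adversarial
# harmonization cycles
cfg <- experiment_config(seed = 1, approaches = "tm")
res <- run_experiment(cfg)

round(c(disease_acc_before   = res$tm$before$disease_metrics$accuracy,
        disease_acc_after    = res$tm$after$disease_metrics$accuracy,
        scanner_probe_before = res$tm$before$feature_probe$scanner,
        scanner_probe_after  = res$tm$after$feature_probe$scanner), 3)
#>   disease_acc_before    disease_acc_after scanner_probe_before
#>                0.814                1.000                1.000
#>  scanner_probe_after
#>                0.441
```

Reading the numbers: before harmonization, a fresh ridge-logistic probe
decodes the scanner type from the encoder's held-out features essentially
perfectly (1.000 against a chance level of 0.25) — the representation is
saturated with acquisition information.  After eight adversarial cycles the
probe falls to 0.441 while held-out disease accuracy *improves* from 0.814
to 1.000: the encoder traded scanner-specific intensity cues for disease
signal.  `res$tm$*$pca` holds the corresponding PCA-mode audit, and
`res$central` (when requested) the centralized baseline.

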