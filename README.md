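# vesselmend

Noise-tolerant vessel segmentation that trains a network on imperfect
pixel-wise annotations **and corrects the annotations while it trains**.

## The problem

Dense annotations of thin curvilinear structures (retinal vessels are the
canonical case) are expensive, so labels often come from rough manual
tracing, junior annotators, or pseudo-labeling. Such label maps contain
pixel errors — deleted thin branches, shifted and straightened contours —
that degrade any supervised segmenter trained on them. `vesselmend`
implements a joint framework that (a) trains a small U-Net-style
segmenter on the noisy labels and (b) iteratively rewrites those labels
using per-pixel temporal statistics of the network's own historical
predictions.

## The method

Training runs in an initialization phase followed by `M` cycles of `E`
epochs. Within cycle `j`, a **memory bank** records, per image and per
pixel, the historical best prediction
`S̃ = S^k, k = argmin_u |S^u − L^j|` and its worst counterpart `S̄`
(argmax), over the cycle's epochs `u`. After `T` warm-up epochs on the
plain criterion `E(S, L^j)` (binary cross-entropy with soft targets),
training switches to the **temporal memory loss**

    L = E(S^e, S̃^e) + λ · E(S^e, L^j),   λ = 0.1

self-supervising toward the historical best while keeping a weak pull
toward the current labels. At the end of the cycle the per-pixel
rangeability `d = |S̃ − S̄|` (large spread = unstable, untrustworthy
prediction) weights the **label-correction compensation**

    Q^j = D ⊙ S̃^j + (1 − D) ⊙ S^j

and the labels move along the anchored convex path

    L^{j+1} = 1/(j+1) · L^0 + j/(j+1) · Q^j .

Optimization is Adam (lr 7×10⁻³) with cosine-annealing warm restarts and
stochastic weight averaging; each image is seen as 4 flip views whose
predictions are reversed to canonical orientation before entering the
bank.

No external dataset is needed: the package generates vessel phantoms
with gold masks and corrupts them with polygonal contour-approximation
noise at three severities (LV-1/2/3), the same mechanism used to pollute
annotations in the evaluation protocol it follows.

## Worked example

```r
library(vesselmend)

# 8 phantoms, gold masks corrupted at LV-2
data <- make_noisy_dataset(8, noise_spec("contour_approx", "LV2", seed = 1),
                           seed = 1, size = 96)
mean(sapply(data, function(r) f1_score(r$noisy, sample_gold(r))))
#> [1] 0.6702895        # label quality before correction

cfg <- train_config(total_epochs = 30, init_epochs = 14, n_cycles = 4,
                    epochs_per_cycle = 4, warmup_epochs = 2,
                    sgdr_start_epoch = 10, sgdr_period = 4,
                    seed = 101, model_width = 8)
fit <- run_training(cfg, data)
fit$report$cycles
#>   cycle        f1    pr_auc
#> 1     1 0.6702895 0.8548196
#> 2     2 0.7223021 0.8614118
#> 3     3 0.7708130 0.8789604
#> 4     4 0.8016040 0.8917275
```

The `f1` column is the quality of the corrected label maps against the
(held-back) gold masks after each cycle: label F1 recovers from 0.670 to
0.802 (+13.1 points) in four cycles, and increases monotonically — the
curve the framework is designed to produce. (Cycle 1 equals the baseline
by construction: the `j = 1` update is a half-half blend that cannot move
any pixel across the 0.5 threshold.) `pr_auc` treats the soft corrected
maps as pixel scores.

## Command line

```sh
Rscript inst/cli/vesselmend simulate --n 8 --size 96 --level LV2 --seed 1 --out data/
Rscript inst/cli/vesselmend train --config cfg.yaml --data data/ --out run/
Rscript inst/cli/vesselmend evaluate --pred run/corrected --gold data/gold --out eval.json
Rscript inst/cli/vesselmend ablate --mode q_is_s --config cfg.yaml --data data/ --out run_ablation/
```

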