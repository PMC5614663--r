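# gpdnet

Compact convolutional classification of gastric precancerous lesions
(erosion, polyp, ulcer) with fire modules, plus **iterative reinforced
learning (IRL)** — a prune-and-retrain fine-tuning loop — and a
weight-magnitude sensitivity analysis. Everything runs on 32×32 RGB
images on a plain CPU, and a built-in synthetic lesion-texture
generator makes the whole pipeline reproducible without clinical data.

## What it implements

**GPDNet (fire variant).** A fully convolutional classifier:

    conv 5×5 (3→32) → max pool → fire(32; s16; e1×1 32; e3×3 32)
    → avg pool → fire(64; s16; e1×1 32; e3×3 32) → avg pool
    → conv 1×1 (64→L) → global average pool → softmax

A fire module squeezes channels with 1×1 filters, then expands through
parallel 1×1 and 3×3 branches concatenated channel-wise. For L = 3 the
network has exactly **14,368** kernel weights, versus **144,928** for
the CIFAR-10-quick-style dense-head baseline (`use_fire = FALSE`) — a
tenfold reduction.

**Training.** Mini-batch SGD (N = 32) with momentum 0.9 on the summed
cross-entropy

    Loss = Σ_{(X_i, l_i) ∈ D} −log P(l_i | X_i; (W, b)),

Xavier initialization, step learning-rate decay, fully seeded and
bit-reproducible.

**IRL.** With threshold α (default 0.001):

    w ← 0   if |w| ≤ α,   then retrain with the modified model as the
                          pretrained start; repeat.

Zeroed weights may relearn freely — there is no sparsity mask.
`sweep_irl()` scans a threshold grid, sharing one scratch model.

**Sensitivity.** Histogram kernel weights into the ten magnitude bins
[0, 0.001), [0.001, 0.005), …, [0.3, 0.4), [0.4, ∞); zero out one bin
at a time from the intact model and re-measure test accuracy.

## Worked example

```r
library(gpdnet)

spec <- build_gpdnet(3, use_fire = TRUE)
print(spec)
#> GPDNet network spec: 9 layers, 3 classes, 32x32 input
#>   ...
#> kernel weights: 14368 (with biases: 14563)

set <- generate_synthetic_gpd(150, seed = 1, difficulty = "easy")
sp  <- split_train_test(set, per_class_test = 50, seed = 1)

fit <- gpdnet(sp$train, variant = "fire",
              config = train_config(epochs = 12, base_lr = 0.015,
                                    step_size = 6, gamma = 0.3,
                                    seed = 1, eval_every = 4),
              test_set = sp$test)
print(fit)
#> fitted GPDNet (fire variant), 3 classes
#> kernel weights: 14368; epochs: 12; final loss: 105.2128
#> final test accuracy: 0.9200
```

The final loss is the summed cross-entropy over the 300 training
images; 0.92 is top-1 accuracy on the 150 held-out images. A short IRL
run (here 2 iterations on a 6-epoch budget) records the zeroed-weight
count and accuracy per iteration:

```r
irl <- run_irl(fit$spec, sp$train, sp$test,
               train_config(epochs = 6, base_lr = 0.015, step_size = 6,
                            gamma = 0.3, seed = 1, eval_every = 6),
               irl_config(threshold = 0.001, iterations = 2))
print(irl)
#> IRL trace: threshold 0.001, 2 iterations
#>  iteration zeroed accuracy
#>          0      0     0.82
#>          1    123     0.66
#>          2    111     0.88
```

and the sensitivity analysis shows the hallmark asymmetry: zeroing the
~1,200 weights below magnitude 0.01 costs nothing, while zeroing the
mid- and high-magnitude bins collapses accuracy toward chance:

```r
sens <- sensitivity_curve(fit$spec, coef(fit), sp$test)
print(sens)
#> weight-magnitude sensitivity (baseline accuracy 0.9200)
#>            bin    lo    hi count  accuracy
#>      [0,0.001) 0.000 0.001   107 0.9200000
#>  [0.001,0.005) 0.001 0.005   469 0.9200000
#>  ...
#>    [0.3,0.400) 0.300 0.400   228 0.5400000
#>      [0.4,Inf) 0.400   Inf     3 0.9133333
plot(sens)   # bar = counts, line = post-ablation accuracy
```

## Command line

A thin wrapper script ships in `inst/cli/`:

```sh
Rscript inst/cli/gpdnet.R simulate --out data --n-per-class 500 --split 300
Rscript inst/cli/gpdnet.R train --data data/train --test data/test --out run1
Rscript inst/cli/gpdnet.R irl --data data/train --test data/test \
        --out run2 --threshold 0.001 --iterations 6
Rscript inst/cli/gpdnet.R sensitivity --weights run1/weights.rds \
        --data data/test --out run3
Rscript inst/cli/gpdnet.R count-params --no-fire
```

Every command writes a JSON run manifest (seed, resolved options,
outputs, timestamps) so a run can be reproduced exactly.

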