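# cellsage

Lightweight attention-augmented convolutional classification of H&E
histopathology patches, implemented end to end in R.

## What this package is for

Pathologists classify breast-tissue biopsies as benign or malignant from
stained microscope images — slow, fatiguing work with real inter-observer
variability. CNN assistants help, but clinically deployable models must be
small and fast. `cellsage` implements such a network and everything around
it: stain-aware preprocessing, leakage-free patient-level data
partitioning, the full training recipe, evaluation metrics with
cross-validation aggregation, Grad-CAM saliency, analytic efficiency
profiling, and a synthetic histology-patch generator so the entire pipeline
is testable on a laptop with no external data. There is no deep-learning
framework underneath: convolutions, batch norm, attention, backpropagation
and Adam are written on base R + BLAS, with the backward pass verified
against finite differences and explicit-loop oracles.

## The model

For an input patch `x` (3 × 224 × 224):

```
F_mscfe = concat(conv7(x), conv5(x), conv3(x))          # multi-scale extractor
F_dwb   = dropout(relu(pw(relu(bn(dw(F_mscfe))))))      # × 8 separable blocks
F_cam   = σ(MLP(maxpool(F_dwb)) + MLP(avgpool(F_dwb)))  # channel attention
F'      = F_cam ⊙ F_dwb
F_sam   = σ(conv7x7(concat(maxpool_c(F'), avgpool_c(F'))))  # spatial attention
F''     = F_sam ⊙ F'
p(malignant) = σ(w·GAP(F'') + b)
```

The channel-attention MLP is a single shared bottleneck (C → C/16 → C)
applied to both pooled descriptors. The frozen reference configuration
(stage widths 120/240/544/1472, 32-channel branches) was calibrated with
the package's analytic profiler to meet the published efficiency budgets:
3.8 M parameters and 0.49 GFLOPs per forward pass (1 MAC = 1 FLOP).

## Worked example

Profile the reference network and the baseline oracles:

```r
library(cellsage)
count_macs(reference_config(), 224)
#>                layer params     macs
#>      mscfe.branch7x7   4736 59006976
#>      mscfe.branch5x5   2432 30105600
#>      mscfe.branch3x3    896 10838016
#>  stage1.block1.dw3x3    960  2709504
#>  ...                                    (30 layers)
#> total: 3,833,680 params (3.83 M), 489,433,122 MACs (0.489 G)

profile_mobilenet_v2()$total_params      # 3504872  (validates the counter)
profile_efficientnet_b0()$total_macs/1e9 # 0.3858   (prints as 0.39 G)
```

Generate a synthetic dataset, split it patient-wise, train a width-reduced
model and evaluate on held-out patients:

```r
dir <- tempfile()
idx  <- generate_dataset(synthetic_config(), dir)   # 16 patients, 192 patches
plan <- patient_stratified_split(idx, seed = 7)     # 60/20/20 by patient
prof <- default_stain_profile()

tiny <- model_config(input_size = 64L, mscfe_branch_channels = 4L,
                     stage_widths = c(15L, 30L, 68L, 184L),
                     cbam_reduction_ratio = 8L)
fit <- train(build_model(tiny, seed = 11),
             subset_index(idx, plan, "train"),
             subset_index(idx, plan, "val"),
             train_config(learning_rate = 3e-3, batch_size = 16L,
                          max_epochs = 70L, early_stop_patience = 30L,
                          seed = 11L),
             prof, dir)
res <- evaluate(fit$model, subset_index(idx, plan, "test"), prof, dir)
c(res$accuracy, res$f1, res$auc)
#> [1] 87.500000  0.888889  1.000000
```

Accuracy is percent correct at threshold 0.5; F1 is for the malignant
class; AUC is the probability a random malignant patch outscores a random
benign one — here the held-out patients are ranked perfectly. Grad-CAM
saliency (red = high attention, blue = low):

```r
img <- read_png(file.path(dir, idx$image_path[100]))
gc  <- grad_cam(fit$model, preprocess_image(img, prof, 64L))
write_png(gradcam_overlay(resize_bilinear(img, 64), gc$map), "overlay.png")
```

A command-line wrapper ships in `inst/exec/cellsage`
(`profile`, `synthesize`, `split`, `normalize`, `train`, `evaluate`,
`gradcam`).

## Layout

* `R/` — model core, profiler (+ MobileNetV2/EfficientNet-B0 layer
  tables), preprocessing, data pipeline, synthetic generator, training /
  metrics / Grad-CAM, PNG codec, CLI.
* `vignettes/cellsage-methods.Rmd` — the model, every tunable with units
  and defaults, generator design, numerical choices, limitations.
* `tests/testthat/` — unit and property suites plus `test-acceptance.R`
  (one block per acceptance criterion).
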