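# SpineVCR

Automated measurement of the **vertebral compression ratio (VCR)** on
lateral thoracolumbar spine radiographs, for researchers building or
validating vertebral-fracture quantification pipelines.

Vertebral compression fractures deform vertebral bodies; the standard
screening quantity is the anterior-height compression of a level relative
to its neighbours:

```
VCR = [ 1 − V₂ / ((V₁ + V₃) / 2) ] × 100 (%)
```

where `V₂` is the anterior vertebral height (AVH) of the index vertebra and
`V₁`, `V₃` the AVHs of the cranial and caudal neighbours. Measuring it
automatically requires segmenting each vertebral body; SpineVCR implements
the full chain:

* **Pre-processing** — 16→8-bit percentile rescale, CLAHE, Gaussian
  denoising, aspect-preserving resize with zero padding to 512×512, and an
  invertible coordinate transform so measurements map back to original
  pixels or millimetres. PNG and (minimal, uncompressed) DICOM readers.
* **MDR2-UNet segmentation** — a U-shaped network whose first encoder stage
  is a multi-dilated residual block (parallel 3×3 convolutions at dilation
  rates 2/4/8/16, concatenated and reduced by a 1×1 bottleneck, with a
  shortcut) and whose remaining stages are recurrent residual blocks
  (weight-shared convolution applied over time steps with feature
  accumulation). Implemented natively on RcppArmadillo kernels, with
  dice-loss training, Adam, reduce-on-plateau scheduling, best-epoch
  checkpointing and seeded k-fold cross-validation.
* **Post-processing** — removal of under-sized connected components and
  iterative strict 8-neighbourhood hole filling (plus a flood-fill mode).
* **Measurement** — 8-connected instance separation, craniocaudal ordering
  along the principal spine axis, corner landmarks by signed-projection
  extrema, per-level VCR with severity grading, flagged maximum level.
* **Evaluation** — pixel sensitivity/specificity/accuracy/DSC (per image,
  mean ± sd), pooled ROC and precision–recall curves with trapezoidal AUC,
  and Pearson + Bland–Altman agreement between VCR series.
* **Synthetic phantoms** — a generator of lateral-spine phantoms with
  pixel-perfect masks, exact corner ground truth and known per-vertebra
  compression, so every stage is testable without patient data.

## Worked example

Generate a phantom whose third vertebra is anteriorly wedged by 35% and
measure it from the ground-truth mask:

```r
library(SpineVCR)
s <- generatePhantom(phantomSpec(compressedIndex = 3,
                                 compressionFraction = 0.35, seed = 7))
measureVCR(phantomMask(s))
#> VCRReport: 5 vertebrae, 3 interior levels
#>   levelIndex v1 v2 v3 vcrPercent    grade
#> 1          2 65 65 42     -21.50     none
#> 2          3 65 42 65      35.38 moderate
#> 3          4 42 65 65     -21.50     none
#> flagged level: 3 (max VCR 35.4%)
```

Level 3 is flagged with a measured VCR of 35.4% against the built-in 35%
(the sub-pixel gap comes from rasterisation), graded *moderate* under the
default 20/25/40 cut points. The neighbouring levels report negative values
— they are taller than the mean of their neighbours, one of which is the
compressed body — and negative values are deliberately not clamped.

Training a desk-scale model on phantoms and evaluating it end to end:

```r
ds   <- generatePhantomDataset(phantomSpec(imageHeight = 128,
                                           imageWidth = 128), 50, seed = 1)
imgs <- lapply(ds, function(s) phantomImage(s) / 255)
msks <- lapply(ds, phantomMask)
model <- buildModel(modelConfig(depth = 4, baseFilters = 8,
                                inputSize = c(128, 128)), seed = 1)
fit <- trainModel(model, imgs[1:40], msks[1:40], imgs[41:50], msks[41:50],
                  trainConfig(epochs = 30, seed = 1))
preds <- lapply(41:50, function(i)
  cleanMask(predictMask(fit$model, imgs[[i]])$mask))
segMetricsSet(preds, msks[41:50])$mean
#> sensitivity specificity    accuracy         dsc
#>   0.9686731   0.9969244   0.9916683   0.9769475
```

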