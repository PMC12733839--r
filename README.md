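# deepclahe

Learned, stage-specific contrast enhancement for non-contrast brain CT in
ischemic stroke.

Early infarcts are nearly invisible on CT: gray/white matter contrast is a
handful of Hounsfield units and a hyperacute lesion can sit below the noise
floor.  `deepclahe` implements an enhancement framework in which a compact
convolutional network inspects each scan and predicts three parameters -- the
slope `alpha` in [0.5, 2] and intercept `beta` in [-5, 5] of a linear HU
transform, and the CLAHE clip limit `gamma` in [0.1, 2] -- so that the
enhanced image

```
enhanced = CLAHE( uint8( window( alpha * HU + beta ) ), gamma )
```

minimizes a composite objective

```
loss = 0.8 * (-EME/50) + 0.2 * (-PSNR/40) + 0.01 * reg
```

that rewards block-based local contrast (EME), preserves fidelity to the
windowed original (PSNR), and penalizes extreme parameters (squared
normalized deviation from the range midpoints).  Infarct appearance evolves
across temporal stages (hyperacute, acute, subacute, chronic), so networks
are trained per stage and the package reports per-stage 95% confidence
intervals of the learned parameters.

The package is self-contained and CPU-sized:

* **phantom** -- seeded synthetic brain-CT phantoms with stage-labeled
  hypodense lesions and exact ground-truth masks, plus flip/rotation
  augmentation and inter-scanner affine jitter;
* **preprocess** -- DICOM rescale-pair conversion to HU, bilinear
  resampling, brain windowing (35/70), round-half-up 8-bit quantization;
* **enhance** -- the constrained linear transform, a fully specified CLAHE
  dialect (relative clip, single-pass redistribution, reflection padding,
  bilinear tile interpolation), and six classical enhancers (gamma, power
  law, log, CLAHE, HE, AHE);
* **metrics** -- EME, PSNR, and the composite loss;
* **optimize** -- the parameter-prediction CNN (5 conv blocks with batch
  norm/ReLU/max-pool, adaptive average pooling, 4 FC layers; implemented in
  vectorized base R with a tested analytic backward pass), trained through
  the hard pipeline via wide-step central differences, plus an exhaustive
  grid-search oracle and stage-stratified parameter summaries;
* **classify** -- encoder features + LR/SVM/RF behind a stratified k-fold
  harness with the standard ACC/PPV/recall/F1 (+/- SD) report layout;
* **compare** -- paired t-tests of EME/PSNR before vs after a prior linear
  transform for each classical enhancer;
* **interpret** -- Grad-CAM attention maps over the final conv block, a
  lesion localization score, and overlay PNG output;
* **workflow** -- a seeded end-to-end pipeline with a hash manifest, also
  exposed as a thin CLI (`inst/cli/deepclahe`).

## Worked example

```r
library(deepclahe)

# a chronic-stage phantom with its ground-truth lesion mask
sample <- make_phantom(phantom_spec("chronic", image_size = 64, seed = 3))

# train a stage-specific parameter network on 40 phantoms
train <- make_dataset(40, "chronic", base_seed = 101, image_size = 64)
cfg <- param_net_config(conv_channels = c(8, 12, 16, 24, 32),
                        fc_widths = c(128, 64, 16, 3), dropout_rate = 0.2,
                        pooled_size = 2, input_size = 32, seed = 42)
fit <- train_param_net(train, build_param_net(cfg),
                       train_config(epochs = 25, batch_size = 8,
                                    learning_rate = 0.01, seed = 7))

# predict per-image parameters and compare with the exhaustive oracle
p <- predict_params(fit$net, resample_to(sample$image, 32))
p
#> <enhancement_params alpha=1.1155 beta=-4.9962 gamma=0.3026>

res <- enhance_pipeline(sample$image, p)
combined_loss(res$ref8, res$enhanced8, p)
#> <metric_report eme=21.491 psnr=36.62 dB loss=-0.5104>

grid_search_params(sample$image, 9)$loss
#> [1] -0.5351
```

The network, trained for a minute on a laptop CPU, lands within 0.025 loss
units of the 729-point exhaustive optimum on this held-out phantom, and far
below the static baseline `(1.25, 0, 1.0)` (loss -0.426 here): the learned
per-scan parameters recover most of what exhaustive per-image search would
buy.  `summarize_stage_params()` then aggregates predictions into the
per-stage confidence-interval table, and `gradcam()` renders where a trained
stage classifier looks:

```r
clf <- train_image_classifier(imgs8, labels, clf_cfg, epochs = 10,
                              learning_rate = 3e-3, seed = 2)
map <- gradcam(clf, imgs8[[1]], "chronic")
localization_score(map, sample$lesion_mask)  # fraction of heat on lesion
```

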