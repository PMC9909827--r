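# bodycomp

Automated body-composition analysis of abdominal CT in R: encoder–decoder
neural networks segment axial slices into subcutaneous fat, visceral fat,
and skeletal muscle; per-slice areas are integrated into compartment
volumes; and the L3 skeletal muscle index (SMI = muscle area / height²,
cm²/m²) drives a sarcopenia screen with ROC analysis and Youden-optimal
cutoff selection.

The package is self-contained and CPU-only. Three network variants
(U-Net, attention U-Net, SegNet-style) are built on compiled
convolution/pooling primitives with a hand-verified reverse-mode
gradient tape, trained with Adam on a combined cross-entropy + soft-Dice
loss. A geometric phantom generator produces labelled synthetic CT with
closed-form analytic areas, so every stage — losses, gradients,
trapezoidal volume integration, ROC logic, file I/O — is validated
against exact references. See
`vignettes/body-composition-methods.Rmd` for the full model description.

## Worked example

Simulate a labelled phantom stack and quantify its ground-truth masks:

```r
library(bodycomp)

base <- phantom_spec(image_size = 64L, pixel_spacing = 3.5)
vs <- phantom_volume_spec(base, n_slices = 5, slice_thickness = 5)
gv <- generate_volume(vs, seed = 7)
gv$volume
#> <ct_volume> 64 x 64 x 5 slices, 3.5 x 3.5 mm pixels, 5 mm thickness

quantify_masks(gv$masks, pixel_spacing = 3.5, slice_thickness = 5)
#> $areas
#>       subq visceral muscle
#> [1,] 85.75  18.4975  61.74
#> [2,] 85.75  18.4975  61.74
#> [3,] 85.75  18.4975  61.74
#> [4,] 85.75  18.4975  61.74
#> [5,] 85.75  18.4975  61.74
#>
#> $volumes
#>     subq visceral   muscle
#>  171.500   36.995  123.480
```

Train a small U-Net on phantom slices and evaluate the segmentation
(about four minutes on one CPU core):

```r
train <- lapply(1:16, function(s) {
  sl <- generate_slice(base, seed = s)
  list(image = sl$image, mask = sl$mask)
})
net <- build_network(network_config("unet", depth = 2, base_channels = 8),
                     seed = 1)
net
#> <seg_network> unet, depth 2, base 8 channels, 29339 parameters

fit <- train_model(net, train, config = training_config(epochs = 200, seed = 1))
fit
#> <seg_fit> unet trained 200 epochs; final train loss 2577.2498

pred <- predict(fit, train[[1]]$image)
evaluate_masks(list(pred), list(train[[1]]$mask))
#>   image   tissue       dsc       iou precision    recall
#> 1     1     subq 1.0000000 1.0000000 1.0000000 1.0000000
#> 2     1 visceral 0.9453682 0.8963964 0.9851485 0.9086758
#> 3     1   muscle 0.9960396 0.9921105 0.9940711 0.9980159
#> ...
```

Screen a synthetic cohort for sarcopenia from noisy area measurements:

```r
coh <- generate_cohort(cohort_spec(n_patients = 300L), seed = 2)
set.seed(3)
screen_cohort(coh, measured_areas = coh$muscle_area_cm2 + rnorm(300, 0, 3))
#> Sarcopenia screening (n = 300, cutoff 38.5)
#>   TP 110  FP 3  FN 4  TN 183
#>   accuracy 0.977  sensitivity 0.965  specificity 0.984  prevalence 38.0%
#>   AUC 0.9969; Youden-optimal cutoff 38.94 (J = 0.956)
```

`run_full_pipeline()` chains these stages for a CT volume and a fitted
network: segment every slice, extract the 41-slice L3 window, compute
areas, volumes, SMI, and the sarcopenia flag, and optionally write NIfTI
masks, a quantification CSV, and a checksummed manifest.

A command-line front end with `simulate` / `quantify` / `screen`
subcommands is installed at `inst/cli/bodycomp.R`.

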