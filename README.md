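# scosnet

Does *jointly* learning to segment spatially-correlated organs make a
segmentation network more robust to image rotation than one network per
organ?

Thoracic organ-at-risk contouring models are trained almost entirely on
supine (unrotated) CT, but deployed scans can be rotated in-plane by
positioning and immobilisation. `scosnet` is a desk-scale, fully synthetic
re-implementation of that comparison for the thorax (bilateral lung, heart,
spinal cord): it provides the data, the models, the metrics and the
orchestrated study, so the whole experiment runs on one CPU in minutes
instead of on a private clinical cohort and a GPU.

The compared learning-task settings, all sharing one U-net-like
encoder-decoder backbone (depth *d*, base filters *f*; 1×1 convolution
heads):

| setting | heads | loss |
|---|---|---|
| STL (single-task ×3) | 1 sigmoid per network | `L = -(1/N) Σᵢ Diceᵢ` |
| SCOS (joint) | 3 sigmoid (lung, heart, cord) | `L = -(1/N) Σᵢ (Dice_lung + Dice_heart + Dice_cord)ᵢ` |
| TASKS1 | 3 sigmoid + linear distance map | `L_seg + Σₓ (g(x) − p(x))²` |
| TASKS2 | TASKS1 + 3 sigmoid contour heads | `L_seg + L_contour + L_distance` |

with `Dice = 2|X∩Y| / (|X| + |Y|)`, Adam (lr 10⁻³, batch 8), and a fixed
epoch budget. Evaluation uses Dice, maximum and 95th-percentile Hausdorff
distance, average surface distance (ASD), and `N(inf)` — the number of
cases where the prediction is empty although the organ is present
(ASD = ∞, total recognition failure). Rotation-robustness protocol: train
on unrotated slices only, test on slices rotated by ±30° (2D) and on
volumes rotated by modest whole-case angles (3D, with
largest-connected-component post-processing).

The synthetic thorax phantom generates CT-like slices with exact analytic
masks at any rotation angle: air/lung/soft-tissue/bone contrast, a heart
that is *only* identifiable from its position between the lungs, and a
small spinal cord inside a bright vertebral ring. Interpretation tools
(guided grad-CAM, input-gradient maps, average feature maps, analytic
receptive fields) reproduce the visualisation analyses used to explain the
robustness differences.

## Worked example

Train the joint model on unrotated phantoms, then score it on rotated ones:

```r
library(scosnet)

# a labelled phantom cohort: training is unrotated, the test set is rotated
cfg <- phantom_config(seed = 42)
train <- generate_dataset(cfg, 96)
test_cfg <- cfg; test_cfg$seed <- 43
test <- generate_dataset(test_cfg, 40, rotated = TRUE)

# jointly learn the three spatially-correlated organs on one backbone
fit <- scosnet(train, setting = "SCOS", epochs = 40, seed = 1)
print(fit)
#> Fitted network (SCOS), depth 3, base filters 8, 29339 parameters
#> heads: lung, heart, cord
#> trained 40 epochs (batch 8, lr 0.001); final train loss -2.8970

# predict organ masks for the rotated test slices and score them
pred <- predict(fit, test, type = "mask")
pred_cases <- lapply(seq_along(test), function(i)
  lapply(pred[c("lung", "heart", "cord")], function(a) a[, , i]))
truth_cases <- lapply(test, function(s) s$masks)
records <- evaluate_masks(pred_cases, truth_cases, mode = "2d")
print(summarize_records(records), digits = 3)
#>    organ metric     q1 median    q3    iqr  mean  n n_inf
#> 1   lung   dice 0.9692  0.976 0.982 0.0128 0.975 40     0
#> 2   lung max_hd 1.0000  1.414 2.000 1.0000 2.618 40     0
#> 3   lung   hd95 1.0000  1.000 1.000 0.0000 1.010 40     0
#> 4   lung    asd 0.1202  0.170 0.240 0.1194 0.184 40     0
#> 5  heart   dice 0.9035  0.947 0.962 0.0590 0.912 40     0
#> ...
#> 9   cord   dice 0.8961  0.917 0.953 0.0573 0.919 40     0
cat("total recognition failures:", n_inf(records), "\n")
#> total recognition failures: 0
```

The network trained only on upright phantoms still finds all three organs
on ±30°-rotated slices (median Dice 0.98 / 0.95 / 0.92 for lung / heart /
cord here; distances in pixels). The full comparison against single-task
networks and rotation augmentation is one call:

```r
study <- run_study(experiment_config(settings = c("STL", "SCOS", "SCOS_aug"),
                                     seeds = 1:3), verbose = TRUE)
print(study)
dice_difference(study, "SCOS", "STL", mode = "2d")   # paired per-case bars
```

In our runs the most robust signal mirrors the full-scale finding through
the failure counts: summed over organs on the rotated 2D test, the
single-task networks accumulate hundreds of total recognition failures
(one seed's cord network collapses completely on rotated slices despite a
0.94 validation Dice), the joint network a handful, and the augmented
joint network none — while all settings remain essentially tied near
ceiling on the intensity-separable lung.

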