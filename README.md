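# roscope

Image-based assessment of reactive oxygen species (ROS) in single microglial
cells. Activated microglia raise their cellular ROS level; fluorogenic dyes
such as CellROX report it as a punctate fluorescence signal that can be
imaged by confocal microscopy alongside an actin reporter outlining the
cell. `roscope` implements the full analysis platform for such experiments,
for cell biologists quantifying treatment effects (e.g. cannabidiol, CBD, as
a ROS-reducing agent under immune challenges such as LPS, GP120 or
amyloid-beta 1-42) and for image-analysis researchers studying what compact
CNN classifiers can learn from fluorescence z-stacks.

The package covers six stages, each usable on its own:

1. **Simulation** — labelled synthetic two-channel (actin + ROS) confocal
   z-stacks of single cells with exact ground truth
   (`generate_cell_stack()`, `generate_dataset()`, `separable_scene()`).
2. **Quantification** — ImageJ-style per-cell measures over the
   actin-outlined cell: area (µm²), mean, max, integrated density
   (mean × area) and raw integrated density (pixel sum), compared between
   treatment groups with Welch's two-tailed t-test,
   t = (x̄₁ − x̄₂)/√(s₁²/n₁ + s₂²/n₂), with Welch–Satterthwaite degrees of
   freedom (`segment_cell()`, `measure_cell()`, `welch_test()`,
   `compare_groups()`).
3. **Preprocessing** — z-slice augmentation (every optical section becomes a
   training image), min–max normalization to 8 bits, 256×256 area resize,
   histogram equalization, and stratified 72/8/20 train/val/test splits with
   leakage-safe by-cell grouping (`preprocess_slice()`, `split_dataset()`).
4. **Models** — the two-convolution / three-linear-layer CNN whose shape
   chain on a 1×256×256 input is pinned to conv(8, k16) → 5×5 max pool +
   0.20 dropout → 8×48×48 → conv(16, k5) → pool → 1×1024 → 256 → 64 → 2 (or
   3 classes for the condition model), with an exact layer-shape calculus
   (`build_treatment_model()`, `build_condition_model()`, `trace_shapes()`).
5. **Training & evaluation** — cross-entropy + Adam (lr 0.0001, 10 epochs,
   batch 32) with accuracy/loss curves, confusion matrices (TN upper-left,
   positive = CBD) and ROC/AUC; the engine (im2col convolutions, explicit
   backprop, Adam) is implemented in the package with RcppArmadillo kernels
   and is seed-reproducible (`train_model()`, `evaluate()`,
   `overfit_divergence()`).
6. **Interpretability** — Grad-CAM saliency maps from the conv layers plus
   an edge-saliency fraction quantifying how much saliency sits at the cell
   boundary (`grad_cam()`, `edge_saliency_fraction()`).

`run_pipeline()` chains everything from one seeded YAML config
(`inst/extdata/demo_config.yaml`); `inst/scripts/roscope.R` is a thin
command-line wrapper with matching subcommands.

## Worked example

Simulate a small LPS study (8 cells per treatment), quantify it, and test
the CBD effect on the raw integrated density:

```r
library(roscope)

scene  <- scene_params(image_size_px = 96, n_slices = 6, pixel_size_um = 0.5,
                       cell_radius_um = c(12, 18))
design <- effect_design(n_per_group = 8, conditions = "LPS",
                        baseline_mult = 1, cbd_mult = 0.6,
                        motif = "peripheral")
dir <- tempfile()
generate_dataset(scene, design, dir, seed = 1)
measures <- quantify_dataset(dir, pixel_size_um = 0.5)
compare_groups(measures)$comparisons
#>   condition     measure n_control n_treated mean_control mean_treated
#> 1       LPS raw_int_den         8         8      6602359      4467640
#>           t       df            p stars
#> 1 -5.790744 11.27789 0.0001096768   ***
```

CBD-treated cells carry about a third less measured ROS signal here (the
designed effect is a 0.6 multiplier on the ROS signal itself; the constant
imaging background dilutes the measured ratio), and Welch's test flags the
reduction at p < 0.001.

Train the binary treatment classifier on the strongly class-separated
benchmark (400 slices from 100 synthetic cells) and evaluate it:

```r
slices <- simulate_slice_dataset(
  effect_design(n_per_group = 50, conditions = "LPS", baseline_mult = 1,
                cbd_mult = 0.5, motif = "peripheral"),
  separable_scene(), seed = 1)
split <- split_dataset(slices$info, seed = 1)          # 288/32/80, by cell
model <- train_model(build_treatment_model(), slices, split,
                     train_config(seed = 1, eval_test = TRUE))
tail(as.data.frame(model$history), 1)
#>    epoch train_loss   val_loss train_acc val_acc test_acc
#> 10    10 0.03406288 0.04324229       100     100      100
evaluate(model, slices, split)
#> <eval_report> n = 80, accuracy = 100.00%, macro AUC = 1.000
#>          predicted
#> truth     control CBD
#>   control      40   0
#>   CBD           0  40
```

The test accuracy reaches 100% by epoch 5 on this benchmark; `grad_cam()`
on any test slice returns a 256×256 saliency map, and
`edge_saliency_fraction()` scores how much of it lies on the cell edge.

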