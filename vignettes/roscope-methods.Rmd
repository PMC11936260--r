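---
title: "Methods: simulation, quantification and classification of microglial ROS images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, quantification and classification of microglial ROS images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(roscope)
```

# The problem

Activated microglia produce reactive oxygen species (ROS), and fluorogenic
dyes such as CellROX report cellular ROS as a punctate green signal that can
be imaged by confocal microscopy alongside an actin reporter outlining the
cell. `roscope` implements a complete image-based ROS assessment platform for
this kind of experiment: single cells are imaged as two-channel z-stacks, the
actin channel defines the cell outline, the ROS channel is quantified per
cell with ImageJ-style measures and compared across treatment groups by
Welch's t-test, and the same z-stack slices feed compact convolutional
classifiers that predict either the treatment (CBD vs vehicle control) or
the immune challenge (LPS, GP120 or amyloid-beta 1-42). Because no suitable
public dataset of this design exists, the package ships a first-class
synthetic-data generator with ground truth, and every quantitative claim the
package makes is demonstrated on that generator.

# The synthetic scene model

`generate_cell_stack()` renders one cell per field, following the single-cell
crops the quantification works on.

**Geometry.** The cell body is an ellipsoid whose in-plane boundary is
perturbed by low-order radial harmonics (orders 2-5, amplitudes up to 7%),
giving the irregular but convex-ish outlines typical of HMC3 somata. The
acquired z-range is centred on the cell and the cell's axial semi-extent
scales with the stack height (`z_extent_factor`, default 0.75 stack
heights), so every optical section intersects the cell, as it does when an
operator centres a stack on a cell; sections near the stack edges see a
smaller cross-section, and values above 1 keep even the end sections close
to the equatorial size.

**Actin channel.** A bright cortical rim follows the boundary (Gaussian
profile of the stated cortex width on the inside, falling off four times
faster outside so the outline does not overshoot the membrane) on top of a
dim cytoplasmic fill at 15% of the rim amplitude.

**ROS channel.** Puncta counts are Poisson with the scene rate; peak
amplitudes are log-normal, parameterized by their expectation so that all
effect multipliers act exactly multiplicatively on the expected signal.
Puncta are placed inside the mask according to the group's spatial motif
(`peripheral`, `perinuclear` or `diffuse`, implemented as Beta-distributed
radial positions) and rendered as 3-D Gaussian spots, truncated to the mask.
A diffuse cytoplasmic component rides underneath, since CellROX-style signal
is seen throughout the cell and not only in puncta. The recorded ground
truth `true_integrated_ros` is the noiseless ROS sum inside the mask, so the
conservation property holds by construction up to the 16-bit storage
rounding (half a count per voxel).

**Noise and storage.** Optional Poisson shot noise around signal +
background, additive Gaussian read noise, per-slice multiplicative
z-attenuation, and 16-bit unsigned storage clipped to [0, 65535] — the
standard confocal acquisition model. Defaults (puncta rate 30 per cell,
amplitude expectation 3000 counts with log-sd 0.5, background 150, read
noise 40, attenuation 0.97 per slice, 0.25 um pixels) were chosen once as
plausible confocal values; the source experiments' intensity statistics are
not published, so these are explicitly synthetic stand-ins. Effects follow
the reported qualitative pattern: the CBD multiplier defaults to 0.6 under
LPS and amyloid-beta and to 1.0 (null) under GP120.

What the generator does *not* emulate: photobleaching, a realistic PSF,
multi-cell fields, cell processes/ramification, or cell motion. Passing
tests on this generator therefore demonstrates the correctness and
statistical behaviour of the pipeline, not performance on real microscopy.

# Quantification

`segment_cell()` follows the only description available for the original
workflow — the actin signal "outlines" the cell — with a standard recipe:
Otsu threshold on the max-projected actin channel, morphological closing
(disc radius 2 px), largest connected component, hole filling. A fixed
threshold mode is provided for reproducibility studies. The resulting 2-D
footprint is replicated across slices as the measurement volume.

`measure_cell()` computes the five per-cell quantities with ImageJ
semantics: mean and max ROS intensity, the raw integrated density
(`raw_int_den`, the plain pixel sum), the footprint area in um², and the
integrated density (`int_den = mean x area_um2`). Sums, means and maxima are
taken over the 3-D masked voxel set (a flag-free design choice: the source
workflow reconstructs cells in 3-D but reports 2-D surface area), so
`raw_int_den = mean x n_voxels` always, and the 2-D identity
`raw_int_den = mean x area_px` holds exactly for single-slice masks — which
is how the identity is tested. Adding or changing pixels outside the mask
changes nothing.

`welch_test()` implements the unequal-variance two-sample t statistic with
Welch–Satterthwaite degrees of freedom and a two-tailed p-value, verified
against `stats::t.test` to 1e-10; `compare_groups()` applies it to each
condition's CBD-vs-control contrast. The degenerate all-equal case returns
p = 1 by convention. No multiple-testing correction is applied by default
(matching the per-measure reporting convention of the source analyses); a
Holm option exists.

# Preprocessing

Each z-stack slice becomes an independent training image (an 18-20-slice
stack yields a twenty-fold data increase). A slice then passes through:

1. **Min–max normalization** to 8 bits:
   `new = (old - min) / (max - min) * 255`, rounded half-to-even (R's
   `round()`), clipped to [0, 255]. A constant slice cannot be rescaled and
   becomes all zeros with a warning.
2. **Grayscale**: fluorescence channels are already single-channel; RGB
   inputs collapse by the 0.299/0.587/0.114 luminance weights.
3. **Area-interpolation resize** to 256 x 256: each output pixel is the
   exact area-weighted mean of the input region it covers (anti-aliasing by
   construction; block averaging for integer factors), re-rounded to 8 bits.
4. **Histogram equalization**:
   `out(v) = round((cdf(v) - cdf_min) / (N - cdf_min) * 255)` over the 256
   intensity bins. Re-equalizing an equalized image changes pixels only
   through rounding of an almost-linear CDF.

`split_dataset()` apportions slices 72/8/20 (train/validation/test) by
largest remainder, stratified by condition x treatment. The default grouping
keeps all slices of a cell in one partition (`by_cell`), preventing leakage
of near-identical sections of the same cell across train and test;
`by_slice` is retained because slice-level splitting is what a plain
TIFF-pool split does. Benchmarks in this package use `by_cell`, the
conservative choice.

# What survives this preprocessing — and the benchmark scene

Min–max normalization followed by histogram equalization is a *rank
transform*: it is invariant to any monotone per-image intensity map. A
treatment effect that only multiplies the ROS signal is therefore invisible
to the classifier except where the multiplication changes pixel *ordering* —
that is, where signal crosses the background noise floor or the 8-bit
quantization step. This is worth stating plainly because it governs what any
intensity-based classifier can learn from equalized fluorescence images.

`separable_scene()` is the package's benchmark scene, designed around this
fact. The cell fills a realistic fraction of a 128 um single-cell crop (so
its intensity levels carry histogram mass through equalization), the diffuse
cytoplasmic component sits about three noise standard deviations above
background, and puncta sit modestly above that. Halving the ROS signal
(multiplier 0.5) then visibly degrades the image: the cell body turns from a
smooth, solid region into a grainy one partially submerged in background
noise, and the dimmer puncta lose visible area. These are exactly the
signatures a halved CellROX signal shows on real detectors. Two further
geometry choices matter: slices are rendered natively at the classifier's
256-pixel grid, because downscaling averages away part of the noise
interactions that carry the class signal; and the cell spans the full
acquired z-range, so the end sections of a stack are not systematically
low-signal ambiguous images. On 400 slices from this scene (100 cells x 4
slices, 50 cells per class) the binary classifier reaches its accuracy
plateau within a few epochs; the package's acceptance benchmark trains
three seeds and reports median test accuracy at epochs 5 and 10.

# The classifier

Both tasks share one architecture, pinned by its shape chain on a 1 x 256 x
256 input: conv(8 filters, kernel 16) → ReLU → 5x5 max pool (stride 5) →
dropout 0.20 → conv(16 filters, kernel 5) → ReLU → 5x5 max pool → flatten →
1024 → 256 → 64 → n classes → softmax. Convolutions are unpadded with stride
1 and pooling uses floor division; `trace_shapes()` reproduces the defining
8x48x48 conv2 input and 1024-long flattened vector exactly, and any padding
would break them. The treatment head has 2 outputs, the condition head 3;
nothing else differs.

Choices the published description leaves open, fixed here as defaults:

* **Activation**: ReLU (standard for CNN classifiers; Grad-CAM's rectified
  weighting assumes ReLU-family activations).
* **Hidden linear widths**: 1024 → 256 → 64 → n (only the endpoints are
  pinned); configurable.
* **Dropout position**: dropout acts on the conv1 response grid and the
  5x5 max pooling is applied to the dropout layer. Besides being the
  literal reading of the architecture description, this order is much less
  noisy than dropping pooled outputs: a dropped unit is usually replaced in
  the pooled output by its window's runner-up, which matters for gradient
  quality over a short 10-epoch schedule.
* **Initialization**: convolution filters are random orthogonal sets
  scaled to the Kaiming magnitude (mutually non-redundant filters from any
  seed, which matters over a short schedule); hidden linear layers are
  Kaiming-normal; the final classification layer starts at zero so that
  early training is not dominated by random initial logits (with a small
  learning rate and a 10-epoch budget, random initial logits of the usual
  magnitude would otherwise compete with the learned signal). All biases
  start at zero.
* **Batch size 32**, reshuffled each epoch from the run seed.
* **Softmax at inference only**: training uses logits with cross-entropy,
  mathematically identical to a softmax layer plus cross-entropy and
  numerically standard.

Training uses cross-entropy optimized by Adam at learning rate 0.0001 for 10
epochs. The engine (im2col convolutions via single-precision BLAS, fused
conv/ReLU/pool kernels, explicit backward passes, Adam) lives in the package
itself; its gradients are verified against finite differences in the test
suite, and all randomness — initialization, shuffling, dropout masks — draws
from R's RNG so a run is a pure function of its seed. The best-validation
checkpoint is retained alongside the final epoch's parameters.

`evaluate()` reports test accuracy, a confusion matrix oriented with true
classes in rows and the negative class first (so the binary matrix reads TN,
FP / FN, TP with CBD positive), and ROC/AUC via pROC — one curve on the
positive-class probability for binary tasks, one-vs-rest with macro-average
AUC for the ternary task. `overfit_divergence()` summarizes the loss curves:
final and maximal validation-minus-train gap, plus a flag raised when
validation loss rises for three consecutive epochs while training loss
falls.

# Grad-CAM

`grad_cam()` backpropagates the pre-softmax logit of the explained class to
the post-ReLU activation maps of a convolutional layer (the last one by
default), weights each channel by the spatial mean of its gradient,
rectifies the weighted sum, bilinearly upsamples it to the input grid and
divides by the maximum. On a one-filter network with a positive head weight
this reduces to the activation map itself, which the tests verify against a
closed form. `edge_saliency_fraction()` turns the qualitative observation
that saliency concentrates at the cell edge into a number: the fraction of
saliency mass within a band (default 8 px, about 3% of the frame) around the
mask boundary, computed from the dilation-minus-erosion of the footprint.

# Problem sizes and numerical conventions

The test suite and the acceptance benchmark are scaled to run comfortably on
one CPU: unit tests use 48-96 px scenes with 3-6 slices; the repeated
-simulation power checks run 100 replicates of 80 cells per group at 48 px;
the classifier benchmark uses the 400-slice separable scene at 256 px with
three training seeds. Rounding
is half-to-even everywhere an 8-bit value is produced; Welch's test returns
p = 1 for identical degenerate groups; segmentation refuses images with no
component above threshold ("no cell found"); a constant slice normalizes to
zeros with a warning; an all-zero saliency map has edge fraction 0 by
convention.

# Known limitations

* The generator's realism gaps listed above; in particular real microglia
  show ramified processes whose geometry the ellipsoid-plus-harmonics model
  does not attempt.
* Measures are taken over a footprint cylinder, not a per-slice segmented
  volume; for strongly non-convex cells in z this overcounts background
  voxels.
* The classifier benchmark demonstrates the training recipe on synthetic
  data whose separability is designed; accuracy numbers do not transfer to
  real CellROX images.
* Checkpoints are stored as JSON text for portability, which is compact
  enough for this architecture (~284k parameters) but not for larger ones.
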