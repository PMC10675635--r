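---
title: "Multi-camera depth-image body condition scoring: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-camera depth-image body condition scoring: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Body condition scoring (BCS) grades a dairy cow's subcutaneous fat reserves
on a 1--5 scale in 0.25 steps. Trained scorers judge how skin wraps around
a handful of skeletal landmarks -- hook bones, pin bones, tail head,
spinous processes: an under-conditioned cow is angular, with protruding
bones; an over-conditioned cow is rounded. Automated scoring from
time-of-flight depth cameras makes the assessment frequent and consistent.
`bcsfusion` implements a complete multi-camera pipeline: three depth
cameras over a crush (angled, rear, top), per-camera image pre-processing
into three-channel stacks, sub-sampling augmentation, compact
convolutional classifiers, and early/mid/late fusion of the camera views,
evaluated with tolerance-band, class-weighted metrics. In a working herd
the class distribution concentrates heavily at BCS 2.50--3.00, so
cost-sensitive (inverse-frequency weighted) training is part of the core
method rather than an option.

Since no public multi-camera BCS depth dataset exists, the package ships a
first-class synthetic scene generator that reproduces the geometry and the
statistical structure such a pipeline must cope with; all tests and the
shipped benchmark run against it.

## Data model

A *depth frame* is an integer matrix of ranges in millimetres (424 x 512
by default, matching a Kinect-v2-class sensor), 0 reserved as the no-data
sentinel. Frames are stored as single-channel 16-bit grayscale
uncompressed TIFF -- lossless, integer-exact, and readable by any imaging
tool. A *manifest* (plain CSV: `cow_id, camera, frame_ref, bcs, split`,
plus `phase` after augmentation) indexes every frame; the cow, not the
frame, carries the label and the train/test assignment. Classification is
over the eight grid levels 1.75--3.50 actually observed in a milking herd;
the index mapping is `class = round((score - 1.75) / 0.25)`.

All array indexing in the package follows R's native convention: 1-based,
row-major presentation, origin at the top-left pixel.

## The synthetic scene

`generate_cow_surface()` models the cow back as the upper patch of an
ellipsoid (semi-axes 0.33/0.85/0.38 m, back line at 1.43 m) sampled as a
3-D point cloud. Condition enters purely geometrically, as displacement
along the surface normal:

* Gaussian bumps at the scoring landmarks (two hooks, two pins, tail head,
  a row of spinous processes along the spine);
* a broad *sunken loin* depression either side of the spine, giving thin
  cows the angular cross-section a scorer actually looks for -- and the
  only condition cue a rear camera can see at fine granularity;
* a low-frequency "flesh unevenness" field.

Every term scales with one number, the bone amplitude
`bone_amplitude_mm(score) = 70 - 36 * (score - 1.75)` mm (70 mm for an
emaciated 1.75 down to 7 mm at 3.50). The map is linear and strictly
decreasing; its endpoints were fixed once, by simulation before the
classifier work, so that the within-cow gradient statistic separates
classes monotonically with a margin above Monte-Carlo noise at the
benchmark's pixel pitch -- a signal that is learnable but far from
trivial, as the benchmark accuracies show. With amplitude 0 the surface is
exactly the smooth ellipsoid, which the tests exploit as a closed-form
oracle. Per-cow nuisance variation: body scale ~ N(1, 0.04) truncated to
[0.92, 1.08], per-landmark amplitude jitter (sd 8%), and per-frame pose
jitter (lateral/longitudinal shifts sd 30/50 mm, yaw sd 3 degrees).

`render_depth()` is an orthographic point-splatting z-buffer: scene points
project along the camera's forward axis onto the sensor raster, each pixel
keeps the nearest range, quantised to integer millimetres, with additive
Gaussian noise (default sd 5 mm, truncated at zero) on covered pixels.
The background -- pen floor, crush bars, a back wall -- is rendered
behind the cow; ranges beyond the far clip are kept at their true value,
because removing background is the *pre-processing* stage's job, exactly
as with a real sensor. Pixels no geometry covers are 0. The default poses
put the top camera 3 m above the floor, the rear camera 3 m behind the
cow at 1.6 m height tilted ~8.5 degrees down at the rump (a flat rear
view measures almost nothing: the rump's relief is parallel to a
horizontal optical axis), and the angled camera on a 45-degree diagonal
at the rear quarter.

What the generator does *not* emulate: legs, udder and tail, fur or
radiometric effects, multipath/self-shadowing artifacts, gait, and real
anatomical diversity beyond the parametric jitter above. Passing tests on
synthetic herds therefore demonstrate that the pipeline machinery is
correct and that the models can extract a condition signal of realistic
geometry from realistic imbalance -- not that the shipped weights
transfer to a real barn.

## Pre-processing and channels

Per camera, in order (`build_channel_stack()`):

1. **Distance limiting** -- every pixel beyond a camera-specific threshold
   is zeroed (background suppression without background subtraction, which
   fails when the cow occludes the background). Residual clutter is left
   for the models to learn to ignore.
2. **Cropping** -- a fixed per-camera window over the informative region;
   square for the angled view, taller than wide for the rear, wider than
   tall for the top.
3. **Channels** -- (i) depth normalised by the distance threshold, hence
   in [0, 1]; (ii) a binary silhouette: 1 strictly below the binarize
   threshold, 0 at or beyond it, and 0 for the no-data sentinel (a literal
   reading would paint removed background as cow); (iii) the left-to-right
   first derivative in mm per pixel step, first column zero-padded, with
   any magnitude above the gradient cap set to 0 -- the cap removes object
   edges (hundreds of mm) while keeping surface relief. The comparison is
   on absolute value: large negative spikes are edge artifacts too. The
   derivative is computed on raw millimetres, before any normalisation, so
   its units stay physical.

Thresholds and crops are configuration, not constants; the defaults are
matched to the synthetic geometry (the analogous values for a real rig
were experimentally determined in the field and are rig-specific).

At network-input assembly (not in the stack contract) two conditioning
steps are applied: the derivative plane is divided by the gradient cap,
and the depth plane is mean-centred over covered pixels and rescaled
(factor 8). Without them, the derivative plane's raw scale and the large
cow-to-background step dominate the early convolutions and the millimetre
relief that actually encodes condition is invisible; mean-centring also
cancels the global range shift caused by where the cow happens to stand.

## Augmentation and splitting

Factor-2 phase sub-sampling (`subsample_phases()`) takes every second
pixel across and down at the four (row, column) phase offsets, producing
four half-resolution images with slightly different information; for even
shapes the four interleave back to the original exactly, which is tested.
Flips and rotations are deliberately absent: an angled view is asymmetric
and background removal is imperfect. Augmentation runs after channel
construction, plane-wise, so all four phase images inherit one label.

Dataset assembly enforces three rules: at most 7 frames per cow and
camera (the temporally middle ones); a cow-level 70/30 split --
`round(0.3 * n)` cows to TEST, optionally stratified by class, so no
individual leaks across the boundary; and exactly one pre-augmentation
test frame per cow and camera (a seeded draw), so a slow cow cannot be
scored repeatedly. With augmentation each test cow contributes exactly 4
samples per camera set.

## Models and training

The backbone is a compact CNN, identical per camera up to input shape:
three blocks of conv 3x3 (same padding, ReLU) + max-pool 2x2 with 16, 32
and 64 filters, flatten, dense 64 (ReLU), dense 8 + softmax. The three
fusion assemblies (`build_model()`):

* **EARLY** -- the per-camera stacks are resampled (nearest-neighbour) to
  the smallest selected crop and concatenated into one 9-channel input for
  a single backbone;
* **MID** -- one conv trunk per camera; the flattened features are
  concatenated into a shared dense head;
* **LATE** -- one complete classifier per camera; predictions are fused by
  `ensemble_average()`, the equal-weight element-wise mean of the softmax
  vectors, argmax with lowest-index tie-break. With one member it reduces
  to that member exactly. Averaging the members' numeric BCS values
  instead of their probability vectors is available behind
  `predict(..., fuse = "score")`.

Training minimises class-weighted cross-entropy: weights
`w_c = (N/K) / n_c` over the K non-empty classes, so `sum(w_c n_c) = N`
and every class contributes equal total weight -- the cost-sensitive
correction for the 2.50--3.00 concentration. The optimiser is Adam at
learning rate 0.001, batch size 32 (8 and 16 behave comparably), seeded
shuffling and He-normal initialisation, everything derived from one run
seed so runs are bit-reproducible on a fixed BLAS. Small models on small
data overfit quickly, so the retained checkpoint is the epoch with the
lowest validation loss from epoch 5 onward, the band where these models
peak; validation is a held-out 15% of *training cows* (again cow-level).
The engine itself (im2col convolutions, pooling with first-maximum
gradient routing, dense layers, Adam) is written in R on BLAS matrix
products; its gradients are verified against finite differences in the
test suite, and `model_stats()` reports exact trainable-parameter counts
and a 2-multiply-add FLOP estimate per weight application.

## Evaluation

Accuracy is reported in three tolerance bands -- exact, within 0.25 BCS
(one grid step), within 0.5 BCS (two steps) -- the conventional
human-error ranges. Banding is applied by *relabelling*: a prediction
inside the band is scored as the true class, one outside is left as is.
Under this convention the class-weighted recall of a band equals the band
accuracy, an identity the tests assert on random inputs and on the
published table values the package reproduces. Per class,
`precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
`F1 = 2PR/(P+R)`, as percentages, with a zero denominator scoring 0 (the
convention visible in published tables for near-empty edge classes);
class-weighted summaries use `W_c = n_c / N`. Reported percentages are
rounded half-up to 2 decimals. `evaluate_camera_sets()` scores the three
single cameras, the three pairs and the full ensemble from one set of
member probabilities, producing the standard seven-row table
(A, R, T, A&R, A&T, T&R, All). No significance testing is attached; the
method's literature reports none.

## The shipped benchmark

`run_benchmark(benchmark_config())` is the package's reference experiment,
sized for minutes on one CPU: 300 synthetic cows, a quarter-pitch sensor
(106 x 128, 28 mm/pixel), 32 x 32 crops (16 x 16 network inputs after
sub-sampling), 5--7 frames per cow and camera, the default herd class
mix, late fusion over all three cameras, 25 epochs. It reports the seven-row
accuracy table, per-camera exact accuracies and the majority-class
baseline (the exact-band accuracy of always predicting the most frequent
training class) that any informative model must beat. The acceptance
script re-runs exactly this under the caller's seed.

## Numerical and degenerate-input choices

* Binarize tie: a pixel exactly at the threshold is "far", hence 0.
* Derivative of a width-1 frame is a geometry error; the first output
  column is always 0 by padding.
* `distance_limit` is idempotent; applying it twice is tested to equal
  once.
* Probability vectors must sum to 1 within 1e-6 before fusion; fused
  argmax ties break to the lowest class index.
* Depth writing rejects values above 65535 mm; rendering clamps there.
* An all-zero frame propagates to an all-zero channel stack.
* Class weights with an all-zero count vector, empty camera sets, empty
  prediction sets, out-of-bounds crops and off-grid labels are errors,
  not silent repairs.

## Known limitations

* The synthetic scene is geometric, not photometric; domain transfer to
  real sensors is out of scope.
* The backbone is a generic small CNN; published parameter counts for
  field systems depend on unpublished layer dimensions, so
  `model_stats()` makes this package's counts explicit instead of
  matching any external number.
* Orthographic projection slightly understates perspective foreshortening
  at the scene scale.
* The rear view remains the least informative camera; its usefulness
  depends on mounting height and tilt.
* Training determinism holds for a fixed BLAS/threading configuration;
  across numerics libraries bit-identity is not guaranteed.
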