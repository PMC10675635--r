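# bcsfusion

Automated dairy-cow **body condition scoring (BCS)** from multi-view
time-of-flight depth cameras, in R.

Body condition scoring grades a cow's subcutaneous fat reserves on the
five-point scale (1–5 in 0.25 steps). Scorers look at a few skeletal
landmarks — hook bones, pin bones, tail head, spinous processes — and
judge whether the animal is angular (under-conditioned) or rounded
(over-conditioned). Regular, consistent scoring matters for milk yield and
herd health, which is why farms automate it with depth cameras.
`bcsfusion` implements a complete multi-camera pipeline of that kind and a
synthetic depth-scene generator to drive it, aimed at researchers in
precision-livestock imaging who want a tested, reproducible reference
implementation:

* **depth I/O** — integer-millimetre depth frames (424 × 512,
  Kinect-v2-like) as lossless 16-bit grayscale TIFF, plus plain-CSV
  dataset manifests keyed by cow;
* **synthetic scenes** — a parametric cow back (ellipsoid patch with
  condition-dependent bone bumps and a sunken-loin depression,
  `amplitude = 70 − 36·(BCS − 1.75)` mm) rendered by an orthographic
  z-buffer from three camera poses (angled, rear, top) over a pen floor
  and crush bars, with Gaussian depth noise;
* **pre-processing** — per-camera distance limiting, fixed crops, and the
  three CNN input channels: normalised depth, binary silhouette, and the
  left-to-right first derivative with a gradient cap;
* **augmentation & splitting** — factor-2 phase sub-sampling (4
  half-resolution images per frame), a 7-frame-per-cow cap, leakage-free
  cow-level 70/30 splitting, and one test frame per cow and camera;
* **models** — a compact CNN backbone (3 × [conv 3×3 + maxpool], 16/32/64
  filters, dense 64, softmax over 8 classes) with early (stacked
  channels), mid (concatenated features) and late (ensemble-averaged
  softmax) fusion, trained with class-weighted cross-entropy
  (`w_c ∝ 1/n_c`, the cost-sensitive correction for the herd's 2.50–3.00
  concentration) and Adam; the engine is pure R over BLAS, with gradients
  verified against finite differences;
* **evaluation** — tolerance-band metrics (exact, ±0.25, ±0.5 BCS) by
  relabelling, per-class and class-weighted precision/recall/F1
  (`P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`,
  `W_c = n_c/N`), and the standard seven-row camera-set comparison
  (A, R, T, A&R, A&T, T&R, All).

## Worked example

The shipped reference experiment simulates a 300-cow herd, prepares the
samples, trains the three-camera late-fusion model and scores every
camera subset:

```r
library(bcsfusion)
res <- run_benchmark(benchmark_config(n_cows = 300, seed = 1))
res$accuracy_table
#>   approach exact within_0.25 within_0.5
#> 1        A 35.00       75.28      95.28
#> 2        R 37.78       84.17      97.78
#> 3        T 42.22       90.00      99.17
#> 4      A&R 43.33       84.44      97.50
#> 5      A&T 46.67       91.39      98.33
#> 6      T&R 48.61       91.94      98.89
#> 7      All 51.11       91.94      98.89
round(res$baseline_exact, 2)
#> [1] 26.67
```

Reading the table: each row is one camera set (A = angled, R = rear,
T = top, pairs, and all three fused); columns are the percentage of test
samples scored correctly at exact, ±0.25 and ±0.5 BCS tolerance. Every
single-camera model clearly beats the 26.67 % majority-class baseline
(always predicting the most common training class), and fusing cameras
raises exact-band accuracy further — the central claim a multi-camera rig
rests on. Accuracy grows with the tolerance band by construction.

Smaller pieces work standalone, e.g.:

```r
f1_score(23.08, 27.27)            # 25.0 — F1 from a precision/recall pair
class_weights(c(10, 30))          # 2.0 0.667 — inverse-frequency weights
ph <- subsample_phases(matrix(0:15, 4, 4, byrow = TRUE))
length(ph)                        # 4 phase images per frame
```

A thin command-line wrapper over the same functions lives at
`inst/scripts/bcsfusion.R`
(`simulate` / `prepare` / `train` / `evaluate` subcommands, YAML config).

## Limitations

The generator is geometric, not photometric: it establishes that the
pipeline is correct and that its models extract a realistic condition
signal under realistic class imbalance, not that trained weights transfer
to a physical barn. See the methods vignette
(`vignettes/bcsfusion-methods.Rmd`) for the full model description,
parameter rationale and design decisions.
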