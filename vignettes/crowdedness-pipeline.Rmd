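---
title: "Measuring hospital crowdedness from surveillance imagery and visit records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring hospital crowdedness from surveillance imagery and visit records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edcrowd)
```

`edcrowd` turns two routine data sources of an emergency department —
surveillance video frames and visit records — into quantitative
crowdedness measurements. This vignette is the package's methods account:
the models, their assumptions, the parameters that matter, the numerical
choices, and what the synthetic data used by the test suite does and does
not establish.

## 1. From head annotations to density maps

A waiting-area frame is annotated with one point per visible head
(0-based pixel coordinates, `x` = column, `y` = row). The annotation grid
has value 1 at each head pixel (coincident heads accumulate additively —
required for the count to be conserved) and 0 elsewhere. The ground-truth
density map filters that grid with a truncated Gaussian kernel, by
default 15 px wide with σ = 4 px, chosen to spread each head's unit mass
over roughly a head-sized neighbourhood. The defining invariant is

> total pixel value of the density map = number of annotated people.

Plain convolution violates this at image borders: a head near a corner
loses up to three quarters of its kernel mass outside the frame. Each
head's clipped kernel is therefore renormalised to unit mass, which makes
mass conservation exact for *every* annotation set; in the interior (at
least 7 px from every edge) the per-head construction and plain filtering
of the annotation grid coincide, and the test suite checks both the
equivalence and the corner behaviour against a brute-force oracle.

## 2. The counting network

`mfcnn()` regresses the density map from the image with a fully
convolutional encoder–decoder:

* an **input block** of two stride-2 convolutions condenses each spatial
  dimension to a quarter (set `input_reduction = 2` for the
  quarter-*area* reading; the per-dimension reading is the default as the
  conventional one);
* **four downsampling stages** of residual bottleneck blocks
  (1×1 reduce, 3×3 transform, 1×1 expand, identity shortcut), each stage
  halving the spatial size; deeper stages contain more blocks
  (default schedule 1–2–3–4, the smallest non-decreasing one), with stage
  widths doubling from `base_width` (default 32);
* a **decoder** that upsamples the deep maps (nearest-neighbour, to the
  exact size of the lateral map so odd sizes round-trip) and fuses them
  by addition with 1×1-projected shallower encoder maps, U-Net style;
* a **fine-grained regressor** that cuts the fused quarter-resolution
  map into `strip_count` horizontal and, independently, vertical strips
  (zero-padded to divide evenly, cropped after splicing), passes each
  strip through a bottleneck block whose parameters are shared within a
  dimension (so the parameter count is independent of `strip_count`),
  splices the strips back, and adds the width- and height-enhanced maps;
* a **regression head** with no fully connected layer: global average
  pooling followed by a 1×1 convolution forms a sigmoid channel gate
  (the natural fully-convolutional reading of "GAP + convolution replaces
  the dense layer"), a 1×1 convolution emits a one-channel coarse map,
  which is enlarged to the input size and refined by a 3×3 convolution
  with dilation 2. A dilated convolution cannot itself change spatial
  size, so enlargement is implemented as interpolate-then-refine. A final
  rectifier enforces a non-negative map.

The network is fully convolutional, so any input of at least 64×64 px is
accepted and the output map always has the input's size. The predicted
count is the map's total mass.

### Training

The loss is the field-standard pixel-wise squared error between predicted
and ground-truth density maps; the protocol defaults are batch size 8,
Adam at a fixed learning rate of 10⁻⁵, 50 epochs. Every epoch records the
training loss and validation MCE/RMSE, and the returned weights are those
of the epoch with the lowest validation MCE (training MCE when no
validation split is requested). All randomness — initialisation (He
normal), the validation split, batch shuffling — flows from explicit
seeds, and training is bit-reproducible on one machine.

One numerical choice deserves emphasis: **ground-truth magnification**
(`output_scale`, default 100). Density values peak near 1/(2πσ²) ≈ 0.01,
deep inside the final rectifier's dead zone, where the one-sided clipping
of background pixels biases counts upward and gradients are poorly
scaled. The network therefore regresses `output_scale ×` the density map
and predictions are divided back down; counts are unaffected. With
magnification the memorisation check (20 scenes, ≤ 300 epochs at learning
rate 10⁻⁴) reaches a training MCE well below one person; without it the
same budget stalls around 1.5–3.

Since no deep-learning framework is available to R in this stack — and
the network is the package's own contribution — the convolution
forward/backward kernels are implemented in C++ (im2col + BLAS matrix
products via RcppArmadillo) under a small reverse-mode tape in R. The
tape's gradients are verified against finite differences in the test
suite.

## 3. The sampling design

The surveillance plan is: one 60-second video every 30 minutes, frames at
0.2 fps, capped at 10 frames per video (offsets 0, 5, …, 45 s; the cap is
explicit because 60 s at 0.2 fps would admit 12 grid points). Bounded
operating hours include both endpoints — an 8:00–18:00 area samples 21
videos/day, the only convention consistent with a 10-hour window — while
a 24-hour area samples 48, since 24:00 coincides with the next day's
0:00. Two round-the-clock areas and three 10-hour areas over 7 days give
1113 videos and 11,130 frames.

Per-slot counts are the arithmetic mean over a video's frames, stored
exact; rounding (half-up, configurable digits) happens only when a report
is written. Count tables always recompute their daily/weekly margins from
the cells rather than trusting input margins.

## 4. Unit congestion rate

Following Hall's proxemics, each waiting person psychologically claims a
disc of personal distance d = 1.2 m (a parameter, not a constant), so an
area of A m² holds `N_theoretical = A/(π d²)` people before discomfort,
and the unit congestion rate is `R_c = N_actual/N_theoretical` —
dimensionless, linear in occupancy, and invariant under consistent unit
changes.

`congestion_report()` averages occupancy over *operating-hour slots
only*: a 10-hour area's weekly mean divides its person-time total by
21 × 7 = 147 slots. "Fitting" the within-day congestion curve is
implemented as a centred moving average (default window 3 slots, window 1
= identity), since no specific fitting method is prescribed by the
procedure the package implements; the per-process and day-over-day
cross-sections are plain re-orderings of the same per-slot rates.

The packaged planning table (`ed_area_specs()`) prints 2-dp-*truncated*
capacities (e.g. 115.02 m² → 25.4250 printed as 25.42); the package
always computes full precision and the tests compare at the printed
precision. One column of that table (internal medicine and surgery) is
internally inconsistent — 66.78 m² gives 14.76 by the formula, not the
printed 17.76 — and the package deliberately reproduces the formula, not
the printed cell.

## 5. Visit-time statistics

From each record's milestones, both anchored at the earliest receipt
("pickup") time:

* **T2**, diagnosis time = earliest diagnosis − receipt;
* **T1**, the post-diagnosis visit-time measure = earliest dispensing
  (fallback: earliest payment) − receipt.

Dispensing is preferred as the later patient-journey milestone; the
preference is a `group_scheme()` switch because the rule is genuinely
underdetermined. Whether "time after diagnosis" should instead be
T1 − T2 is equally underdetermined, so `compute_durations()` returns
`t1_post = T1 - T2` alongside, with T1-as-anchored primary. A record is
unusable when a needed milestone is missing or a duration is negative;
missingness is a state, never an error.

Age bands are half-open (`[6,12)`, `[12,20)`, …), resolving the
overlapping printed band edges by assigning age 12 to the adolescent
band; every non-negative age maps to exactly one band. Group comparisons
use a two-sample t-test for 2 groups; for more, one-way ANOVA when every
group passes Shapiro–Wilk normality and Levene's test (mean-centred, the
SPSS convention) finds homogeneous variances, both at α = 0.05, else
Kruskal–Wallis. The gates are named explicitly because the procedure
being reproduced states the conditions but not the tests. Raw p-values
are reported per factor (no multiplicity correction, matching the
reporting convention); `adjust = "bonferroni"` is available.

## 6. What the synthetic data is — and is not

The generator exists so that every downstream stage is testable with no
external data:

* **Scenes** are textured backgrounds with elliptical head-like blobs
  (radii 4–12 px, randomised intensity, mild overlap); annotations are
  the exact blob centres. They exercise counting, not appearance realism:
  no perspective scaling, occlusion by furniture, lighting changes or
  camera noise. A model that counts blobs has been shown to optimise the
  density objective, not to count real patients.
* **Daily profiles** are base-plus-Gaussian-bump expectations on the
  half-hour grid (morning/evening peaks), with slot counts drawn Poisson
  and at most ±1 person of within-video jitter, reflecting the
  near-stationary waiting crowds of one-minute videos.
* **Visit records** carry planted effects in SD units (defaults: older →
  longer diagnosis, age_t2 = 0.5; younger → longer after diagnosis,
  age_t1 = −0.3; more diagnoses → longer after diagnosis, ndiag_t1 =
  0.5), a cohort structure matching the surveyed one (4717 records, 22.1%
  with a missing milestone, two-thirds children, 54.3% respiratory), and
  missing-completely-at-random milestone deletion — the real missingness
  mechanism is unknown, so MCAR is the explicit, simplest choice.
  Baselines are 25 min diagnosis time, 60 min post-diagnosis time,
  residual SD 15 min — plausible emergency-department magnitudes chosen
  once.

All generators take one explicit seed per call and restore the caller's
RNG state.

## 7. Problem sizes and numerical choices in the test suite

The suite runs at desk scale, chosen so the full run stays in minutes on
one CPU: 64×64 scenes with 0–8 heads; the memorisation check trains the
default network on 20 scenes for 150 epochs at learning rate 10⁻⁴
(reaching MCE < 1 within ~2 min); metric identities are checked on 1000
random batches; type-I error uses 200 null replicates of 200 records
(accepted within three binomial standard errors of 0.05) and power uses
100 replicates of 600 records with a 0.5-SD planted age trend (≥ 80%
rejections). Gradient checks compare the tape against finite differences
at step 10⁻⁵. Degenerate inputs are contracts, not crashes: empty
batches, empty hours, zero-head scenes, strip counts exceeding the
feature extent and out-of-bounds annotations all raise a typed
invalid-argument error naming the offence.

## 8. Known limitations

* The counting network is validated on synthetic blob scenes; performance
  numbers on real surveillance imagery (and against pretrained baselines)
  require annotated hospital frames and external benchmark data, which
  this package deliberately does not ship.
* Nearest-neighbour decoder upsampling is the only interpolation
  implemented; bilinear would smooth block edges but adds nothing to the
  contracts tested here.
* The congestion rate models standing crowds via personal space only; it
  ignores seats (reported but unused) and any queueing dynamics.
* Visit-time tests are association tests on raw p-values; nothing causal
  follows, and the T1 anchoring ambiguity (Section 5) should be kept in
  mind when comparing T1 effects across studies.
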