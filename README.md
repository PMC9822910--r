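# edcrowd

Measuring how crowded a hospital really is, from the data hospitals
already have: surveillance cameras and visit records. `edcrowd` implements
an image-based occupancy pipeline for emergency-department waiting areas —
density-map crowd counting with a multi-fusion encoder–decoder network, a
half-hourly frame-sampling design, a proxemics-based *unit congestion
rate*, and post-hoc visit-time statistics — together with a synthetic
scene and record generator so the whole pipeline runs and is tested
without any hospital data.

It is aimed at health-services researchers and hospital-operations
analysts who want quantitative, reproducible crowdedness measurements
rather than staff impressions.

## The methods in brief

**Counting.** Each head in a frame is a point annotation; filtering the
annotation grid with a truncated Gaussian kernel (size 15, σ = 4, per-head
renormalised at borders) gives a density map whose total mass *is* the
head count. A fully convolutional encoder–decoder (`mfcnn()`) regresses
that map from the image; the predicted count is the map's total. Accuracy
over R images is summarised by

    MCE  = (1/R) Σ |C_gt − C_pred|
    RMSE = sqrt( (1/R) Σ (C_gt − C_pred)² )

**Sampling.** Every half hour a one-minute video is taken per area; frames
are extracted at 0.2 fps, ten per video. A 24-hour area yields 48 videos a
day, an 8:00–18:00 area 21; per-slot counts are the mean over the ten
frames, assembled into an areas-by-time table with recomputed margins.

**Congestion.** From Hall's personal distance d = 1.2 m, an area of A m²
comfortably holds

    N_theoretical = A / (π d²)

people, and the unit congestion rate is `R_c = N_actual / N_theoretical`.
R_c > 1 means the waiting crowd is packed beyond the personal-space
comfort limit.

**Visit times.** From each record's milestone timestamps: T2 (diagnosis
time) = earliest diagnosis − receipt; T1 (visit time after diagnosis
measure) = dispensing (or payment) − receipt. Group differences in T1/T2
across sex, age band, diagnosis count and disease type are tested with a
t-test (2 groups) or, for more groups, ANOVA when Shapiro–Wilk normality
and Levene homogeneity both hold and Kruskal–Wallis otherwise, at
α = 0.05.

## Worked example

```r
library(edcrowd)

# paediatric waiting area: 67.14 m^2, mean 40.75 people waiting
cap <- theoretical_capacity(67.14)
cap
#> Theoretical capacity: 14.84 people (area 67.14, d = 1.20)
congestion_rate(40.75, cap)
#> [1] 2.745735
```

A congestion rate of 2.75: the paediatric crowd sits at almost three times
the personal-space comfort capacity, while the pharmacy (110.24 m², mean
3.82 waiting) idles at 0.16 — the two ends of the resource-allocation
problem.

Train the counting network on synthetic scenes and count an unseen frame:

```r
scenes <- lapply(1:12, function(i) generate_scene(i %% 6, seed = i))
fit <- mfcnn(scenes, network = network_config(seed = 1),
             training = training_config(epochs = 60, learning_rate = 1e-4,
                                        val_fraction = 0, seed = 1))
fit
#> Multi-fusion counting network
#>   base width 32, blocks 1-2-3-4, strip count 4
#>   trained 60 epoch(s), best epoch 60 (MCE 0.6847)
predict(fit, scenes[[3]])
#> Density prediction: 64x64 map, count 2.540   (true count: 3)
evaluate_model(fit, scenes)[c("mce", "rmse")]
#> $mce  0.6847  $rmse  0.8600
```

(~20 s on one CPU; the counts are the density-map masses, reported
un-rounded.)

A shell front end wraps the same functions:

```sh
Rscript inst/cli/edcrowd schedule
#> 1113 videos / 11130 frames over one week
Rscript inst/cli/edcrowd full-demo --out demo --seed 7
```

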