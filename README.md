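# gaitseg

Stride segmentation, stride/non-stride classification and gait-event
detection for six-axis inertial recordings from foot-worn sensors, plus a
multi-annotator toolkit for quantifying how much human gait labelers disagree
with each other.

The package is aimed at movement scientists and engineers who work with
instrumented-shoe or foot-mounted IMU data (100 Hz accelerometer + gyroscope)
and need to turn long, messy recordings — walking mixed with stomping,
jumping, turning and rest — into per-stride gait events they can trust, while
keeping an honest error bar derived from inter-rater agreement.

## The method

The pipeline is a two-stage design: find candidate strides first, then look
for events only inside accepted candidates, so a detection error can never
leak outside its own stride.

1. **Region-of-motion (ROM) segmentation.** The angular-rate magnitude
   `ω_a[k] = sqrt(ω_x² + ω_y² + ω_z²)` is low-pass filtered (zero-phase
   Butterworth, order 4, 10 Hz) and thresholded at
   `τ = max(30 deg/s, 0.2 × rolling 95th percentile)`; active runs are
   merged, padded and duration-gated into disjoint candidate regions.
2. **Feature extraction.** Each ROM is summarised as `F = {M, c}`:
   `M ∈ [0,1]^{100×6}` is the per-channel min-max normalized,
   Fourier-resampled signal image, and `c ∈ ℝ^19` is
   `(Δt, 1/d_1, r_1, p̂_1, …, 1/d_6, r_6, p̂_6)` where `d_i` is the
   path-length-normalized DTW distance of channel `i` against a 100 × 6
   stride template `T` (the mean of resampled training strides), `r_i` and
   `p_i` the Pearson correlation of the warped channel with the template
   column, and `p̂_i = 0.1 · log p_i`.
3. **stepperNet.** A small CNN: three 10 × 6 kernels at step 1 over `M`
   (feature maps 91 × 1 × 3), 3 × 1 max pooling (30 × 1 × 3), concatenation
   (90) joined with `c` (109), dense ReLU layers of 30 and 15 units, softmax
   over 2 classes. Trained by per-example SGD (7 epochs, learning rate 0.015,
   momentum 0.75) restarted from 10 random initializations; the restart with
   the best held-out accuracy is kept. A ROM is a stride iff the stride
   probability exceeds 0.5.
4. **Gait-event rules** inside each accepted stride: heel off (HO) and flat
   foot (FF) are the first and last sample with `ω_a[k]/σ_ωa > 0.5`; heel
   strike (HS) is the most prominent local maximum of `dȧ_z/dt` after HO; toe
   off (TO) is the first zero crossing of `a_x − a_z` between HO and HS.
5. **Label condensation and limits of agreement.** Event-timestamp sequences
   from N labelers are matched pairwise with a Needleman–Wunsch alignment
   (match cost `|x_i − y_j|`, gap cost = mean inter-label interval of the
   first sequence), iteratively discarding labels gapped in any pairwise
   alignment until all sequences correspond 1:1. From the matched matrix
   `L ∈ ℝ^{M×N}`, row means `l̄` give consensus labels, `D[:,i] = l̄ − L[:,i]`
   the per-labeler errors, and the limit of agreement (LOA) is the 95th
   percentile of `|D|`.

Everything runs on synthetic data out of the box: the built-in generator
produces treadmill-like stride waveforms with known (gold) event times,
non-stride motion archetypes, and noisy multi-labeler annotations.

## Worked example

```r
library(gaitseg)

# train a classifier on a balanced synthetic corpus
corpus <- synthetic_feature_corpus(400, seed = 2024)
model  <- stepper_train(corpus$features, corpus$labels, train_config(seed = 2024))
model
#> <stepper_net> held-out accuracy 1.000 over 10 restart(s); final loss 0.0003801

# run the full pipeline on a fresh recording: 12 strides + 5 non-stride bursts
sim <- simulate_recording(n_strides = 12, n_nonstride = 5, seed = 99)
res <- run_pipeline(sim$recording, corpus$template, model)
length(res$strides); nrow(res$rejected)
#> 12 strides accepted, 5 candidates rejected (17 ROMs found)
res$strides[[1]]$events
#> <gait_events> HO 2.880  TO 3.010  HS 3.400  FF 3.690 s

# compare detected events with the generator's gold annotations
ann <- pipeline_annotations(res)
error_metrics(sort(ann$t[ann$event == "HS"]),
              sort(sim$event_table$t[sim$event_table$event == "HS"]))
#> <error_metrics> mean 0.0  std 0.0  MAE 0.0  RMSE 0.0  LOA 0.0 ms (n = 12)

# inter-labeler agreement: 5 simulated labelers, 10 ms timing jitter
gold <- cumsum(rep(1.1, 400))
seqs <- simulate_labelers(gold, labeler_noise(jitter_sd = 10),
                          n_labelers = 5, seed = 7)
condense_labels(lapply(seqs, `*`, 1000))        # work in milliseconds
#> <label_matrix> 381 matched labels x 5 labelers, 90 removed (4.51%), LOA 18
```

The pipeline recovers all 12 strides, rejects all 5 non-stride bursts, and
on this low-noise corpus every detected event lands on the gold sample (MAE
0 ms). The labeler simulation shows the LOA estimator at work: with 10 ms
i.i.d. jitter over 5 labelers the expected LOA is
`1.96 · 10 · sqrt(1 − 1/5) ≈ 17.5 ms`, and the empirical value is 18 ms.

A command-line front end wrapping the same functions (subcommands
`simulate`, `segment`, `extract-features`, `train`, `classify`,
`detect-events`, `condense`, `loa`, `evaluate`, `run`) is installed at
`system.file("cli/gaitseg.R", package = "gaitseg")`.

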