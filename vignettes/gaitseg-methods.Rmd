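---
title: "Stride segmentation and gait-event detection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stride segmentation and gait-event detection: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitseg)
```

This vignette is the package's own account of the science it implements: the
models and rules, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the choices made where the design
was genuinely open.

## 1. Problem and pipeline

Foot-worn IMUs record walking as six channels at 100 Hz: accelerations
$a_x, a_y, a_z$ (m/s²; $x$ heel-to-toe, $z$ sole-normal up) and angular
rates $\omega_x, \omega_y, \omega_z$ (deg/s). Long free-living recordings
mix strides with rest and with non-stride motion (stomping, jumping,
shuffling). The pipeline therefore works in two stages: *first* isolate
candidate strides, *then* look for gait events only inside candidates that a
classifier accepts. The payoff is fault isolation — a bad candidate can only
lose itself, never corrupt the neighbouring strides — which the test suite
asserts literally (corrupting one region leaves every other stride's output
bitwise unchanged).

The four events per stride are heel off (HO), toe off (TO), heel strike
(HS) and flat foot (FF), in that order; TO→HS is the swing phase.

## 2. Region-of-motion segmentation

The activity signal is the angular-rate magnitude
$\omega_a[k] = \sqrt{\omega_x[k]^2 + \omega_y[k]^2 + \omega_z[k]^2}$,
low-pass filtered with a zero-phase Butterworth filter. A sample is active
when the filtered activity exceeds a dynamic threshold; active runs are
merged across short gaps, padded, and duration-gated.

| parameter | default | unit | why |
|---|---|---|---|
| `lowpass_cutoff` | 10 | Hz | walking energy is essentially below 10 Hz; zero-phase filtering avoids shifting event times |
| `lowpass_order` | 4 | – | standard slope/ripple compromise |
| `threshold_fraction` | 0.2 | – | threshold adapts to gait intensity: 20% of the rolling 95th percentile of activity |
| `threshold_floor` | 30 | deg/s | rejects gyroscope noise at rest, where the percentile is meaningless |
| `merge_gap` | 0.1 | s | mid-stance dips shorter than this stay inside one candidate |
| `margin` | 0.05 | s | covers the edge smear the low-pass filter introduces, so HO and FF stay inside the region |
| `min_duration`, `max_duration` | 0.2, 3.0 | s | wide enough for slow pathological strides, tight enough to drop drift |

The rolling 95th percentile uses a centered 5 s window, evaluated on a
coarse grid and linearly interpolated — a deterministic approximation that
keeps segmentation O(n). Raising `threshold_fraction` can only shrink the
active set; because merged regions are only padded by `margin` on each side
and any region split removes at least the inactive gap, total ROM duration
is monotone non-increasing in the threshold (tested).

## 3. Features: signal image and similarity scores

Each region is summarised as $F = \{\mathbf M, \mathbf c\}$.

$\mathbf M \in [0,1]^{100\times 6}$: each raw channel is min-max normalized
and resampled to 100 samples by Fourier (DFT-domain) interpolation. The
resampling is exact for band-limited signals and is built with explicit
conjugate symmetry so real input gives real output; Gibbs ringing can leave
$[0,1]$ by a few ULPs, which is clipped. A constant channel has no range to
normalize; it becomes all zeros with a warning rather than NaN so the
classifier input stays finite.

$\mathbf c \in \mathbb R^{19}$ is
$(\Delta t, 1/d_1, r_1, \hat p_1, \dots, 1/d_6, r_6, \hat p_6)$, built
against a 100 × 6 stride template $\mathbf T$ (columnwise mean of
resampled training strides — 448 by default in the corpus factory):

* $d_i$ — DTW distance of raw channel $i$ against template column $i$,
  normalized by the optimal path length. The DTW uses the classic step set
  $\{(1,1),(1,0),(0,1)\}$ with absolute-difference local cost, anchored
  endpoints and no window; the accumulated cost counts every cell on the
  path, and the path length is the number of cells. These conventions are
  pinned to a brute-force path enumeration in the tests. $d_i$ is floored at
  $10^{-6}$ before inversion so a perfect template match yields a large but
  finite feature.
* $r_i, p_i$ — Pearson correlation of the *warped* channel (query averaged
  onto the reference grid where several samples map to one index — the mean
  is the natural reduction that keeps the correlation well defined) with the
  template column; the p-value is the usual two-sided t test with
  $n - 2 = 98$ degrees of freedom.
* $\hat p_i = 0.1\,\log p_i$ with the natural log (the convention of the
  scientific-python ecosystem this transform originates from), with $p$
  clamped at machine epsilon so the feature is finite even when the
  correlation is numerically perfect.

## 4. stepperNet

Architecture (all sizes derived, and asserted, from the configuration):
100 × 6 input → three 10 × 6 kernels, step 1, valid support → 91 × 1 × 3 →
ReLU → 3 × 1 max pooling at stride 3, remainder truncated → 30 × 1 × 3 →
concatenate (90) → append $\mathbf c$ (109) → dense 30 (ReLU) → dense 15
(ReLU) → linear 2 → softmax; the stride probability is the second softmax
component and a candidate is accepted iff it exceeds 0.5 (a tie is
rejected — rejection is the conservative default for a gatekeeper).

Where the published description was ambiguous, the printed tensor sizes
decide: an output height of 91 forces valid (no-pad) convolution
(100 − 10 + 1), and a concatenated length of 90 forces pooling stride =
kernel = 3 with the remainder sample truncated (3 × ⌊91/3⌋). The
nonlinearity (ReLU), the 15 → 2 output head and the mean cross-entropy loss
are unstated upstream and are this package's choices.

Training is plain per-example SGD with classical momentum — defaults 7
epochs, learning rate 0.015, momentum 0.75 — restarted from `n_restarts =
10` He-style uniform random initializations; each restart is scored on a
held-out split (default fraction 0.13, mirroring a 3493/521-style split) and
the best restart is kept. A small network trained briefly on few examples is
genuinely initialization-sensitive, which is why restarts, not longer
training, are the lever. The analytic backpropagation is verified against
central finite differences to 1e−5 relative error.

## 5. Event rules

Within an accepted stride region:

* **HO/FF** — first and last $k$ with $\omega_a[k]/\sigma_{\omega_a} > 0.5$.
  $\sigma_{\omega_a}$ is the *population* standard deviation over the region
  (upstream leaves the estimator and its support unstated; the region-local
  choice makes the rule scale-invariant per stride, and the rule is tested
  to be invariant under positive rescaling of all rate channels).
* **HS** — the most prominent local maximum of $\dot a_z$ after HO, with
  topographic prominence (height above the higher of the two flanking key
  saddles) and ties to the earliest index.
* **TO** — the first zero crossing of $a_x - a_z$ strictly between HO and
  HS, returning the later sample of the crossing pair; sampled signals
  almost never satisfy $a_x[k] = a_z[k]$ exactly, so the sign change is the
  faithful discrete reading of that equality, and an exact zero counts as
  the event sample.

The composition enforces HO < TO < HS < FF; any sub-detector failure or
ordering violation marks the stride invalid with a reason code instead of
raising, so batch processing never aborts. Note that a genuinely random
signal can satisfy this grammar by chance — soft failure is guaranteed for
signals missing a signature (no sustained rotation, no derivative peak), not
for arbitrary noise.

## 6. What the generator emulates — and what it does not

`simulate_stride()` composes Gaussian bumps and a rate plateau rather than
simulating biomechanics: a sagittal-rate lobe peaking mid-swing
(350 deg/s), HO/HS rate dips, a sustained rate plateau (120 deg/s) between
HO and FF, a sharp vertical-acceleration impulse (15 m/s²) at HS, and a
push-off transition of $a_x - a_z$ (6 m/s²) crossing zero exactly halfway
between the samples flanking TO. Stride duration is drawn from
N(1.1 s, 0.1²), swing fraction 0.38, sensor noise 2% of channel range —
values a gait lab would call ordinary for self-selected treadmill walking.
Event positions are fixed fractions of the segment (HO 10%, TO 22%, HS =
TO + swing fraction, FF 88%), so gold events are known by construction and
noise-free detection recovers them to within one sample.

Non-stride segments come in three archetypes (stomp, jump, band-limited
wiggle), deliberately heterogeneous because the variety of non-walking
motion is exactly what makes the non-stride class the harder one.
`simulate_labelers()` adds i.i.d. Gaussian timing jitter snapped to a 10 ms
grid, per-label misses and uniform spurious insertions.

Passing tests on this corpus therefore show that the *algorithms* do what
they claim under the stated signal grammar and noise model. They do not show
robustness to physiological variability the generator lacks: asymmetric or
pathological waveforms, soft-tissue artifacts, sensor drift or
misalignment, variable cadence within a recording, or event signatures that
deviate from the constructed ones. Claims about real recordings require
real recordings.

Under the generator's default conditions (1,000 balanced examples) the full
recipe reaches at least 90% stride and 80% non-stride held-out accuracy on
every tested seed — comfortably the regime reported for the method on real
data, though on an easier corpus; the numbers are not comparable beyond the
regime.

## 7. Label condensation and the limit of agreement

Labelers produce different numbers of labels, and equal counts do not imply
correspondence. Sequences are therefore matched pairwise with a global
(Needleman–Wunsch) alignment run as cost minimization: matching $x_i$ with
$y_j$ costs $|x_i - y_j|$ and every gap costs the mean inter-label interval
$\bar g = \mathrm{mean}(\delta x)$, $\delta x_i = x_i - x_{i-1}$, $x_0 = 0$,
of the *first* sequence. The penalty is asymmetric by construction, so the
pair order is fixed (lower labeler index first) to keep results
deterministic; traceback ties prefer match over a gap in $x$ over a gap in
$y$. After each round over all unordered pairs, every label gapped in *any*
alignment is discarded — the strictest reading of "iterate until the counts
converge", chosen because it guarantees termination (the label count
strictly decreases every non-final round) and positional correspondence at
the fixed point. A consequence worth knowing: one labeler missing an event
removes that event's entire row, so with miss probability $p$ per label and
$N$ labelers the removed fraction is approximately $1-(1-p)^N$ plus the
spurious rate — a few percent at $p = 0.01, N = 5$.

From the matched matrix $\mathbf L \in \mathbb R^{M\times N}$: consensus
labels $\bar l$ (row means), errors $\mathbf D[:,i] = \bar l - \mathbf
L[:,i]$ (rows of $\mathbf D$ sum to zero by construction), and LOA = 95th
percentile (linear-interpolation quantile) of $|\mathbf D|$. For i.i.d.
Gaussian jitter with standard deviation $\sigma$ the errors are
$N(0, \sigma^2(1 - 1/N))$, so the LOA converges to
$1.96\,\sigma\sqrt{1 - 1/N}$; at $\sigma = 10$ ms, $N = 5$, $M = 2000$ the
empirical LOA lands within 5% of 17.5 ms (tested). Label arithmetic is done
in milliseconds to avoid float-second rounding in metrics; detector
evaluation (`error_metrics`) reuses the same alignment to pair detected with
reference events and reports mean, SD, MAE, RMSE and the 95th-percentile
absolute error in ms.

## 8. Numerical choices and degenerate inputs

* Derivatives are backward differences against the true time axis with the
  first sample fixed to 0, so derivative signals keep their source length.
* Indices are 1-based inclusive throughout, as idiomatic in R; all reported
  event times are timestamps, so nothing outside the API depends on indexing.
* Quantiles everywhere are the linear-interpolation definition
  (`stats::quantile` type 7).
* Model files round-trip bitwise: weights are stored as base64-encoded
  little-endian float64 inside JSON.
* Every stochastic routine takes a seed; a fixed seed reproduces corpora
  bytewise after serialization (tested).

## 9. Problem sizes used by the test suite

The suite runs the dynamic-program oracles on hundreds of small instances
(alignment lengths ≤ 5, DTW lengths ≤ 6, where exhaustive enumeration is
feasible), the LOA recovery at M = 2,000 × N = 5, event recovery on 500
noise-free and 500 noisy strides, and the classifier regime on 1,000
balanced examples across 5 seeds — sizes chosen so the statistical
assertions are stable while the whole suite stays a desk-scale run.

## 10. Known limitations

* The ROM detector is offline (zero-phase filtering needs the whole
  recording) and its defaults were chosen for 100 Hz walking data.
* One template represents one stride morphology; heterogeneous or
  pathological gait would need a template library or a density model of
  stride shape, which is out of scope here.
* Sub-sample event interpolation is not attempted: event times are sample
  timestamps, so 10 ms granularity at 100 Hz is intrinsic.
* The LOA toolkit quantifies *inter*-labeler disagreement only;
  test–retest (intra-labeler) consistency is a different measurement.
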