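---
title: "Hierarchical fusion of wearable motion and camera data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical fusion of wearable motion and camera data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The recognition problem

A wearable hybrid sensor system — a 6-channel inertial measurement unit
(3-axis accelerometer + 3-axis gyroscope) and an egocentric camera — records
a person's day. The goal is to label each moment with one of $n$ activities
of daily living (ADLs): computer use, eating, napping, sweeping, walking
outside, and so on. The two modalities fail in complementary ways. The IMU
distinguishes *postures and movement* (lying, sedentary, standing, walking)
extremely well, but activities that share a posture — writing vs. computer
use — are invisible to it. The camera sees *context* (desk, plate, street),
but treats every activity as one among $n$ candidates.

`hierfusar` implements a two-layer cascade that lets each sensor work in
the classification mode it is good at:

1. **Motion-state layer.** An LSTM over the 3 s sensor window assigns one
   of $m$ coarse motion states, $y = \mathrm{softmax}(\mathrm{FC}(\mathrm{LSTM}(x)))$.
2. **Activity layer.** The motion state selects a *group* of candidate
   activities; a group-specific image classifier — a single softmax FC
   layer on global-average-pooled convolutional features for low-frame-rate
   photo streams, or an LSTM over per-frame features for high-frame-rate
   streams — resolves the activity within that reduced candidate set.
   Groups containing a single activity are emitted by the motion layer
   directly; no image model is consulted.

The cascade is driven by a *correspondence* $C_{A \leftrightarrow M}$
linking each activity to every motion state in which it can occur
(reading can happen seated or standing). Its inverse images
$C^{-1}(M_j)$ are the groups. When every activity has one state the groups
partition $A$ and group sizes satisfy $\sum_i n_i = n$; with multi-state
activities the groups overlap and $\sum_i n_i > n$. The packaged
`eButton` grouping (15 ADLs over lying / sedentary / standing / walking)
has group sizes $(2, 11, 9, 2)$, total 24.

The baseline it is compared with is *direct fusion*: two flat classifiers
each score all $n$ activities and their softmax outputs are pooled
elementwise (average, or maximum followed by renormalization — the
renormalization cannot change the argmax and is adopted only so the fused
vector reads as a posterior).

## Time alignment

Each frame shot at time $t_c$ receives the sensor window
$[t_c - t_w/2,\; t_c + t_w/2)$ with $t_w = 3$ s by default. Windows are
half-open so adjacent non-overlapping windows partition time; the
convention at the window endpoints is ours (the choice is invisible except
at exact sample boundaries). A window always yields exactly
$L = \mathrm{round}(f_s t_w)$ rows (270 at 90 Hz): samples are addressed by
nearest-sample index computed from $f_s$ rather than by per-sample
timestamp search, which makes extraction deterministic under timestamp
jitter, and rows falling outside the recorded stream are filled by edge
replication and flagged. Continuous streams are cut at centers
$(k + 0.5)\,\Delta c$, $k = 0, \ldots, \lfloor D/\Delta c\rfloor - 1$ —
the unique uniform-spacing convention that cuts a 15 s sequence into
exactly 15 overlapping 3 s windows at $\Delta c = 1$ s. How the first and
last clipped windows of such a sequence obtain full 3 s support is not
dictated by the protocol; clipping + edge padding is one consistent
choice and is flagged per row in `pad_flags`.

## Classifiers and training

The recurrent networks are implemented in vectorized base R (a
single-layer LSTM with forget-gate bias 1, trained by Adam with full
backpropagation through time); no deep-learning framework is required.
Default hyperparameters follow the published recipe: Adam at learning
rate $10^{-3}$ with moment decays $0.9/0.99$; the motion classifier uses
128 hidden units, 150 epochs, batch 30; image heads use 50 epochs, batch
8; sequence heads use a 512-unit LSTM and a 512-unit FC layer with
dropout 0.7. The image-head dropout asymmetry is deliberate: no dropout
is applied to the motion classifier, matching the recipe, which states
dropout only for the image-sequence heads. Neither softmax temperature
nor class weighting is used.

Two deliberate departures from a GPU-scale setup:

* **Feature extraction is an injectable contract.** The reference system
  extracts frame features with an ImageNet-pretrained VGG-16 whose layers
  are frozen while a single FC head is fine-tuned. Here the extractor is
  an interface with two shipped implementations — a pass-through for
  precomputed feature vectors (the synthetic generator's native format)
  and a small seeded convolutional stack for raster images — both used
  frozen during head training, which asserts a parameter fingerprint
  before and after. A pretrained backbone can be plugged in by
  implementing `extract_features()`.
* **A desk-scale training profile.** `train_config("ci")` shrinks hidden
  sizes to 32, epochs to 30–40, and block-averages the 270-row segment to
  30 time steps before the recurrence. Temporal pooling preserves the
  orientation and low-frequency oscillation cues that distinguish motion
  states while cutting the recurrence length ninefold. All tests and the
  worked examples below use this profile; the full published recipe is the
  default for users with time to spend.

Multi-state activities contribute their frames to the training set of
*every* group they belong to, so each group head sees all contexts in
which its activities occur. Sensor channels and features are standardized
with training-set statistics stored in the fit. Every fit records its
seed; identical seeds give bitwise-identical parameters on a fixed
BLAS/thread configuration. Ties at any argmax resolve to the lowest
canonical index; a prediction is scored correct iff the final activity
label matches, regardless of which group it was routed through.

## The synthetic data generator

Real recordings of this kind are either private or large external
downloads, so the package ships a seeded generator that reproduces the
*statistical premise* of the cascade rather than the pixels:

* **Sensor model (per motion state).** Accelerometer = a gravity
  orientation vector (9.81 m/s², orientations spread over a quarter
  circle), plus i.i.d. Gaussian noise (sd 0.3 m/s²); states suggesting
  periodic movement (walking, running, cycling, push-ups, sit-ups) add a
  sinusoid near the 2 Hz human gait band with a uniform random phase, on
  accelerometer and gyroscope channels. Crucially, *activities sharing a
  state share that state's signal model exactly*: within a group the IMU
  carries no activity information, by construction.
* **Image model (per activity).** Feature vectors from a Gaussian cluster
  in $d = 16$ dimensions: mean $\delta u_a$ with the $u_a$ the signed axes
  of one random rotation (layout seed separate from the dataset seed), so
  every pair of cluster means is at least $\delta\sqrt{2}$ apart and
  $\delta$ is a genuine separation scale; within-cluster sd 1.
  $\delta = 2.5$ by default — informative but not saturated, so the
  benefit of reducing the candidate set is measurable. Low-rate payloads
  are single vectors; high-rate payloads are $K = 90$ frame features
  following an AR(1) chain with $\rho = 0.9$ (3 s at ~30 fps).
* **Presets.** `"ebutton-like"` (15 ADLs, 4 posture states, low rate,
  frames ≥ 4 s apart) and `"multimodal-like"` (20 activities, the M6
  grouping, high rate, 15 s sequences cut at 1 s spacing).

`bayes_oracle()` returns the exact activity posterior under this
generative model (the oscillation phase is marginalized numerically over
a 64-point grid) and upper-bounds what any classifier can achieve.

What passing tests on this generator do **not** show: robustness to real
IMU artifacts (drift, orientation changes, non-stationary gait), to real
image nuisances (lighting, occlusion, camera angle), or to label noise.
The generator validates the *framework* — routing, grouping, fusion,
evaluation — not a claim about field accuracy.

## Study conditions used by the test suite

The comparison experiment trains on 3000 and tests on 1500 samples of the
`ebutton-like` preset under the `"ci"` profile (seed 21). These sizes make
the suite complete in minutes on one CPU while leaving the ordering of
methods far outside seed noise; a representative run prints:

```
       method macro_f1 accuracy
 hierarchical   0.7687    0.776
  sensor_only   0.1885    0.282
   image_only   0.6443    0.652
   direct_avg   0.6864    0.698
   direct_max   0.6502    0.664
```

(printed by `run_experiment()` at 1000/500 samples, seed 21). The ordering
— hierarchical above direct fusion above image-only, sensor-only far
behind — is the asymmetric-modality regime: the sensor is near-perfect
about states and uninformative within groups, so averaging its flat
posterior into the image posterior dilutes it, while routing through it
sharpens the candidate set. The premise check verifies both halves
directly: motion-state accuracy exceeds 0.95 while within-group
sensor-only activity accuracy is statistically indistinguishable from
within-group chance (exact binomial test at $\alpha = 0.01$).

## The online cost model

For deployment the relevant quantity is per-frame compute. The
direct-fusion baseline runs two optical-flow extractions, three
convolutional passes and up to four recurrent passes per frame:
$2 t_{OF} + 3 t_{C1} \le t_1 \le 4 t_{L1} + 2 t_{OF} + 3 t_{C1}$. The
hierarchical pipeline runs one CNN pass and at most one motion LSTM plus
one CNN-LSTM pass: $t_{C2} \le t_2 \le t_{L2} + t_{C\!-\!L}$. At the
published component times ($t_{OF} = 12.2$, $t_{C1} = 9.709$,
$t_{L1} = 0.659$, $t_{C2} = 2.395$, $t_{L2} = 0.659$,
$t_{C\!-\!L} = 4.103$ ms) these give $53.527 \le t_1 \le 56.163$ ms and
$2.395 \le t_2 \le 4.762$ ms. `fps_range()` converts to frame rates as
raw $1000/t$ values (210.0–417.5 fps for the hierarchical pipeline); we
return unrounded values because no single rounding convention reproduces
all the integer rates quoted alongside the worked example, so the raw
floats are authoritative here.

## Numerical choices and degenerate inputs

* Argmax ties: lowest canonical index (deterministic).
* `0/0 → 0` for precision, recall and F1 of absent or never-predicted
  classes; macro averages are unweighted means.
* A one-group hierarchy ($m = 1$) reduces exactly to the flat image
  classifier; this is tested.
* Singleton-group training is rejected rather than silently fitted: a
  one-class head is undefined and the cascade never calls one.
* The leave-one-sequence-out protocol forms $k$ splits whose test sets
  hold exactly one sequence per activity; the splits partition the data
  when every activity has exactly $k$ sequences (the 20 × 10 case).
* Windows that do not intersect the stream raise an error at extraction
  and are skipped (with a counted warning) during manifest association.

## Known limitations

* The hand-rolled LSTM is single-layer and unidirectional; stacked and
  bidirectional variants are out of scope.
* Group routing is hard (argmax); probabilistic soft routing over groups
  is a documented non-goal.
* No clock-drift correction between camera and IMU; alignment trusts the
  shared timestamp base.
* The generator's simplicity is intentional; see the caveats above about
  what it cannot certify.
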