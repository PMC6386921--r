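# hierfusar

Hierarchical fusion of wearable motion-sensor and egocentric camera data
for recognizing activities of daily living (ADLs).

## The problem and the method

A wearable hybrid system — a 6-channel IMU (3-axis accelerometer + 3-axis
gyroscope at 90 Hz) and a chest-worn camera — observes a person's day; the
task is to label each 3 s window with one of *n* activities (computer use,
eating, napping, sweeping, walking outside, ...). The IMU is excellent at
coarse **motion states** (lying, sedentary, standing, walking) and nearly
blind within them; the camera sees context but faces all *n* candidates at
once. `hierfusar` implements a two-layer cascade that assigns each sensor
its best classification mode:

1. **Motion-state layer** — an LSTM over the sensor window:
   `y = softmax(FC(LSTM(x)))` selects a motion state `M_j`.
2. **Activity layer** — the correspondence `C_{A<->M}` (each activity
   linked to every state it can occur in) turns `M_j` into a group of
   candidate activities `C^-1(M_j)`. A singleton group is emitted
   directly; otherwise a group-specific image classifier decides:
   `y_t = softmax(FC(GAP(conv(I_t))))` for a low-frame-rate single frame,
   or `y_t = softmax(FC(LSTM({f_1..f_K})))` over per-frame GAP features
   for a high-frame-rate sequence.

The package ships the correspondence algebra with packaged groupings (the
15-activity/4-state `eButton` hierarchy; the 20-activity `M5`–`M8`
lifelogging groupings), frame-to-sensor window alignment, the three
classifier contracts (base-R LSTM + softmax heads, Adam training, seeded
and reproducible), direct-fusion baselines (average/maximum softmax
pooling), confusion-matrix / per-class F1 evaluation with a
leave-one-sequence-out protocol, an online per-frame cost model, and a
seeded synthetic multimodal generator so that every stage runs and is
testable on one CPU with no downloads.

## Worked example

Train and score all five methods on the low-frame-rate synthetic preset
(15 ADLs, 4 posture states, deliberately asymmetric modalities):

```r
library(hierfusar)
spec <- preset("ebutton-like")
cfg  <- experiment_config(spec, n_train = 1000, n_test = 500,
                          train = train_config("ci"), seed = 21)
run_experiment(cfg)
#> Recognition experiment (synthetic data)
#>        method macro_f1 accuracy
#>  hierarchical   0.8308    0.832
#>   sensor_only   0.1773    0.284
#>    image_only   0.7362    0.736
#>    direct_avg   0.7754    0.780
#>    direct_max   0.7512    0.756
```

The sensor alone collapses (it cannot see inside motion-state groups, by
construction of the generator), and averaging its flat posterior into the
image posterior (`direct_avg`) dilutes the image signal — while *routing*
through the motion state (`hierarchical`) raises accuracy above every
baseline by shrinking the candidate set.

The online per-frame cost model, at published component times
(milliseconds):

```r
p <- cost_params(t_of = 12.2, t_c1 = 9.709, t_l1 = 0.659,
                 t_c2 = 2.395, t_l2 = 0.659, t_cl = 4.103)
t1_bounds(p)   # direct-fusion baseline:  lower 53.527  upper 56.163
t2_bounds(p)   # hierarchical pipeline:   lower  2.395  upper  4.762
fps_range(2.395, 4.762)  # fps_min 210.0  fps_max 417.5
```

The baseline needs 53.5–56.2 ms per frame (two optical-flow extractions
dominate); the cascade needs 2.4–4.8 ms, i.e. it sustains hundreds of
frames per second.

A thin command-line front end over the same functions lives at
`inst/cli/hierfusar-cli.R` (subcommands `cost-model`, `generate`,
`experiment`, `sweep`).

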