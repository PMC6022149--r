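# harfall

User-adaptive human-activity recognition and fall detection from
waist-worn six-axis inertial (IMU) streams, for researchers and
engineers building wearable activity monitors who cannot ask every new
wearer to label training data.

## The method

A new user's 50-Hz accelerometer + gyroscope recording is turned into a
personal classifier without any manual annotation:

1. **Preprocess** — per-channel calibration `x = raw/k + b`; gravity /
   body-acceleration separation with a zero-phase 3rd-order Butterworth
   low-pass at 0.3 Hz; segmentation into 1-s windows with 50% overlap
   (window *k* starts at sample 25·(k−1)).
2. **Features** — 13 time-domain features per window: mean, standard
   deviation, energy, mean-crossing rate, max and min of the
   body-acceleration magnitude `a` and of the angular-velocity
   magnitude `ω`, plus the tilt angle
   `TA = sqrt((∫ωx dt)² + (∫ωz dt)²)`; min–max normalization fitted on
   training data.
3. **Seeded K-Means annotation** — Lloyd iterations initialized at the
   labelled class centroids `c_k = mean(S_k)` of a pre-collected
   dataset from *other* users; converged clusters inherit the seed
   labels (LIA / MIA / VIA — light, moderate, vigorous intensity).
4. **LLOF filtering** — a local outlier factor with neighbor search
   restricted to each window's own labelled cluster; windows scoring
   above a threshold (default 1.5, k = 20) are discarded as
   low-confidence annotations.
5. **Per-class Gaussians + fall rule** — one multivariate Gaussian
   `p_k(x)` per intensity class (MLE with shrinkage ridge); windows are
   classified by `argmax p_i(x)`, and a vigorous winner is a **Fall**
   when both `p_3(x) ≤ ε2` (density anomaly) and `TA ≥ ε3` (≥ 60°
   posture change). Falls never appear in training data.

The package also ships a multi-subject synthetic IMU simulator
(per-subject amplitude/cadence/rotation-style shift, scripted 300-ms
fall transients inside vigorous activity) and an evaluation harness:
per-class F-measure, a leave-one-out generic-vs-personalized protocol
with a 4:1 train/test split, and Fisher's exact test for 2×2
improvement tables.

## Worked example

Train a personalized classifier on one simulated subject's fall-free
recording, seeded by another subject's labelled windows, then classify
the held-out fifth (which contains three scripted falls):

```r
library(harfall)

stream <- simulate_subject(subject_profile(seed = 42))
cut <- floor(nrow(stream$samples) * 0.8)
train <- har_stream(stream$samples[1:cut, ], 50, stream$labels[1:cut])
test  <- har_stream(stream$samples[(cut + 1):nrow(stream$samples), ], 50,
                    stream$labels[(cut + 1):nrow(stream$samples)])

seed_subj <- separate_gravity(simulate_subject(subject_profile(seed = 7)))
seed_X <- window_features(segment_windows(seed_subj))

clf <- train_personalized(train, seed_X, attr(seed_X, "labels"))
clf
#> <personalized_classifier>
#>   training windows: LIA=97 MIA=99 VIA=92
#>   thresholds: eps2 = 6.774e+08 (density on p3), eps3 = 60 deg
#>   pipeline: 1 K-Means iteration(s), 11 window(s) removed by LLOF

pred <- classify_stream(clf, test)
table(truth = pred$truth, predicted = pred$predicted)
#>       predicted
#> truth  Fall LIA MIA VIA
#>   Fall   12   0   0   0
#>   LIA     0  15   0   0
#>   MIA     0   0  16   0
#>   VIA     0   0   0  31
```

The training report shows the adaptive pipeline at work: the user's 299
unlabeled windows were annotated in one K-Means pass from the other
subject's centroids, 11 low-confidence windows were removed by LLOF,
and the fall threshold `eps2` was placed at the 1st percentile of the
vigorous-class training density. All 12 fall windows in the held-out
data are detected with no false alarms.

A cohort-level comparison (10 subjects, leave-one-out):

```r
cohort <- make_cohort(n_subjects = 10, master_seed = 1)
loo_generic_vs_personalized(cohort)
#> <har_eval_report> 10 subjects, 8:2 train:test split
#>  class f_personalized f_generic    delta
#>    LIA         0.9935    0.9935 0.000000
#>    MIA         0.9903    0.9871 0.003226
#>    VIA         0.9984    0.9968 0.001587
#>   Fall         1.0000    1.0000 0.000000
```

A command-line wrapper with subcommands `simulate`, `features`,
`annotate`, `filter`, `train`, `classify` and `evaluate` is installed
at `inst/cli/harfall` (run it with `Rscript`); configuration comes from
a YAML file or `--` flags, and every JSON artifact embeds the effective
configuration and its hash.

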