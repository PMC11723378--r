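# gaitshift

Laboratory-of-origin discriminability analysis for gait cycle time series.

## The problem

Clinical gait analysis records, per gait cycle, a panel of 24
time-normalized signals (100 samples each): joint-angle trajectories for
pelvis, hip, knee, ankle and forefoot in three planes, three
ground-reaction-force components, and sagittal joint moments and powers.
When two laboratories collect such data — even with matched equipment and
protocols — a deep time-series classifier can often identify the source
laboratory of a *single cycle* with high accuracy. That discriminability
is a batch effect, and it bounds the transferability of any machine
learning model between sites: if a network can tell the labs apart, a
model trained in one lab will not behave reliably in the other.

`gaitshift` implements the complete analysis pipeline around this
question, for methodologists studying dataset shift in clinical time
series:

- a **synthetic two-laboratory gait generator** calibrated to published
  cohort summaries (a Dublin-like n = 96 and a Madrid-like n = 31
  pediatric cohort), with controllable *difference knobs* — extra
  initial-segment noise, high-frequency content, stance-timing warp,
  amplitude gain/offset, harmonic phase jitter — whose zero setting makes
  the two labs statistically exchangeable;
- the standard **preprocessing chain**: truncation of the first 30% of
  the cycle, Savitzky–Golay smoothing (order 3, window 9), z-scoring,
  rank-to-uniform standardization (the n-th smallest of 70 values maps
  to n/70), decimation, and sub-window extraction;
- **repeated balanced classification**: per-signal lab-of-origin
  classifiers (ResNet, CNN, MLP, transformer, LSTM; the convolutional
  models run in a compiled single-precision engine) trained under
  leave-one-cycle-out (LOCO) or leave-one-patient-out (LOPO)
  cross-validation; the *classification score* is the median test
  accuracy over repetitions;
- **divergence statistics** that explain the classifier: per-lab median
  autocorrelation curves and their minimum-lag log-ratio
  `|log2(tau_A/tau_B)|` and inter-curve area; Welch power spectra with
  the analogous peak and area deltas; and random continuous ordinal
  patterns (COPs) scored by the maximum |Cohen's D| between labs;
- **association analysis**: Spearman rank correlation and OLS fits of
  classification scores on divergence metrics, reproducing the finding
  that labs differing more in correlation/spectral structure are easier
  to classify.

## Worked example

```r
library(gaitshift)

# two labs that differ in high-frequency content and stance timing
ds <- generate_dataset(
  dublin_profile(),
  madrid_profile(difference_knobs(delta_hf = 0.5, delta_warp = 2)),
  n_a = 96, n_b = 31, cycles_per_side = 5, seed = 7,
  signals = "hip_moment")

res <- evaluate_signal(
  ds, "hip_moment",
  preprocess = preprocess_preset("smoothed"),
  classifier = classifier_config("resnet", desk_scale = TRUE),
  evaluation = evaluation_config(desk_scale = TRUE, seed = 7))
res
#> <classification_result> hip_moment (resnet, LOCO): score 1 over 10 repetitions

divergence_metrics(ds, "hip_moment")
#> # A tibble: 1 x 9
#>   signal     tau_a tau_b delta_minima_acf delta_area_acf delta_maxima_psd ...
#> 1 hip_moment    30    29           0.0489           3.30                0 ...
```

The score of 1.0 says every one of the 10 independently trained reduced
ResNets classified all held-out cycles correctly: these two synthetic
labs are fully discriminable from a single hip-moment cycle. The
divergence table explains why: the labs' median autocorrelation curves
differ substantially in shape (`delta_area_acf` = 3.3, against a null
level near 0.2 for exchangeable labs), while their ACF minima sit at
almost the same lag (30 vs 29, `delta_minima_acf` = 0.05). With all
knobs at zero and identical profiles, the same call calibrates to a
score near 0.5 — chance level.

A full experiment (several signals × preprocessing presets × schemes,
divergence, association, report files) runs through `run_experiment()`
or the CLI:

```sh
Rscript inst/scripts/gaitshift run-all --config my_experiment.yaml \
        --seed 7 --desk-scale --out results/
```

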