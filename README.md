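# gammaflow

Movement-related oscillation features, TMS inhibition measures and
Bayesian correlation inference for sensorimotor neurophysiology.

## The problem

Voluntary movements are accompanied by band-specific changes in
sensorimotor oscillatory power: a beta-band (13–30 Hz) desynchronisation
during movement with a rebound after movement offset, a slow-gamma
(30–60 Hz) synchronisation peaking at movement offset, and a mid-gamma
(60–90 Hz) synchronisation confined to the movement. Individual
differences in these responses — especially each person's *peak frequency*
within a band — can be related to GABAergic intracortical inhibition
(measured with paired-pulse TMS as the SICI ratio) and to motor-learning
ability. Testing such relationships requires a long chain of processing:
continuous-data conditioning, EMG-based movement timing, source projection,
time–frequency decomposition, per-subject feature extraction, TMS trial
curation, behavioural scoring, and correlation inference with principled
evidence quantification.

`gammaflow` packages that chain as tested, reusable R functions, plus a
synthetic-data generator with explicit ground truth so every stage can be
validated end to end without access to recorded data. It is aimed at
researchers building or auditing movement-locked M/EEG + TMS + behaviour
pipelines.

## What is inside

| Stage | Functions |
|---|---|
| Synthetic data with ground truth | `sim_config()`, `make_trial_schedule()`, `simulate_recording()`, `simulate_population()`, `simulate_mep_trials()`, `simulate_ml1()`, `simulate_ml2()` |
| Conditioning | `resample_recording()`, `filter_band()`, `split_bands()`, `gesd()`, `detect_bad_segments()` |
| EMG movement timing | `detect_onset_offset()`, `detect_movements()`, `exclude_trials()` |
| Source projection | `eigen_normalize()`, `lcmv_weights()`, `project_sources()`, `sensor_covariance()` |
| Spectral features | `dpss_tapers()`, `multitaper_tf()`, `baseline_correct()`, `extract_band_peak()`, `power_map()` |
| TMS / SICI | `peak_to_peak()`, `reject_mep_trials()`, `grubbs_once()`, `sici()` |
| Learning scores | `ml1_score()`, `ml2_bin()`, `ml2_score()` |
| Correlation inference | `mahalanobis_bootstrap_outliers()`, `pearson_bf10()`, `bf10_from_r()`, `classify_bf()`, `compare_correlations()`, `correlate_features()` |
| Orchestration | `experiment_template()`, `run_subject_features()`, `run_subject_sici()`, `run_experiment()` |

The core statistics are implemented from first principles and verified
against independent oracles in the test suite: Rosner's generalised extreme
studentised deviate (GESD) test, Grubbs' single-iteration test, DPSS tapers
from the tridiagonal Slepian eigenproblem, the LCMV beamformer
`w = (l'C⁻¹l)⁻¹ l'C⁻¹` with PCA rank reduction, and the default-prior
correlation Bayes factor

    BF10 = ∫ p(r | ρ, n) / p(r | 0, n) · π_κ(ρ) dρ,

with a stretched-beta prior of width κ (κ = 1: uniform on (−1, 1)) and the
exact sampling density of the Pearson correlation.

## Worked example

Simulate one subject with a slow-gamma peak planted at 47 Hz, run the
sensor-to-feature chain, and compute a SICI ratio from simulated TMS
trials:

```r
library(gammaflow)

cfg <- sim_config(seed = 11, sampling_rate = 250,
                  n_channels = c(MAG = 4L, GRAD = 4L),
                  grid_dims = c(2L, 2L, 2L), snr = 5)
cfg$band_truth$slow_gamma$freq <- 47

res <- run_subject_features(cfg, experiment_template("experiment1"),
                            seed = 99, bands = "slow_gamma", rank = 8,
                            max_trials = 20)
res$features
#>                  band    power peak_freq_hz peak_loc n_epochs
#> slow_gamma slow_gamma 5.580245           48        8       18

trials <- rbind(simulate_mep_trials(cfg, "spMEP_early", 15, 1),
                simulate_mep_trials(cfg, "SICI_early", 15, 2))
sici(reject_mep_trials(trials), "SICI_early", "spMEP_early")
#> <sici_measure> ratio 0.522 (conditioned 0.542 / unconditioned 1.040 mV; n = 13/15)
```

The chain found the planted source (grid index 8, matching the ground
truth), estimated its peak frequency at 48 Hz from 18 retained epochs
(1 Hz from the planted 47 Hz — the output grid spacing), and a
movement-related power of 5.6 times baseline. The SICI ratio 0.52
estimates the planted 0.5: two conditioned trials were lost to the
rejection rules.

Correlating two subject-level features with outlier removal and a Bayes
factor:

```r
x <- c(0.9, 1.1, 1.0, 1.2, 0.8, 1.05, 0.95, 1.15, 1.0, 0.85, 7.5)
y <- c(1.0, 1.2, 1.1, 1.3, 0.9, 1.10, 1.00, 1.25, 1.1, 0.95, 0.2)
correlate_features(x, y, seed = 3)
#> <correlation_result> r = 0.987 (n = 10), BF10 = 3.81e+04: extreme evidence for H1
#>   removed outliers: 11
```

The bootstrapped Mahalanobis rule removed the planted bivariate outlier
(subject 11) before the correlation was assessed.

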