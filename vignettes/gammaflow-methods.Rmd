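---
title: "Movement-related oscillation analysis with gammaflow: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement-related oscillation analysis with gammaflow: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gammaflow)
```

# Scope

`gammaflow` implements an analysis chain for movement-locked
electrophysiology: from continuous multichannel recordings with a surface
EMG channel, TMS motor-evoked-potential (MEP) trial tables and
motor-learning behavioural series to subject-level features — band-specific
peak power, peak frequency and peak location; short-interval intracortical
inhibition (SICI) ratios; learning scores — and finally to cross-subject
Pearson correlations with default-prior Bayes factors. A synthetic-data
generator with explicit ground truth makes every stage testable without
access to recorded data.

The three frequency bands of interest are beta (13–30 Hz), slow gamma
(30–60 Hz) and mid gamma (60–90 Hz). Movement elicits a beta
desynchronisation (ERD) during the movement and a beta rebound (ERS) for
roughly a second after movement offset; a slow-gamma synchronisation that
ramps up during the movement and peaks at movement offset; and a mid-gamma
synchronisation confined to the movement itself.

# The sensor model and the synthetic generator

The generator writes sensor data as

$$X = G^\top S + N,$$

where $G$ is a sources-by-channels leadfield on a regular volumetric grid
(8 mm spacing by default), $S$ holds source time courses and $N$ is a
white/pink noise mixture scaled so that the clean-signal RMS divided by the
noise RMS equals the configured `snr`, plus a mains sinusoid (50 Hz). Band
responses are amplitude-modulated sinusoids at each subject's true peak
frequency with Hann-tapered envelopes over the windows described above —
the simplest shapes matching the verbal phenomenology. Every source also
carries ongoing pink background activity (`source_background_rms`, default
equal to the response amplitude). The background matters: in real
recordings task responses modulate only a modest fraction of total sensor
variance, and the bad-segment detector (below) assumes artefacts are *rare*
extremes. Without background, every movement window looks like an outlier
and the detector eats the data.

The EMG channel is baseline white noise with a flat-top burst (10 ms linear
edges) spanning each trial's true movement onset-to-offset window at ten
times the baseline RMS — a conservative figure for a ballistic index-finger
abduction against a relaxed baseline.

Trial schedules implement three designs: a 70-trial cued Go/NoGo task with
20% NoGo trials, a 200 ms cue, a 1 s cue–stimulus interval and uniform
2–4 s inter-trial intervals; a 140-trial Go-only variant with intervals
drawn from {2.7, 3.2, 3.7, 4.2, 4.7} s; and a paced-press design with four
digits cued at 1 Hz, eight flashes per digit, the 32-flash cycle repeated
eight times. True reaction times are Gaussian around 250 ms (SD 40 ms),
movement times around 400 ms (SD 60 ms).

The population layer draws latent trait pairs from a standard bivariate
normal with correlation `trait_corr` and maps them onto subject parameters
by monotone affine clamps: slow-gamma peak frequency into 35–57 Hz
(46 + 5.5·z), SICI ratio into 0.05–1.45 (0.55 + 0.2·z). The clamps keep
truths in the empirically plausible ranges; the default `trait_corr` of
0.65 plants an effect of the size the chain is designed to recover.

Within-subject trial-to-trial variability of the injected band responses is
not an empirically anchored quantity; it is exposed as `trial_amp_sd`
(log-SD of a per-trial amplitude jitter, default 0.2) rather than asserted.

# Continuous-data conditioning

Recordings are downsampled (500 Hz for the MEG-style templates, 250 Hz for
the EEG-style one), band-passed (1–245 Hz or 1–95 Hz) and notch-filtered
(49–55, 99–101, 149–151, 199–201 Hz, or 49–51 Hz), then split into the
analysis bands.

`filter_band()` works in the frequency domain: the spectrum is multiplied
by a real transfer function that is exactly 1 across the pass-band, falls
through raised-cosine transitions (1 Hz wide by default) and is exactly 0
inside each notch, after reflection padding against wrap-around transients.
A real transfer function has zero phase, so event latencies are preserved;
a flat pass-band makes the filter idempotent there, which low-order IIR
designs are not (an order-4 Butterworth band-pass at 13–30 Hz attenuates
even the band centre by several percent per zero-phase pass).
Integer-factor downsampling applies the same machinery as an anti-alias
low-pass (flat to 0.8 of the new Nyquist, zero at the new Nyquist) followed
by decimation; event indices rescale with round-half-away-from-zero.

Artefactual segments are found by computing, in non-overlapping 1 s
windows, the standard deviation of the signal pooled across all non-EMG
channels, and applying the generalised extreme studentised deviate test
(GESD, Rosner's sequential procedure) at significance 0.05 with at most 20%
of windows flaggable. `gesd()` caps the outlier count at
`floor(fraction * n)` so the flagged share never exceeds the cap. Flagged
windows are masked — dropped from covariance estimation and epoch
eligibility — not interpolated. The EMG channel is exempt: its bursts are
signal. Whether the 20% cap should apply per channel or globally is not
settled; it is applied globally here.

# EMG movement detection

Per trial (−1 to +3 s around the Go stimulus) the EMG is high-pass filtered
at 10 Hz and reduced to a root-mean-square envelope over an 80 ms window.
Three conventions in this step are genuinely open and are fixed as follows,
isolated in `detect_onset_offset()`:

* **Envelope alignment** — the RMS window is *causal* (trailing). A centred
  window smears burst energy ~40 ms backwards in time and biases onsets
  early by one to two search windows; the causal envelope keeps the rise
  aligned with the burst.
* **Threshold** — 3 standard deviations of the high-passed EMG activity in
  the −600 to −200 ms baseline. Basing the threshold on the envelope's own
  SD instead is unstable: the smoothed envelope has so little variance that
  baseline fluctuations cross mean + 3 SD spuriously.
* **Window statistic** — the onset is the start of the first forward,
  non-overlapping 24 ms window in which the envelope *exceeds* the
  threshold (searching from the Go stimulus); the offset is the start of
  the first such backward 120 ms window (searching from the trial end).
  Using the window mean instead delays detection by most of a window.

With these choices, onsets on synthetic data at SNR ≥ 5 fall within ±30 ms
of ground truth in ≥ 95% of trials — commensurate with the 24 ms search
granularity. Trials with no crossing return a no-movement marker, never an
error. Across trials, GESD (α = 0.05) is applied independently to the
envelope peak, reaction time and movement time; the union of flags is
excluded, with every contributing metric recorded.

# Source projection

Sensor groups (e.g. magnetometer-like and gradiometer-like channels) are
equalised by dividing each group's data by the smallest eigenvalue of its
covariance. A linearly constrained minimum-variance (LCMV) beamformer then
maps sensors to grid sources: with sensor covariance $C$ (computed across
the whole retained time course, per band) inverted on its leading
principal subspace (rank 50 by default, clipped to the available rank,
eigenvalues floored at $10^{-12} \lambda_{max}$), each source's weights are

$$w = \frac{C^{-1} l}{l^\top C^{-1} l},$$

which satisfies the unit-gain constraint $w^\top l = 1$ to $10^{-8}$.
Sources with $l^\top C^{-1} l$ at numerical zero are flagged unresolvable.
The synthetic model uses fixed-orientation sources, so the scalar
beamformer suffices. The EEG-style template skips beamforming and extracts
features in channel space.

# Time–frequency decomposition and band peaks

Epochs span −2 to +2 s around movement onset (offset for the beta rebound,
whose baseline is −1.5 to −1 s instead of −1 to −0.5 s). A DPSS multitaper
spectrogram uses 1.6 s windows in 200 ms steps. The taper count is not
pinned down by the window and grid alone; the default half-bandwidth is
1.5 Hz (time–half-bandwidth product 2.4, hence 3 tapers), chosen so the
spectral concentration band is commensurate with the 1 Hz peak-frequency
grid. A wider bandwidth (say 2.5 Hz, 7 tapers) gives smoother power
estimates but smears the background's spectral tilt into the peak: on
synthetic subjects with 1/f background it biased peak-frequency estimates
upward by about one 1 Hz bin, so narrow concentration wins for this
chain's primary quantity. The parameter is configurable for users whose
target is power rather than peak frequency. Tapers are computed from the
tridiagonal Slepian eigenproblem and cached. Windows are zero-padded to a
1 Hz output grid — grid spacing, not true resolution, which is set by the
2.5 Hz half-bandwidth. Only windows fully contained in the epoch are
computed.

Baseline correction divides by the mean baseline power across *all* trials:
$(P - B)/B$ per frequency and location, so the trial-averaged corrected
power over the baseline window is exactly zero. Relative change is the
default; the trial-average convention means single-trial baseline noise
does not blow up the denominator.

Per trial, corrected power is averaged over that trial's own
onset-to-offset window (offset to offset + 1 s for the beta rebound) —
time bins whose centres fall inside the window; the bin nearest the window
midpoint if none does (possible for movements shorter than the 200 ms
step). Averaging across trials leaves a frequency-by-location matrix whose
maximum (minimum for beta ERD) defines the subject's power, peak frequency
and peak location. Ties break towards the lowest frequency, then the lowest
location index, making extraction deterministic and permutation-invariant
to trial order. `power_map()` applies the same averaging at a fixed
frequency to produce one value per location.

# TMS trials and SICI

MEPs are quantified peak-to-peak (max − min) in a response window. Four
rejection rules run in a fixed order: (1) test-pulse amplitude below
0.1 mV — applied to unconditioned trials only, because a small
*conditioned* response may be genuine inhibition; (2) pre-pulse EMG above
0.1 mV in the 80 ms before the pulse (precontraction), measured as the
maximum absolute value; (3) per condition and block, amplitudes outside the
survivors' mean ± 2 SD (the SD recomputed on rule-1/2 survivors, candidate
included); (4) one two-sided Grubbs iteration (α = 0.05) per condition,
rejecting at most one trial. Rule order and the recomputation choice are
documented conventions, not consequences of the definitions. SICI is the
mean conditioned over mean unconditioned amplitude on retained trials;
early/late pre-movement protocols form separate pairs.

# Learning scores

The cued sequence task has 15 blocks of 30 cues; blocks 2–14 repeat a fixed
10-item sequence with per-key counts 3:3:2:2, blocks 1 and 15 are random.
After dropping incorrect presses, anticipatory responses (RT ≤ 0) and — in
a single pass — per-block mean ± 2 SD outliers, the score is the percentage
change in mean RT from block 2 to blocks 10–14. Negative = learning.

The tracing task is scored over time-on-task: trials are assigned to six
bins of equal cumulative movement time; a trial straddling a boundary joins
the bin containing its cumulative-time midpoint (i.e. the bin holding the
majority of the trial). The score is the last-bin minus first-bin mean of
movement time and of absolute angular error.

# Correlation inference

Bivariate outliers are removed per correlation by a bootstrapped
Mahalanobis rule: each point's squared distance is averaged over bootstrap
resamples that do not contain it (about 37% of resamples), so an extreme
point cannot mask itself through the covariance; points are flagged above
the out-of-sample reference quantile. Because centre and covariance are
estimated, that reference is the scaled F distribution
$2\frac{n-1}{n-2}\frac{n+1}{n} F_{2,\,n-2}$ at the 0.975 quantile — the
chi-squared approximation over-flags noticeably at n ≈ 40. Bootstrap count
(1000) and quantile are exposed; results are deterministic given the seed.

The Bayes factor for a nonzero Pearson correlation integrates the
likelihood ratio of the observed $r$ over a stretched-beta prior on $\rho$
of width $\kappa$ ($\kappa = 1$, the common software default, is uniform on
(−1, 1)):

$$\mathrm{BF}_{10} = \int_{-1}^{1}
  \frac{p(r \mid \rho, n)}{p(r \mid 0, n)} \, \pi_\kappa(\rho)\, d\rho,$$

with the exact sampling density of $r$ (involving the Gauss hypergeometric
function $_2F_1(\tfrac12, \tfrac12; n - \tfrac12; (1 + \rho r)/2)$,
evaluated by direct series; its argument stays in [0, 1) and the series
converges fast for n ≥ 5). Quadrature uses adaptive integration at
relative tolerance $10^{-9}$; the test suite cross-checks it against an
independent trapezoid oracle whose $_2F_1$ comes from the Euler integral
representation, to $10^{-6}$ relative. Evidence categories follow the
standard ladder (anecdotal / moderate / strong / very strong / extreme,
for H1 above 1 and H0 below), boundaries assigned to the stronger
category; a Bayes factor of exactly 1 is directionless.

Correlation comparisons Fisher-transform both coefficients. Independent
samples use $z = (z_1 - z_2)/\sqrt{1/(n_1-3) + 1/(n_2-3)}$. For two
correlations sharing a variable within one sample, Steiger's modified z is
used, which requires the correlation between the two non-shared variables —
an explicit argument here, since the statistic is undefined without it.

# Problem sizes and what the tests show

Unit and acceptance tests run the generator at reduced size: 250 Hz
sampling (500 Hz where EMG timing accuracy is itself the quantity under
test, since the 80 ms RMS window needs enough samples for a stable
envelope), 4 + 4 sensor channels, 2×2×2 or 3×3×3 source grids (5×5×5 for
localisation checks), 10–25 trials per subject, 20–40 subjects. These sizes
were chosen so a full population study runs in minutes on one core while
every stage still has enough data to work at its design accuracy; the
defaults of `sim_config()` (1000 Hz, the full 70-trial design) describe the
acquisition-scale setting.

Passing tests show the chain recovers what the generator planted:
frequencies to the 1 Hz grid, sources to one grid step, onsets to the
search granularity, correlations to sampling error. The generator does not
emulate real anatomy or sensor geometry, eye/cardiac artefacts, head
movement, volume-conduction correlations between background sources, or
non-sinusoidal oscillations — so these results bound implementation
correctness, not real-data performance.

# Known limitations

* The beamformer is scalar (fixed orientation); vector orientation
  estimation is not implemented because synthetic sources have known
  orientation.
* Bad-segment masking drops whole 1 s windows; epochs overlapping any
  flagged window are excluded rather than repaired.
* The regularisation floor after PCA rank reduction ($10^{-12}
  \lambda_{max}$) and the vector-orientation question are exposed as
  configuration rather than fixed by evidence.
* Recordings serialise as an RDS + CSV + JSON directory; there is no HDF5
  reader in this implementation.
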