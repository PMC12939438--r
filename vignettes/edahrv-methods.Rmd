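---
title: "Autonomic biosignal features of cancer pain: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Autonomic biosignal features of cancer pain: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edahrv)
```

## Scope

`edahrv` implements a resting-state autonomic biomarker pipeline for
cancer-pain cohorts: per-patient feature extraction from electrodermal
activity (EDA) and single-lead ECG, followed by a nonparametric
group-comparison framework across pain-intensity classes (mild NRS 1–3,
moderate 4–6, severe 7–10) and pain types (nociceptive, neuropathic,
mixed), overall and within clinical strata (bone metastases, breakthrough
cancer pain, morphine-equivalent dose above/below 60 mg/day). A seeded
synthetic cohort generator with full ground truth makes every stage
testable without patient data.

## The EDA model

Skin conductance is modelled as a slow tonic level plus a train of phasic
skin conductance responses (SCRs), each the impulse response of a Bateman
kernel

$$B(t) = \exp(-t/\tau_2) - \exp(-t/\tau_1), \qquad \tau_1 < \tau_2,$$

normalized to unit peak, so that an SCR of amplitude $a$ raises conductance
by exactly $a$ µS at its peak. Defaults $\tau_1 = 0.75$ s, $\tau_2 = 2$ s
are the conventional sudomotor response constants in the deconvolution
literature; the kernel is fixed, not optimized per subject — a deliberate
simplification that keeps the decomposition deterministic and fast.

### Preprocessing

Conductance is low-pass filtered (4th-order Butterworth, 1 Hz, zero-phase
with odd-symmetric reflection padding so that no start/end transients are
introduced) and resampled to 10 Hz. Negative values are clipped at zero;
clipping of more than 1% of samples raises a warning.

### Continuous decomposition analysis (CDA)

The preprocessed signal $s$ is deconvolved with the discretized kernel $K$
under a nonnegativity constraint,

$$\hat d = \arg\min_{d \ge 0} \lVert K d - s \rVert_2^2,$$

solved by FISTA projected gradient with FFT convolutions ($O(n \log n)$
per iteration). Two numerical details matter:

* **Warm start.** The two-pole kernel has an exact 3-tap FIR inverse
  $(1, -(a_1{+}a_2), a_1 a_2)/(a_2{-}a_1)$ with $a_i = e^{-1/(f_s \tau_i)}$,
  advanced by one sample. Starting from this exact inverse, the iterations
  only have to enforce nonnegativity, and convergence typically takes tens
  of iterations rather than thousands.
* **Steady-state initial condition.** A recording starts mid-activity, so
  the pre-recording driver is modelled as the constant level sustaining
  $s(0)$; its decaying contribution is subtracted before deconvolution.
  Without this the solver must synthesize a large start-up impulse and the
  first seconds of the decomposition are meaningless.

The tonic driver is estimated from the driver's inter-impulse baseline:
medians of quiet samples (a robust mask excludes impulse clusters and the
clipped ringing flanking them) on a 10 s grid, interpolated by a smoothing
spline. The tonic conductance component is the reconvolved tonic driver;
the phasic component is the complement, so tonic + phasic reproduces the
preprocessed signal exactly and the solver residual is reported separately.
A grid median over masked quiet samples is used rather than the raw window
minimum because nonnegativity clipping produces exact-zero driver samples
around impulses that would otherwise drag the baseline to zero.

SCRs are scored per driver impulse cluster: onset at the driver rise, peak
at the phasic maximum, amplitude as the phasic rise above the level at
cluster onset; clusters within 1 s merge, and events starting within 2 s of
either recording edge are discarded (filter and deconvolution transients).
The amplitude threshold defaults to 0.05 µS — the conventional minimum SCR
in the skin-conductance literature — and is exposed because it directly
drives the SCR counts.

### Trough-to-peak (TTP) scoring

Each local maximum of the preprocessed signal is paired with its preceding
local minimum; the amplitude is peak minus trough and events are kept when
the amplitude reaches the threshold and the trough-to-peak rise time lies
within 1–5 s (configurable; with the default kernel an isolated SCR rises
in about 1.2 s). When consecutive qualifying peaks share a trough the
larger response is kept.

### Features

For each method (CDA, TTP): the SCR count, max/min/mean amplitude (µS) and
max/min/mean inter-onset interval (s) — fourteen scalars per patient.
"Onset interval" is implemented as the interval between successive onsets
(not onset-to-peak latency), consistent with interval statistics over the
event train; amplitude statistics need at least one event and interval
statistics at least two, otherwise they are encoded as missing (`NA`,
never 0) and dropped pairwise by the statistics layer.

## The HRV model

R peaks are detected with the classic Pan–Tompkins stage chain: 5–15 Hz
band-pass, five-point derivative, squaring, 150 ms moving-window
integration, dual adaptive thresholds with a 200 ms refractory period and
half-threshold search-back for missed beats; accepted integration peaks are
mapped back to the raw R wave. RR intervals outside (0.3, 2.0) s or
deviating more than 30% from the running median of the last five accepted
intervals are dropped (never interpolated) in the time domain.

Time-domain features: mean heart rate (bpm), SDNN (sample SD of RR, ms),
RMSSD (ms). For the frequency domain the RR series is linearly interpolated
to a uniform 4 Hz tachogram, mean-removed, and its PSD estimated by Welch's
method with 60 s Hann segments at 50% overlap — chosen to give at least
two (typically five) segments in a 3-minute recording while still resolving
the 0.04 Hz LF edge. Band powers are trapezoid-integrated over VLF
0.0033–0.04 Hz, LF 0.04–0.15 Hz and HF 0.15–0.36 Hz. The HF upper edge of
0.36 Hz follows the reference analysis even though 0.4 Hz is the more
common convention; VLF limits are the standard ones since the reference
analysis reports VLF power without stating its band. The LF/HF ratio is
missing when HF power is zero. Spectral features require an RR span of at
least 120 s; three-minute recordings are at the short end of what
frequency-domain HRV supports, which is precisely why VLF estimates from
such recordings should be interpreted with caution.

## The statistical framework

Features are screened per group with Shapiro–Wilk (reporting only — the
nonparametric path is always taken). Group comparisons use the
Kruskal–Wallis test on pooled midranks with the tie-correction divisor;
p-values are upper-tail chi-square at $k-1$ degrees of freedom. Post hoc
pairwise comparisons use Dunn's test,

$$z_{ij} = \frac{\bar R_i - \bar R_j}
{\sqrt{\left(\frac{N(N+1)}{12} - \frac{\sum_t (t^3 - t)}{12(N-1)}\right)
\left(\frac{1}{n_i} + \frac{1}{n_j}\right)}},$$

with two-sided normal p-values, both raw and Benjamini–Hochberg-adjusted.
The BH family is the set of pairwise comparisons of one feature under one
grouping (three pairs), not pooled across features — pooling would change
the printed adjusted values this layout reproduces. Group summaries report
the median and the IQR as a single number ($Q_3 - Q_1$). A comparison whose
stratum leaves a group empty, or whose values are all identical (the
tie-corrected statistic is undefined), is reported as not computable rather
than silently skipped.

## The synthetic cohort

The generator emulates the study conditions: 3-minute two-channel
recordings (EDA 100 Hz, ECG 1000 Hz by default; the acquisition board
samples up to 1000 Hz), a 64-patient cohort whose covariate marginals
follow the published cohort table (pain intensity 30.2/25.4/44.4%,
pain type 64.1/21.9/14.1%, BTCP 43.8%, bone metastases 35.9%, MED>60
53.1%). Per patient:

* SCR onsets follow a homogeneous Poisson process thinned to a 1 s minimum
  gap; the rate depends on pain type — defaults 11.7, 13.2 and 1.7
  events/min for nociceptive, neuropathic and mixed pain, chosen so that
  3-minute recordings land near the reported group median counts (about
  35, 39.5 and 5).
* Amplitudes are log-normal (strictly positive, right-skewed like
  empirical SCRs), with the location shifted down for mixed pain and up
  for mild intensity, reproducing the reported effect directions (fewer
  and smaller SCRs in mixed pain; largest maximum amplitudes in mild
  pain). Magnitudes were fixed once from the reported group medians and
  are not tuned.
* The tonic component is a linear drift plus a very-low-frequency
  sinusoid — enough to exercise tonic/phasic separation without
  confounding SCR detection.
* RR intervals are sinusoidally modulated inside the LF (0.1 Hz) and HF
  (0.25 Hz) bands with white jitter; an optional renderer places a fixed
  PQRST template at the cumulative beat times for end-to-end detector
  tests.

What the generator does **not** emulate: motion artifacts, electrode
drift/detachment, respiration coupling, ectopy and arrhythmia (excluded
from the study population), and pathological ECG morphology. Passing
recovery tests on these signals therefore demonstrates correctness of the
algorithms under the stated model, not robustness to every artifact class
of ambulatory recordings.

## Verification problem sizes

The test suite and acceptance script size their simulations as follows:
SCR count/amplitude recovery over 50 synthetic patients (amplitudes
0.2–1.0 µS, gaps ≥ 8 s, noise 0.01 µS); RR recovery over 20 rendered ECGs
at 500 Hz; type-I calibration of the Kruskal–Wallis layer over 2000 null
cohorts of 64 patients (2000 rather than the minimal 500 so that the
binomial error of each per-feature rate is about 0.5%, small against the
±2% acceptance band); and power of the injected mixed-pain deficit over
20 cohorts of 64. On one CPU the whole suite runs in a few minutes.

## Known limitations

* The fixed Bateman kernel biases amplitude estimates when a subject's
  true response shape deviates strongly; the reference CDA method
  optimizes $\tau_1, \tau_2$ per subject and would track this.
* Overlapping SCRs closer than about 2 s merge into one detected event,
  so counts undercount at high SCR rates; both methods undercount
  together, which preserves group contrasts but not absolute rates.
* Three-minute recordings make VLF power and, to a lesser degree, LF power
  statistically fragile; this is a property of the recording protocol, not
  of the estimator.
* The pipeline assumes resting-state stationarity; stimulus-locked SCR
  scoring is out of scope.
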