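---
title: "Methods: state-dependent TMS motor mapping with mepmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: state-dependent TMS motor mapping with mepmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mepmap)
```

## The problem

Transcranial magnetic stimulation (TMS) over the motor cortex hand area
(M1) evokes motor-evoked potentials (MEPs) in hand muscles. At rest this
only works when the coil sits within a centimetre or two of the optimal
scalp site, which is why TMS is usually described as spatially focal.
During natural, goal-directed movement the corticospinal system is far
more excitable: thresholds drop dramatically and MEPs can be evoked from
scalp sites tens of millimetres away from M1 — including nominally
non-motor targets such as the supramarginal gyrus (SMG), roughly 50–55 mm
away along the scalp. Any study that stimulates near M1 during hand
movement therefore risks an unintended motor confound.

`mepmap` implements the full analysis chain for quantifying this
phenomenon: EMG preprocessing and event-related MEP extraction,
orientation-preference circular statistics, interpolated scalp t maps
with contour-area estimation, motor-threshold rules and recruitment
curves, proximity screening against empirical distance cutoffs, electric
field threshold sweeps (consuming externally modeled field tables), and
inverse-distance-weighted MEP volumes. A synthetic-experiment generator
with known ground truth makes every stage testable end to end.

## The generative model

The generator is intentionally the simplest mechanism that reproduces the
four qualitative phenomena the analysis must detect: distance decay,
coil-orientation tuning, state-dependent thresholds, and the coupling of
latency to stimulation intensity. It is phenomenological — one scalar
"drive" per pulse, no volume conductor, no spinal circuit.

For a pulse of intensity $I$ (on a percent-of-maximum-stimulator-output
scale) at scalp position $x$ with induced-current direction $\theta$:

$$\mathrm{drive} = I \; e^{-\|x - x_0\|^2 / 2\sigma^2} \;
  e^{\kappa(\cos(\theta - \theta_0) - 1)}$$

with hotspot $x_0$, spatial decay constant $\sigma$, preferred direction
$\theta_0$ and orientation concentration $\kappa$. The mean MEP amplitude
is a sigmoid of the drive relative to a state-dependent threshold $T$:

$$\bar A = A_{\max}\,\mathrm{logistic}\!\big((\mathrm{drive} - T)/s\big),
\qquad
T = \begin{cases} T_r & \text{rest, isotonic} \\
                  \rho\, T_r & \text{dynamic movement}\end{cases}$$

Trial amplitudes are $\bar A$ times a log-normal factor; onset latency
falls sigmoidally from `latency_max_ms` near threshold to
`latency_min_ms` at saturating drive, plus Gaussian jitter. Background
EMG is band-limited (25–250 Hz) Gaussian noise at a task-specific RMS,
amplitude-modulated at 0.5–3 Hz for the dynamic task to mimic movement
bursts — deliberately non-stationary so that averaging-based background
suppression is exercised against realistic noise.

### Defaults and what anchors them

| parameter | default | anchor |
|---|---|---|
| `active_threshold_ratio` $\rho$ | 0.61 | observed mean active/resting threshold during dexterity tasks |
| `latency_min_ms`, `latency_max_ms` | 21.5, 25.5 | printed extremes of intensity-dependent MEP latencies |
| `rmt_drive` $T_r$ | 55 | typical resting thresholds of 50–70 %MSO |
| `hotspot_xy` | (−52, 5) mm from Cz | mean optimal hand-muscle site, ~5.2 cm lateral, 0.5 cm anterior |
| `theta_pref` | 45° (North-East) | canonical M1-hand coil orientation |
| `sigma_space` | 40 mm | chosen once so that, during movement at ~110 %RMT, effective stimulation reaches ~50 mm from the hotspot while the resting map stays within ~25 mm — the core state-dependency phenomenon |
| `slope` | 1.5 | keeps the 50 µV crossing close to the nominal thresholds so the recovered active/resting ratio reflects $\rho$ |
| `background_rms_mV` | 0.005 / 0.05 / 0.1 | quiet rest baseline; moderate isotonic contraction; strong movement EMG |
| `trial_noise_sigma` | 0.5 | typical log-normal trial-to-trial MEP variability |
| `hotspot_sd_mm`, `rmt_sd` | 7 mm, 5 | between-participant variability; the hotspot SD is a free parameter, not an empirical claim |

The MEP waveform is a damped sinusoid (~10 ms); only its peak-to-peak
amplitude and onset are contractually meaningful. Reproducibility: one
RNG stream per dataset, split per participant by a fixed seed offset, so
any participant's data can be regenerated in isolation.

What the generator does **not** emulate: electrode artifacts, coil click
auditory/startle responses, fatigue and slow excitability drifts,
waveform differences between muscles, and any realistic head geometry.
Passing recovery tests therefore shows the *analysis* is correct and
well-calibrated under the assumed statistical structure, not that the
model is a complete account of real EMG.

## Preprocessing

Offline filtering is a second-order Butterworth band-pass (25–250 Hz)
applied forward and backward. The two-pass scheme squares the magnitude
response and cancels the phase response, which preserves MEP onset
latency — the property that matters downstream. Epochs span −200 to
+200 ms around each trigger, endpoints inclusive (at 5 kHz: 2001
samples); time 0 is the sample nearest the trigger, half-sample ties
resolved toward the earlier sample. Triggers whose window does not fit in
the record are dropped with a warning. Event-related averaging within
(participant × muscle × task × location × orientation × intensity) cells
suppresses background EMG by $\sqrt{n}$ while leaving the pulse-locked
MEP intact; no single trials are discarded beyond edge triggers.

## MEP measures

* **Amplitude**: peak-to-peak of the averaged trace 10–50 ms after the
  pulse, with the matching −50 to −10 ms pre-TMS window as the control
  measure. Normalization divides by the maximum per participant and
  muscle (optionally per task condition — the stricter variant used for
  orientation comparisons); the pre-TMS amplitude is divided by the same
  factor so post/pre contrasts stay comparable.
* **Crossing counts**: the baseline band is mean ± 1.96 SD of the
  −200..−50 ms samples — a tolerance band on sample values, not a
  confidence interval of the mean (the latter would flag nearly every
  sample of any noisy trace and make the contrast trivial). Samples
  outside the band are counted in the post window and the equal-length
  pre window.
* **Automatic latency**: earliest time in (10, 50) ms where the trace
  deviates from the baseline mean by more than `k_sd` baseline SDs
  (default 3) sustained for 2 ms, refined to sub-sample precision by
  linear interpolation of the crossing. Because a *fixed* threshold is
  crossed earlier when MEPs are larger, the onset bias depends on the
  amplitude distribution; for comparisons across conditions with
  different amplitudes a self-scaling `fraction_of_peak` mode (threshold
  at 20 % of the trace's own peak deviation, gated by the detection
  threshold) is provided and used by the matched-latency study. Absence
  of a detectable onset is a value (`NA`), not an error.

## Orientation preference

Each coil orientation contributes a vector of its (normalized) amplitude;
the mean resultant vector is the amplitude-weighted sum divided by the
number of orientations. Equal amplitudes in all directions give length 0;
a single nonzero amplitude of 1 among eight gives length 1/8. Because
ongoing EMG alone produces spurious structure, the pre-TMS resultant
length is subtracted from the post-TMS length. Angles follow the scalp
convention: 0° = East (toward the right preauricular point), 90° = North
(toward the nasion), counterclockwise positive; compass labels snap to
the nearest of eight points with half-way ties going counterclockwise.
Group inference on corrected lengths uses ordinary one-sample t tests on
per-participant values (preference first, statistics second — matching
the repeated-measures structure of the original analyses); no Rayleigh or
V tests are attempted.

## Scalp maps

Per location, a paired t across participants on the post-minus-pre
amplitude contrast (df = n − 1). The t surface is interpolated linearly
on a Delaunay triangulation (via the `interp` package), evaluated on a
1 mm grid clipped to the convex hull — no extrapolation, exact node
reproduction, and no overshoot, so the interpolant cannot create
spurious significant islands. Because the interpolant is a choice the
original analysis does not specify, printed map areas are not expected to
reproduce exactly; areas are interpolation-dependent.

The super-threshold area splits every grid cell into four triangles
against the cell-centre mean and accumulates the exact super-level-set
area of the linear interpolant per triangle — equivalent to marching
squares with the saddle case resolved deterministically, accurate to
sub-cell precision (validated against 0.25 mm pixel counting and an
analytic disc). The default threshold is t = 2.20 (two-tailed 5 % at
df = 11), applied one-sided in the MEP direction. No multiple-comparisons
correction is applied across locations: map locations are spatially
autocorrelated, and inference is carried by focused hypothesis tests at
specific sites, not by the map.

The shipped 27-location layout is an idealized approximation (5×5 grid at
17.5 mm spacing plus two posterolateral extension sites toward SMG); the
true cloth-map geometry exists only as per-participant tables.

## Thresholds and recruitment

`rmt_rossini()` implements the 5-of-10 criterion (≥ 5 of the last 10
trials above 50 µV peak-to-peak); `amt_pegboard()` accepts either that
count or the averaged MEP exceeding 50 µV. Two design decisions matter:

1. **Offline regime reading.** The clinical rules assume monotone
   recruitment and an adaptive hunt. Evaluated offline over a fixed
   intensity ladder, an isolated noise crossing at a sub-threshold
   intensity would capture the estimate, biasing movement-state
   thresholds low (movement background EMG fires the count clause on
   ~30 % of sub-threshold intensities). The default therefore takes the
   lowest intensity *at and above which* the criterion holds for every
   tested intensity — consistent with reporting thresholds as significant
   "at and above" an intensity. The isolated-crossing variant remains
   available (`persistent = FALSE`).
2. **Background-corrected amplitudes during movement.** With 0.1 mV RMS
   movement background, raw post-window peak-to-peak exceeds 50 µV on
   every trial regardless of stimulation. The threshold rules are
   therefore agnostic about the amplitude measure, and the studies feed
   them the post-minus-pre peak-to-peak difference (floored at zero),
   the same post-vs-pre logic used everywhere else in the pipeline.

Recruitment curves aggregate per-participant contrasts into group means
with 95 % CIs per intensity (n reported per point, since detectability
varies), convert intensities to percent of each participant's resting
threshold, and locate the first significant intensity by the same
at-and-above rule (one-sample t, α = 0.05, uncorrected, in the MEP
direction). The matched-amplitude latency comparison selects the
intensity pairs with the most similar group-mean amplitudes among
intensities where at least 10 common participants have measurable
latencies, then runs paired t tests on amplitude and latency; under a
single-source model the latency difference is null.

## Spatial linking

Distances are plain Euclidean: 3-D in MNI space, 2-D in the Cz-referenced
tape-measure plane (no curvature correction — coordinates are scalp mm).
Proximity screening flags targets within 42 mm (brain) or 55 mm (scalp)
of the M1-hand reference — the largest distances at which MEPs were
evoked during natural movement.

The electric-field threshold sweep correlates externally modeled field
magnitudes with mean MEP amplitudes over the pairs at or above each
candidate threshold (0–79 V/m), requiring ≥ 3 remaining pairs and
non-constant values; the best threshold is the smallest attaining the
maximum correlation. A caveat is documented and tested: with very few
remaining points the sample correlation is wildly variable (three points
often correlate near ±1), so single sweeps occasionally return a spurious
best threshold near the top of the range; replicated analyses should
summarize by a robust statistic such as the median. Both a pooled sweep
and per-table sweeps averaged afterwards are possible; the studies use a
pooled 108-pair table (27 locations × 4 orientations) and report means
and medians across replicates.

The inverse-distance-weighted volume uses exponent-1 weights normalized
to sum to one per voxel (a convex combination — otherwise absolute voxel
values would depend on the grid extent), with coincident voxels taking
the site value exactly, then thresholds at the volume mean and rescales
survivors to [0, 1]. Smoothing and MNI warping are out of scope; volumes
are written in native grid coordinates as NIfTI.

## Effects and power

`paired_t()` returns t, df, two-tailed p and the within-participant
effect size $d_z$ = mean/SD. `combine_effects()` is a fixed-effect
inverse-variance mean with $\mathrm{Var}(d) \approx 1/n + d^2/2n$ (the
exact weighting behind published combined effects is not recoverable, so
the method is a labeled knob, with an unweighted alternative).
`sample_size()` defaults to the normal approximation
$n = \lceil ((z_{1-\alpha/2} + z_{\beta})/d)^2 \rceil$ (minimum 2), which
reproduces n = 14 at d = 0.76, α = 0.05, 80 % power; the exact
noncentral-t method is provided and is always at least as conservative.

## Validation strategy and problem sizes

The test suite validates three layers:

* **Oracles**: circular statistics against a complex-sum oracle
  (10⁻¹²), IDW volumes against a per-voxel loop (10⁻¹⁰), interpolation
  against exact affine reproduction (10⁻⁹), contour areas against an
  analytic disc and 0.25 mm pixel counting (2 %), filters against the
  analytic two-pass Butterworth response.
* **Calibration**: paired-t and per-location map tests reject at 5 % ± 1
  percentage point under a simulated null (2,000 replicates, n = 12).
* **Recovery** on generator data at the study scale — 12 simulated
  participants, 10 trials per cell, 20 seeded replicates, EMG synthesized
  at 1 kHz (the low end of the supported range, keeping replicated runs
  affordable): hotspot node recovery, dynamic > rest map area,
  preferred-orientation recovery within ±22.5°, active/resting threshold
  ratio within 0.1 of the configured 0.61, no significant distant-site
  MEPs at rest up to 160 %RMT, and null matched-amplitude latency
  differences under the single-source model (with power against a +3 ms
  offset).

Simulation studies place stimulation sites relative to each simulated
participant's own hotspot, as in individually neuronavigated or
calibrated sessions; the fixed-grid alternative is available for
cloth-map-style designs.

## Known limitations

* The generator's spatial scale is a single Gaussian; with the default
  $\sigma$ the movement-state map reaches ~50 mm, but the simulated
  distant-site onset (~140 %RMT) is higher than the ~104 %RMT reported
  empirically, and the simulated resting map area is detection-limited
  rather than amplitude-limited and so runs larger than the printed
  resting area. Orderings (movement > rest, near > far) are the tested
  claims.
* Latencies from averaged traces carry a jitter-smearing bias (onsets
  detected up to ~1 ms early at high amplitude); the fraction-of-peak
  mode equalizes this across conditions but does not remove it. After
  zero-phase filtering the acausal pre-ringing of large MEPs can trip
  the fixed baseline-SD threshold well before the true onset, so on
  filtered traces the fraction-of-peak mode should be preferred.
* The t-map contour area is interpolation-dependent; only its ordering
  and calibration are asserted.
* No artifact rejection, no notch filtering, no resampling, no
  waveform decomposition, no adaptive threshold staircases, and no
  electric-field computation — field tables are inputs.
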