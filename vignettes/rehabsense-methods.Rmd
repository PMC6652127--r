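---
title: "Methods: from wrist acceleration and beacon RSSI to outcome statistics"
author: "rehabsense"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from wrist acceleration and beacon RSSI to outcome statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rehabsense)
```

## The problem

Patients in subacute rehabilitation wear a smartwatch from morning
(09:00) until evening (18:00). The watch records triaxial acceleration at
16 Hz (±2 g, gravity included) and overhears Bluetooth low-energy (BLE)
beacons mounted at *locations of interest* in the resident room and the
therapy room, each advertising every 250 ms. From these two streams the
package derives, per patient and baseline day, a vector of normalized
activity and location features, and asks which features separate patients
who are eventually re-admitted to hospital from those who return to the
community.

`rehabsense` implements that chain end to end — signal processing, activity
recognition, indoor localization, feature engineering, statistics — plus a
synthetic cohort generator, because clinical sensor streams of this kind are
not publicly available. Everything the statistics layer consumes can
therefore be produced, under a single seed, by the package itself.

## Signal processing

Per sample the **signal magnitude** is the Euclidean norm of the three axes,
$SM = \sqrt{a_x^2 + a_y^2 + a_z^2}$ (g units, gravity included). Magnitudes
are converted to SI units with exactly $1\,g = 9.81\ \mathrm{m/s^2}$; every
threshold below is in SI.

The stream is cut into 10-s windows of 160 samples; consecutive windows
share 1 s of signal (stride 9 s). Windows are anchored to contiguous wear
segments — a window never bridges a non-wear gap — and trailing partial
windows are discarded. Each 160-sample batch is band-pass filtered with a
5th-order Butterworth response, cut-offs 0.5 and 8 Hz, which removes the
gravity (DC) component and out-of-band noise.

Note that at 16 Hz sampling the upper cut-off *is* the Nyquist frequency.
A discretized IIR realization cannot place a band edge there, and a
forward–backward (`filtfilt`) application would square the magnitude
response, turning the −3 dB points into −6 dB points. The filter is
therefore realized in the frequency domain: the FFT of each window is
scaled by the closed-form Butterworth band-pass magnitude

$$|H(f)| = \frac{1}{\sqrt{1 + W(f)^{2n}}},\qquad
W(f) = \frac{f^2 - f_l f_h}{f\,(f_h - f_l)},$$

and inverted. This is zero phase, exactly −3.01 dB at both cut-offs, zero
at DC, and well defined at the Nyquist edge. The tests verify the measured
gain of filtered probe tones against this closed form at 20 frequencies.

The per-window activity quantity is the **mean absolute deviation** (MAD)
of the filtered magnitude, $\frac{1}{n}\sum_i |x_i - \bar x|$. A window is
**active** when its MAD is at or above 0.02 m/s² (2 cm/s²), otherwise
**idle**; equality counts as active. The kinematic reading of the
threshold: a constant 0.02 m/s² sustained from rest over a 10-s window
displaces the wrist by $\tfrac12 a t^2 = 1$ m.

## Activity recognition

Seven features summarize each filtered window: mean, median, variance,
skewness, kurtosis, peak frequency and peak power of the one-sided spectrum
over (0, 8] Hz. Zero-variance windows get skewness and kurtosis 0 by
convention so classifiers accept them.

Recognition is a three-stage hierarchy:

1. **walking vs stationary** — a learned classifier (shallow random forest
   by default; the learner is pluggable by algorithm id);
2. **active vs idle** (stationary windows only) — the fixed MAD threshold,
   not a learned stage, because the threshold is an explicit design
   constant of the processing chain; walking always counts as active;
3. **stand / sit / lay** (stationary windows only) — a learned 3-class
   classifier.

Walking windows carry no posture; this is enforced by construction and by
tests. Sit/stand/lay separation from a wrist sensor is genuinely ambiguous
on real data; on synthetic data the generator gives each posture a distinct
micro-movement frequency band (see below), so the hierarchy's ceiling on
synthetic data is *not* evidence about its ceiling on clinical data. What
the synthetic tests do establish is that the plumbing — feature extraction,
training, the hierarchy's invariants, the evaluation helpers — is correct.

## Indoor localization

Observed RSSI values are clipped into the closed [−100, −50] dBm range
(clipped, not discarded — no discard rule exists for this chain). For each
analysis window the clipped per-beacon values are summarized by their
median — robust against the dropout, multipath and body-absorption noise
BLE suffers — and the beacon with the strongest summary marks the occupied
sublocation; ties break deterministically to the lexicographically smallest
beacon id. Sublocations aggregate to canonical reporting locations
(shower/toilet/sink → bathroom, wall1–3 → wall, numbered beds → the room's
bed) and map to their room. Windows with no events are `unknown`: they stay
in the uptime accounting but are excluded from location-feature
denominators. Nearest-beacon proximity is deliberately simple — no
trilateration or fingerprinting; with beacons a few metres apart it is
identifiable and verifiable.

## Inclusion, baseline day, features

A patient-day qualifies when the watch was worn ≥ 240 min (4 h of the 9-h
protocol) *and* ≥ 15 min of therapy-room wear was recorded; the earliest
qualifying day among the first three admission days is the **baseline
day**, and patients with none are excluded.

Per baseline day the feature taxonomy is:

* **time %** per activity state (walking, standing, sitting, laying, and
  the active overlay) and per location — minutes in the state divided by
  uptime;
* **energy** per window — MAD (cm/s² scale) × the window's time credit —
  summed per state/location;
* **energy intensity** — energy in a state/location divided by the minutes
  spent *in that same state/location* (per-minute intensity). The
  alternative uptime denominator is not used for intensities: per-state
  denominators are the only reading under which walking intensity can
  exceed standing intensity by the observed order of magnitude. The
  uptime-normalized view is retained as the separate energy-% features;
* **energy %** — a state's energy share of total daily energy.

Two accounting conventions matter. First, time percentages use
window-covered minutes (windows × stride) as denominator, so the exclusive
walking/standing/sitting/laying partition sums to exactly 100; wear-mask
uptime (the inclusion quantity) is reported alongside. Second, each window
carries one time credit (the 9-s stride), so state energies, room energies
and total energy are sums over the same disjoint window set and agree
exactly — the tests assert this to 1e-12. Intensities of states that never
occur are *absent* (`NA`), never 0, and group comparisons count
availability per feature.

The energy unit is left uncalibrated (MAD·min on the cm/s² scale): absolute
intensities depend on device and wear position, and no calibration constant
is published for this chain. An intensity cutoff of 90 per minute splits
light from moderate-to-vigorous activity; the boundary value belongs to the
upper band, and the cutoff is configurable.

## Statistics layer

Quantitative features are compared between outcome groups with the
Kruskal–Wallis rank test (tie-corrected, chi-square approximation;
`stats::kruskal.test` underneath, with an all-tied input defined as
$H = 0$); categorical demographics with the Pearson chi-square test, no
continuity correction by default. Effect sizes use Cohen's $d$ with the
*unweighted average-variance* pooling

$$d = \frac{m_1 - m_2}{\sqrt{(s_1^2 + s_2^2)/2}},$$

which is the convention that reproduces the published effect sizes of the
modeled population from their printed group means and SDs (e.g. 1.51 for
standing time %, 1.35 for laying time %, 1.25 for resident-room energy
intensity); sample-size-weighted pooling does not reproduce them at the
9-vs-145 imbalance. Spearman's rho measures feature–feature correlations.
No multiple-testing correction is applied by default, matching the
reporting convention of the field study; a Benjamini–Hochberg adjustment
can be applied downstream with `p.adjust` if desired.

Outcome models are shallow random forests — depth capped at 2 (via the
maximum number of terminal nodes), balanced class weights, fixed random
state 40 — evaluated by stratified 3-fold cross-validation with hospital as
the positive class. Sensitivity is the recall of the hospital minority
class only; specificity the true-negative rate on community; AUC is
computed from out-of-fold class probabilities. Stratification is used
because at 9 hospital cases and 3 folds each fold must inherit ~3 positive
cases for the per-fold metrics to exist at all; folds that nevertheless
lack a positive case are flagged rather than silently dropped.

## The synthetic cohort generator

The generator's defaults are the study conditions, not tuning knobs:

| parameter | default | meaning |
|---|---|---|
| day span | 09:00–18:00 | wear protocol (540 min) |
| sample rate | 16 Hz, ±2 g | wrist accelerometer |
| advertisement interval | 250 ms | beacon cadence |
| RSSI anchor | −66 dBm at 1 ft | line-of-sight calibration |
| path-loss exponent | 2.0 | log-distance model |
| RSSI noise SD | 4 dBm | advertisement-level noise |
| therapy block | ~60 min (SD 8) | one daily session |
| dropout probability | 0.5 | early watch removal per day |
| MAD threshold | 0.02 m/s² | active/idle split |

Group differences are programmed through a **group-effect map**: per-patient
schedule parameters (standing/sitting/laying/walking/active time
percentages; resident-room activity intensity) are drawn from
outcome-specific normal distributions whose means follow the published
community/hospital activity profile of this population — laying dominates
the hospital group (~61% of uptime), standing the community group (~44%),
and the resident-room intensity contrast is programmed at a standardized
difference of 1.25 under a common SD. Each day contains exactly one
therapy-room block; the remaining time is chopped into resident-room dwell
segments (gamma-distributed, ~6 min) whose posture/motion mix follows the
drawn fractions, with walking confined to short standing bouts so that
walking stays below 1% of a typical day.

Waveforms are synthesized per segment: a 1-g gravity vector whose
orientation depends on posture (with small per-segment wobble), a
sinusoidal dynamic component along the gravity axis, and white sensor noise
(0.005 m/s²). Walking oscillates in the 1.5–2.5 Hz cadence band (inside the
filter passband; with a second harmonic); stationary micro-movement sits in
posture-specific bands (lay 0.7–0.9, sit 1.1–1.4, stand 2.9–3.4 Hz) with
idle amplitudes calibrated below, and active amplitudes above, the 0.02
m/s² post-filter MAD threshold. Active amplitude scales with the patient's
drawn resident-room intensity (and with posture: upright movement is the
most vigorous), which makes standing the dominant energy share in community
days, as in the modeled population. RSSI streams place the patient at the
occupied location's beacon plus a ~0.4 m offset and apply the calibrated
log-distance model with Gaussian noise.

What the generator does **not** emulate: realistic gait biomechanics,
radio multipath/diffraction beyond i.i.d. noise, battery effects, device
orientation changes within a posture, or any relation between clinical
covariates and behaviour. Posture separability via distinct frequency bands
is a synthetic convenience (wrist orientation conventions are unpublished),
so recognition accuracies on synthetic data are plumbing checks, not
clinical claims. The wear-time distribution across days is likewise a
stand-in (Bernoulli early removal at 50% plus an occasional mid-day gap),
chosen to reproduce the *kind* of incompleteness the inclusion rules
exist for, not its empirical distribution.

## Numerical and design choices

* "1-second overlap" is read literally: consecutive windows share 1 s
  (stride 9 s). The alternative reading (1-s stride) would inflate window
  counts ninefold; both are available via `windowSec`/`overlapSec`.
* Filtering is applied per 160-sample batch, matching the batch-fed
  processing chain; the FFT realization makes batch filtering exact rather
  than a warm-up-limited approximation.
* MAD is computed on the SI-converted signal so the 2 cm/s² threshold
  applies in its stated unit.
* Degenerate inputs: empty schedules yield empty streams; zero-variance
  windows get moment conventions rather than NaNs; an all-tied rank test is
  $H=0$; intensities over zero minutes are absent markers; an intensity at
  exactly the band cutoff is moderate-to-vigorous.
* Tie-breaks are deterministic everywhere (lexicographic beacon ids;
  p-value ties rank by |d|).
* Determinism: one seed drives cohort generation; identical configurations
  reproduce outputs bit-for-bit at the serialized-CSV level.

## Problem sizes used in the shipped checks

The shipped tests run the full waveform pipeline on a 3-patient, 2-day
cohort (about 100k windows' worth of raw samples), train/evaluate the
hierarchy across days, and exercise the statistical layer with 10,000-run
null calibrations and 200-replicate effect-recovery studies at the study's
154-patient imbalance drawn at the schedule-parameter level. These sizes
were chosen so the whole suite completes in a couple of minutes while
keeping every Monte-Carlo check comfortably powered; scaling the cohort up
changes runtimes, not code paths.

## Known limitations

* Absolute energy scales are uncalibrated; only ratios, percentages and
  standardized differences are comparable across deployments.
* The nearest-beacon rule ignores room geometry beyond beacon placement;
  dense layouts (< ~2 m spacing) would need fingerprinting.
* Published effect sizes are reproduced from printed summaries; a handful
  of printed values for other features are not reproducible from their
  printed means/SDs under any standard pooling and are not asserted.
* The cohort-level AUCs of the modeled study depend on its raw data and are
  out of reach by construction; the model-evaluation layer is validated on
  separable and permuted synthetic features instead.
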