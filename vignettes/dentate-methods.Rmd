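---
title: "Detecting and dissecting dentate spikes and sharp-wave ripples"
author: "dentate package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and dissecting dentate spikes and sharp-wave ripples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Two brief network events dominate the hippocampal local field
potential (LFP) of immobile rodents. Sharp-wave ripples (SPW-R) are
20--200 ms bursts of ~150 Hz oscillation in the CA1 pyramidal layer,
long associated with time-compressed replay of place-cell sequences.
Dentate spikes (DS) are large (> 1 mV), short (< 50 ms) positive
transients recorded in the dentate hilus, and they come in two types
distinguished only by the laminar depth of their current sink: DS1
(outer molecular layer, entorhinal cortex layer II input) and DS2
(middle molecular layer). DS2 in particular is coupled to brain-wide
firing, arousal (pupil dilation, facial movement), and reactivation of
the *current* location rather than a replayed trajectory.

`dentate` implements the complete analysis chain for these events —
detection, current-source-density (CSD) typing, peri-event spiking
statistics with shuffle nulls, brain-wide mutual-information coupling,
Bayesian position decoding with replay-trajectory fitting, and
population-vector similarity — and pairs it with a synthetic-session
generator with full ground truth, so that every stage can be verified
quantitatively at desk scale.

## Detection

DS detection bandpass-filters the hilus channel to 5--100 Hz with a
zero-phase order-3 Butterworth filter (forward–backward; zero phase
preserves peak times, and the input is reflect-padded so filter edge
transients stay outside the analyzed span, which also makes detection
exactly invariant to a DC offset). Local maxima exceeding 4.5 SD of
the filtered trace are DS events: the peak time is the time point at
the maximum, the amplitude is the filtered-trace value there, and the
half-width is measured at half that amplitude on the filtered trace.
The SD is computed over the whole filtered session. Super-threshold
peaks closer than one template width (25 ms) are merged, keeping the
larger, so each physiological event yields one row.

SPW-R detection filters the CA1 pyramidal channel to 120--180 Hz and
takes the envelope as the modulus of the analytic (Hilbert) signal.
Excursions above 3 SD lasting at least 25 ms that contain a peak above
5 SD are events (one per excursion); the ripple time is the maximum
positive value of the filtered trace inside the excursion. The
thresholds are expressed as mean + k·SD **of the envelope**: the
envelope is the quantity being thresholded, so its own statistics are
the natural reference.

Cross-probe synchrony (`coincidence`) matches two event tables
greedily by smallest time difference within 100 ms, each event used at
most once, and reports the synchronous fraction relative to the probe
with fewer events. `evoked_latency` reports, per stimulus onset, the
first DS2 within a strictly post-onset window.

## CSD typing of dentate spikes

`compute_csd` estimates the CSD as the second spatial difference of
voltage across equally spaced channels, sink-negative
(`csd_k = 2 v_k − v_{k−1} − v_{k+1}`), with Vaknin padding (duplicated
boundary channels) so the output covers the full dentate span from the
fissure to the deepest dentate channel. Because the second difference
amplifies independent channel noise — and 1/f background noise puts
most of its power in very slow components that survive differencing —
the voltage is bandpass-filtered to the DS band (5--100 Hz) per channel
before differencing. This is exposed as the `band` argument
(`NULL` = raw voltage; the polynomial-profile oracle tests use that
path, where a depth-linear profile gives exactly zero interior CSD and
a depth-quadratic profile a constant).

`classify_ds` flattens each event's CSD window, normalizes it to unit
Euclidean norm (removing amplitude, preserving shape — this makes
classification exactly invariant to global LFP scaling), projects the
events onto their first two principal components, and clusters the 2-D
scores with DBSCAN. The two largest clusters are mapped to types by
physiology, never by enumeration order: the cluster whose mean CSD
sink sits shallower is DS1 (outer molecular layer), the deeper one
DS2 (middle molecular layer); ties break to the lower mean channel
index. Points in neither cluster are `unclustered`.

DBSCAN's radius defaults to the 95th percentile of the 5-nearest-
neighbour distances of the scores: within a cluster nearly every point
reaches its 5th neighbour inside this radius, while separated clusters
sit many radii apart, so labels are stable across the usable range of
eps (the tests sweep a decade). `min_samples` defaults to 5. Both are
configurable.

## Peri-event firing statistics

Firing rates around each event use 10 ms bins over ±200 ms, centred on
the DS peak or ripple envelope peak. They are z-scored per unit by the
mean and SD of the unit's whole-session rate computed from 100 ms bins
smoothed with a Gaussian filter (sigma = 5 bins). Note a consequence
worth stating: because the standardization SD comes from smoothed
100 ms bins, a 10 ms bin of a Poisson unit has a per-bin z SD of about
13 regardless of rate — individual peri-event z values are legitimately
large, and flatness of a null trace must be judged against its own
standard error (as the tests do). Events with another event *kind*
within 200 ms are excluded first (`exclude_mixed_events`).

The modulation test shuffles each peri-event spike's time uniformly
within the ±200 ms window — the simplest shuffle that preserves
per-event spike counts; a unit is positively modulated if the
maximal bin of its event-averaged rate exceeds the 99.5th percentile
of the shuffled maxima. Because the averaged trace depends only on the
pooled spikes, each shuffle reduces to a single multinomial draw,
which makes thousands of shuffles cheap. Two calibration facts are
documented here deliberately. First, with the nominal 100 shuffles the
empirical 99.5th percentile of 100 maxima is an anticonservative
threshold (exchangeability alone puts the exceedance probability near
1–1.5%); the package therefore leaves `n_shuffles` as a parameter and
the calibration analyses run 2000 shuffles, where the threshold has
converged and the measured type-I error is 0.45–0.5%. Second, with
discrete counts the strict "exceeds" comparison is conservative at low
rates (ties at the threshold); calibration is assessed at a
cortical-like 8 Hz where ties are rare.

High brain-wide firing peaks are bins of the population-average rate
(10 ms bins, all cells pooled) above its 99.9th percentile, one event
per supra-threshold run; coincidence with SPW-R/DS uses a 60 ms
window. The behaviour-change test takes, per event, the post-window
mean minus the pre-window mean of a trace (pupil defaults:
−290…−85 ms before vs −20…+85 ms around the peak; facial:
−140…−40 ms vs +40…+115 ms), builds a pooled null from events shifted
by uniform ±2 s draws, and flags events above the null's 97.5th
percentile (a one-sided increase at two-sided P < 0.05). A practical
caveat the synthetic data makes visible: when every event carries an
identical-amplitude transient at 0.3 Hz density, many ±2 s shifts land
on neighbouring transients and the null cutoff rises towards the
transient amplitude itself; the test's power is therefore assessed on
sparse constructed cases, while its type-I calibration (~2.5% on a
featureless trace) is unaffected.

`dff` fits a cubic polynomial in time as the fluorescence baseline
B(t) and returns (F − B)/B, erroring if the baseline crosses zero;
`event_aligned_z` standardizes event-aligned windows by the preceding
1 s of data.

## Mutual information between regions

Spikes of all units in a region are pooled into 5 ms bins over ±200 ms
around each event (trials), and counts are discretized into four
uniform-count states using empirical quartiles computed over all
trials and bins, with ties assigned to the lower state. (With discrete
counts exact quarter occupancies are impossible — for Poisson-2 counts
the four states carry ~41/27/18/14% of mass; the tests assert the
analytic masses rather than a fictitious 25% each.) Per time bin, the
plug-in mutual information (log base 2) is computed across trials
between two regions' states; the mean over the −200…−100 ms baseline
bins is subtracted to give ΔMI. Significance comes from permuting
whole trials of one region (preserving each region's temporal
structure) with the maximum ΔMI as statistic and the +1-corrected
Monte-Carlo p-value, p < 0.01. The coupling graph keeps pairs that are
significant and observed in at least five sessions, weighted by
maximum ΔMI, and reports the percentage of significant pairs and the
sum of their ΔMI.

## Bayesian decoding and replay

Tuning curves are occupancy-normalized rates in 24 five-cm bins on the
120 cm circular track, restricted to locomotion, with circular
Gaussian smoothing (sigma = 1 bin) and a 0.01 Hz floor applied at
decode time for log-space stability. The decoder assumes independent
Poisson units and a uniform prior:
log P(x|n) = Σ_u [ n_u log(r_u(x)τ) − r_u(x)τ ] + const, normalized to
sum to one; the decoded position is the maximum-probability bin. The
posterior is invariant to a common scaling of all tuning curves.

The current-location test decodes the 20 ms window at each event and
histograms the signed circular error (decoded − actual) in 5 cm bins.
The null circularly shifts each event's decoded position independently
by a uniform draw in ±60 cm (bin multiples), 1000 times, taking each
iteration's maximum bin proportion; observed bins above the null's
97.5th percentile are over-represented. The independent-per-event
reading of "shifted with random values" is essential: a single common
shift per iteration would translate the whole error histogram and
leave its maximum unchanged, making the test powerless.

Candidate population events are maximal runs where the 21 ms
Hanning-smoothed multi-unit activity (1 ms bins) exceeds its mean over
the supplied intervals, with boundaries shrunk inwards to the first
and last spike-containing bin and durations outside 50 ms–2 s (or
fewer than 2 spikes) discarded. Each candidate is decoded in sliding
20 ms windows stepped by 5 ms, and the trajectory slope is fitted by
circular–linear regression on the posterior: for each slope s on a
grid (±3 bins/step, step 0.01, with parabolic refinement around the
grid maximum), the best phase comes in closed form from the
posterior-weighted complex resultant
R(s) = |Σ_{t,x} p[t,x] e^{ia(x − st)}| / Σp with a = 2π/24, and the
goodness of fit is R² = R(s\*)². R² is 1 for a posterior concentrated
on any line — including a stationary one, which is exactly the DS2
signature — and ~0 for a diffuse posterior; fits below R² = 0.3 are
excluded by the caller. On full synthetic sessions the per-event slope
estimate carries a noise floor of roughly 25 cm/s (posterior jitter
over ~26 steps), so recovery is summarized by the correlation between
fitted and injected slopes (r > 0.9 at the default conditions), with
the exact-recovery property checked on constructed posteriors.

Place cells for decoding may be selected by Skaggs spatial information
against a circular time-shift null (95th percentile), one standard
choice among the field's many place-cell inclusion criteria; the
decoder itself accepts any unit set.

## Population patterns

Population vectors count each unit's spikes in the 200 ms window
centred on each DS2 and normalize per unit by its maximum count; units
with session mean rate above 5 Hz or silent in all windows are
excluded. Pearson correlation and cosine similarity are computed over
all event pairs, with a null that independently permutes each unit's
event axis. Units and events are ordered by agglomerative clustering
with Euclidean distance and Ward linkage (`ward.D2` on Euclidean
distances). Stimulus identity (tone vs puff, or evoked vs spontaneous)
is classified by a perceptron (zero initialization, fixed presentation
order, learning rate 1, at most 100 epochs — deterministic given the
fold split) under stratified 10-fold cross-validation, with an
empirical p from 1000 label permutations using the ≥ convention that
includes the observed arrangement.

## The synthetic generator

The generator is the package's acceptance surface: its defaults are
the conditions every recovery claim is made under.

* **Session**: 600 s, 16 channels at 50 µm spacing, 1250 Hz; roughly
  60% immobility in alternating bouts (12–18 s immobile, 8–12 s
  locomotion at 15 cm/s with 1 s ramps) on a 120 cm circular track.
* **Events**: independent Poisson counts per kind over the immobile
  time (DS2 0.3 Hz, DS1 0.05 Hz, SPW-R 0.3 Hz), placed uniformly in
  immobility (0.5 s margins) with a 250 ms minimum separation between
  any two events, enforced by resampling so the per-kind counts remain
  exactly Poisson.
* **DS template**: a raised-cosine (Hann) temporal bump of 25 ms full
  width (so 12.5 ms width at half amplitude, under the < 50 ms
  description) whose laminar profile is *defined in CSD space* — a
  Gaussian sink at the configured molecular-layer channel with a
  balancing source two channels below, integrated twice to voltage
  with a zero superficial boundary. The double integration leaves a
  positive plateau on all channels below the dipole, reproducing the
  hilus-positive signature, and the profile is normalized so the hilus
  channel carries the configured 2 mV amplitude. Because the truth is
  defined in CSD space, classification ground truth is exact.
* **SPW-R template**: a 150 Hz cosine under a 60 ms Hann envelope
  (0.25 mV) on the pyramidal channel, with a slow negative sharp-wave
  deflection on the radiatum channels below.
* **Noise**: 1/f-shaped Gaussian noise, 0.1 mV SD per channel, plus a
  30% common-mode component (which cancels in the CSD).
* **Spikes**: inhomogeneous Poisson on a 1 ms rate grid; 60 units of
  which 50 are CA1 place cells (circular Gaussian tuning, sigma
  10 cm, peak 10–25 Hz, baseline 0.5–2 Hz, active during locomotion).
  Event-kind gains (DS2: 5× on half the units; SPW-R: 3× on 30%)
  follow a 100 ms Hann kernel. During each SPW-R the place cells fire
  along an injected trajectory (uniform |speed| 100–400 cm/s, random
  sign and start, 150 ms duration, 50 Hz ridge peak); during each DS2,
  place cells whose preferred position is near the animal's current
  position receive a 40 Hz reactivation bump — the stationary
  counterpart of replay.
* **Arousal**: pupil diameter is an Ornstein–Uhlenbeck process
  (tau 2 s, SD 0.2) plus a 0.5 a.u. transient starting 40 ms before
  each DS2 peak (during the event's rising phase, so the −20…+85 ms
  window sees the plateau while the −290…−85 ms window stays clear)
  with a 1 s decay; facial motion receives a similar transient 30 ms
  after the peak.

What the generator does **not** emulate: theta and its phase coupling,
gamma, spike waveforms and sorting errors, probe drift, non-Poisson
spiking (bursting, refractoriness), behavioural diversity beyond the
bout structure, and sleep states. Passing recovery tests on this data
therefore demonstrates the correctness of the analysis chain under its
own stated assumptions — thresholds, nulls and estimators do what they
claim on data of known structure — not robustness to every failure
mode of real recordings.

All randomness flows from a single session seed through named
substreams (behaviour, events, LFP, spikes, and one per shuffle
procedure), so any stage can be reproduced in isolation and the full
pipeline is byte-deterministic in (session bytes, config, seed).

## Problem sizes used in validation

The shipped tests and the acceptance script run, among other things:
detection and classification on 600 s sessions (~125 DS + ~105 SPW-R
each; classification pooled over ten seeded sessions); modulation-test
calibration on 2000 null units at 8 Hz with 200 events and 2000
shuffles, and power on 150 five-fold-gain units; the MI null level
over 300–400 independent region pairs at 300 shuffles; decoder checks
against brute-force Poisson enumeration on all instances up to 3 units
and 5 bins, and a median locomotion decoding error below 10 cm with 50
place cells; replay-slope recovery over ~90 injected events (r > 0.9);
and null calibrations of the behaviour-change (~2.5%) and
decoding-error (~2.5% family-wise) shuffles. These sizes were chosen
so each claim has useful statistical resolution while a full run
remains a desk-scale computation.

## Known limitations

* The CSD estimator is the plain second spatial difference; an inverse
  (iCSD) estimator could be added behind the same interface but the
  simple estimator already separates sink depths cleanly.
* The hilus, pyramidal and fissure channels are caller-specified (with
  `theta_power_by_channel` as a ranking helper); there is no automatic
  channel selection.
* Plug-in MI is biased upwards on finite trials; the shuffle null
  absorbs the bias for significance, but ΔMI magnitudes on few trials
  should be compared only within matched trial counts.
* The perceptron is the stated model class for stimulus decoding; no
  attempt is made at stronger classifiers.
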