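---
title: "Methods: contactless vital-sign monitoring from FMCW radar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contactless vital-sign monitoring from FMCW radar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radarvitals)
```

## The measurement model

A frequency-modulated continuous-wave (FMCW) radar mounted at the foot end
of a bed transmits chirps whose frequency sweeps over a band; the beat
signal of each chirp, Fourier-transformed along the ADC-sample axis, splits
the space in front of the antenna into range bins roughly 0.05 m deep. With
the radar at an oblique angle, different body segments fall into different
bins: breathing moves the thorax and abdomen by 1--5 mm and appears in bins
farther from the radar; the heartbeat moves the body surface by only
0.287--0.568 mm and appears in bins nearer to it. Both motions modulate the
*phase* of the reflected carrier: a radial displacement $d$ changes the
two-way path by $2d$, so the phase moves by

$$\varphi = \frac{4\pi}{\lambda}\, d, \qquad \lambda = c / f_c \approx
5\ \mathrm{mm\ at\ 60\ GHz},$$

and one wavelength of displacement corresponds to a $4\pi$ phase excursion.
`phaseToDisplacement()` inverts this relation.

Each frame groups 20 chirps acquired at a 20 Hz frame rate. The per-frame
phase of every bin is summarised by the *chirp median*: the 20 per-chirp
phase angles are wrap-aligned to the first chirp (shifted by multiples of
$2\pi$ into $\pm\pi$ of it — a plain median fails at the $\pm\pi$ boundary)
and the ordinary median (mean of the 10th and 11th order statistics) is
taken. The resulting one-sample-per-frame series is unwrapped over time,
giving a 20 Hz displacement series per range bin
(`chirpMedianPhase()`, `rangeTransform()`).

The radar configuration quotes a 0.05 m resolution, 64 ADC samples and a
2.56 m maximal range; these three numbers are mutually inconsistent
(64 × 0.05 = 3.2 m), so the package treats the retained bin count as
configuration with a default of 52 bins (2.6 m) and makes no attempt to
derive it. Range bin $k$ (0-based) is taken to start at
$k \times 0.05$ m; a bin-centre convention would shift all distances by
2.5 cm without changing any result in this package.

## Motion detection and epoch exclusion

Body movements (turning, limb motion) swamp the millimetre-scale vital
signals, and high motion is itself an indicator of wakefulness. A Doppler
FFT — the DFT along the 20 chirps of one frame — resolves velocity per
range bin. The per-epoch motion parameter follows five steps exactly:
per-frame Doppler FFT; reduction to a velocity profile by summing cell
*magnitudes* over range bins (complex sums would allow phase cancellation
between bins); clutter removal by subtracting each velocity bin's median
over the epoch's frames; a Hamming taper across velocity bins in unshifted
FFT order, so the zero-Doppler bin and its wrap-around neighbour receive
the window's minimal weight and slow clutter is suppressed; and summation
over all cells. A perfectly static epoch scores exactly 0, and negative
post-subtraction cells are kept so that the statistic stays unbiased around
the clutter level.

The parameter is computed on 60 s epochs advanced in 5 s steps (55 s
overlap), smoothed with a centred 5-min moving average (61 epochs at the
5 s spacing, truncated at the edges), and epochs whose smoothed value
*strictly* exceeds the overnight mean are excluded. Two consequences are
worth noting. First, on a quiet, stationary night the mean threshold still
excludes roughly half of the epochs, because the smoothed parameter
fluctuates around its mean; an overnight-mean threshold is designed for
recordings in which genuine wake movement dominates the mean. Second, a
rate epoch is discarded when its interval overlaps *any* excluded motion
epoch; with the shared 60 s/5 s grid each excluded epoch vetoes its
23 overlapping neighbours, which makes the exclusion conservative.
`retainedEpochs()` implements this interval semantics.

Recordings are first cropped to the 22:00--06:00 sleep window
(`cropWindow()`), crossing midnight, before any epoching.

## Rate estimation

**Breathing** (`breathingRate()`): linear detrend, biased normalised
autocorrelation, then the first local maximum with prominence at least
0.15 whose lag lies in $[60/30, 60/6]$ s; the rate is $60/\mathrm{lag}$.
A cycle-consistency check recomputes the rate on the two epoch halves and
rejects the epoch when either half has no peak or the halves disagree by
more than 2 breaths/min — this is what keeps apnoeic or fragmented epochs
from producing a rate. The lag grid is the native 20 Hz sample grid with no
interpolation, a deliberate quantisation floor of
$60 f_s^{-1}/\mathrm{lag}^2$ BPM at the true lag (about 0.05 BPM at
15 BPM). Quality is half the peak prominence (prominence ranges over
$[0,2]$ for a normalised autocorrelation), so clean signals score near 1
without saturating against narrowband noise.

**Heartbeat** (`heartRate()`): zero-phase fifth-order Butterworth band-pass
at 0.667--2.5 Hz (the 40--150 beats/min bounds), peak detection with a
minimum inter-peak distance of $60/150$ s and an adaptive
median + MAD amplitude threshold, parabolic (three-point) refinement of
peak positions, rate $= 60/\mathrm{median(IBI)}$. Epochs are rejected when
fewer than 20 beats per minute are found, when the inter-beat-interval
coefficient of variation exceeds 0.25, when the rate leaves the bounds, or
when the epoch's dominant spectral frequency lies *above* the band — the
last guard prevents a fast out-of-band oscillation from aliasing through
the minimum-distance peak picking as a plausible in-band rate. The
parabolic refinement removes most of the 20 Hz sampling quantisation
(about 1.4 BPM at 72 BPM on the raw grid).

The physiological bounds — 6--30 breaths/min and 40--150 beats/min — are
deliberately wide for an elderly clinical population and are ordinary
configuration (`rateBounds()`).

**Reference channels** (`referenceRates()`): a respiratory-effort waveform
runs through the identical breathing estimator; an ECG runs through a
classical derivative--energy R-peak detector (differentiate, square,
150 ms moving-window integration, median + MAD threshold) followed by the
identical IBI logic, so radar and reference rates share every rejection
rule. A minimal EDF reader/writer (`readEDF()`, `writeEDF()`) covers plain
16-bit EDF exports.

## Range-bin selection

**Single selection** (`selectSingle()`) ranks bins by temporal phase
coherence: the epoch is split into $K$ sub-windows, the DFT phase at the
epoch's dominant in-band frequency is measured in each on a common clock,
and the coherence is $\lvert \frac1K \sum_k e^{i\theta_k}\rvert$. Rates are
computed for the five best bins and the highest-quality one wins
(autocorrelation prominence for breathing, $1-\mathrm{CV}$ for heartbeat;
ties go to the lower bin index, i.e. nearer the radar). Three
implementation choices matter:

* Coherence is ranked on the *raw* (detrended) signal. The dominant-
  frequency restriction already band-limits the statistic; pre-filtering
  the signal instead makes pure-noise bins narrowband and therefore
  spuriously phase-coherent, destroying the ranking contrast.
* The dominant-frequency selection biases the white-noise coherence
  upward: with a fixed frequency the sub-window phasors are uniform and
  the expected resultant is the Rayleigh mean $\sqrt{\pi}/(2\sqrt K)$
  ($\approx 0.36$ at $K=6$), but choosing the largest spectral bin
  conditions the phasors on a large resultant, and the measured white-noise
  mean is near 0.67 at $K=6$. The `tpc()` default stays $K = 6$; the
  recording-level driver ranks with $K = 20$. The noise ceiling falls
  roughly as $1/\sqrt K$, while a vital-sign bin keeps a coherence near or
  above 0.5 even on an epoch that straddles a rate-track step (its phasors
  then form two clusters rather than a uniform spread), so finer
  sub-windows widen the ranking margin precisely on the hardest epochs.
* Breathing rates for the ranked bins are estimated on the band-limited
  signal, so heartbeat content sharing a bin cannot masquerade as a
  harmonic breathing peak.

Single selection is deliberately permissive — it ranks rather than rejects,
so rates are produced for most epochs, including some from bins that carry
no vital signal at all; those estimates are the method's documented error
source.

**Multiple selection** (`selectMultiple()`) accepts every bin whose
band-limited epoch signal has the *shape* of a vital sign, in the
persistence-homology sense, and fuses the accepted bins' rates by their
median:

* Dimension-0 sublevel-set persistence (`sublevelDiagram()`, union-find
  with the elder rule, ties by index): every oscillation cycle contributes
  a finite pair whose persistence is the cycle's peak-to-trough excursion.
  A bin is a candidate only when the number of pairs with persistence at
  least $\tau$ falls in the cycle-count range implied by the rate bounds
  (for a 60 s epoch: 6--30 breathing cycles, 40--150 heart cycles, widened
  by a small slack).
* For breathing, the signal must additionally trace a loop: the
  analytic-signal (Hilbert) phase-plane embedding $(x, \mathcal{H}x)$,
  decimated by a fractional stride to at most 56 points, is fed to a
  Vietoris--Rips filtration (`ripsDiagram()`, boundary-matrix reduction
  over GF(2) with bitset columns) and the strongest 1-cycle must satisfy
  $\mathrm{death}/\mathrm{birth} \ge \rho_{\min}$. A delay embedding with
  an integer lag was tried first and abandoned: at the decimated sampling
  rate the admissible lags quantise the phase offset so coarsely that the
  loop collapses whenever the breathing rate is commensurate with the
  decimated grid (measured ratios near 1 at several rates in 6--30 BPM);
  the analytic embedding gives an exact quarter-period offset at every
  in-band frequency. `delayEmbed()` remains available and tested.
* Heart-rate selection uses the sublevel criterion only; the Rips step
  costs far more than everything else and adds little for the spike-like
  cardiac waveform.

The thresholds ($\tau = 0.6$ mm breathing / $0.2$ mm heartbeat, count slack
2/3, $\rho_{\min} = 1.5$, 56-point clouds) were calibrated once on the
labelled synthetic scene with `scripts/calibrate_thresholds.R` — the
largest thresholds keeping true-bin acceptance above 90% with zero
noise-bin accepts — and are exposed as configuration
(`multipleThresholds()`). $\tau$ is an *absolute* displacement floor,
which is what makes the method strict: a weakly coupled heartbeat episode
whose cycles fall below $\tau$ is rejected outright, while the single
method's relative (median + MAD) threshold still reads it. This one
asymmetry produces the characteristic pattern: multiple selection has
lower coverage, especially for heartbeats, but what it accepts is accurate;
single selection covers more epochs at the price of occasional rates from
meaningless bins.

## Agreement evaluation

`agreementReport()` compares per-epoch reference and radar rates over a
shared grid: recall (the fraction of analyzed epochs with a computed rate,
reported per side with counts), MAE, MAPE (reference in the denominator),
Spearman correlation (Pearson on mid-ranks), the fraction of complete pairs
with error strictly below 1 BPM, the uncovered duration (the measure of the
analyzed axis not covered by the union of rate-bearing epoch intervals —
with 55 s overlap this is *not* the rate-less epoch count times the step),
and Bland--Altman statistics (differences are reference minus radar;
limits are mean $\pm 1.96$ sample SD; the percentages strictly outside
each limit are reported). Undefined metrics propagate as `NA`, never as 0,
so aggregate tables cannot silently absorb empty recordings. Rounding to
two decimals happens only at presentation.

## The synthetic bed scene

`simulateScene()` generates the full radar cube for a configurable scene,
deterministically from a seed:

* **Geometry.** Heartbeat motion in bins 8--12 (0.35--0.6 m, nearer the
  radar), breathing in bins 18--26 (0.85--1.3 m), matching a foot-end
  mounting where the chest is farther from the antenna than the torso
  front.
* **Waveforms.** Breathing is an asymmetric raised-cosine cycle (inhale
  35% of the period), the heartbeat a narrow systolic spike over a quarter
  of the cycle — non-sinusoidal on purpose, so the shape criteria are
  exercised; amplitudes are drawn per bin from 1--5 mm and
  0.287--0.568 mm (half-amplitudes; the peak-to-peak excursion is twice
  the draw).
* **Rate tracks.** Piecewise-constant per 2-min block with bounded jumps
  (±2 breaths, ±5 beats), multiplied by a beat-scale jitter bounded at 2%.
  The per-epoch ground truth is the *median* instantaneous rate over the
  epoch — the faithful counterpart of median-interval estimators; a
  mean-based truth would impose a shared error floor on every epoch that
  straddles a block boundary which no selection method could reduce.
* **Heartbeat coupling envelope.** The cardiac displacement is multiplied
  by a slow AR(1)-driven envelope in $[0.15, 1]$ (logistic-squashed,
  ~2-min correlation): the mechanical coupling of the heartbeat to the bed
  waxes and wanes with posture. This is what gives the night its
  mixed-quality character — episodes where the heartbeat is weak but clean
  sit exactly in the band where the strict gate rejects and the permissive
  estimator still succeeds.
* **Clutter that mimics vital signs.** Bins 30--34 carry non-vital
  oscillations that share the vital-sign bands without their shape:
  breathing-band "bedding flutter" (narrowband Gaussian noise, 0.5--1 mm,
  which has neither a stable phase-plane loop nor a regular cycle-count)
  and a weak heart-band mechanical resonance (0.10--0.17 mm, below the
  persistence floor of a genuine heartbeat, with a slowly wandering
  phase). These bins are what separates the two selection philosophies:
  coherence ranking will sometimes trust them, the shape and amplitude
  gates of the persistence method reject them. A fixture without such
  spectrally plausible distractors would make ranking look artificially
  reliable.
* **Nuisances.** A static reflector in every bin, per-bin linear baseline
  drift, frame-level phase noise, complex per-chirp sample noise, a small
  breathing leakage (0.15 mm) into the heartbeat bins, independent in-band
  micro-vibration on every body bin (per-bin SD drawn from 0.02--0.1 mm;
  this is the error component that median fusion across accepted bins can
  suppress and a single chosen bin cannot escape), and optional whole-body
  motion bursts whose per-chirp micro-phase follows the frame-to-frame
  velocity, so the Doppler motion parameter sees them.
* **Variants.** The default scene is a calm 30-min night.
  `noisyScene()` is a *restless* night: whole-body bursts every 5 min,
  5-fold drift, doubled sample noise, the same phase-noise floor. The
  phase-noise floor is kept clean on purpose: in-band noise above roughly
  $\tau/4$ per sample *lifts* weak heartbeat cycles past the absolute
  persistence threshold (an extreme-value effect on per-cycle excursions)
  and would paradoxically make the strict method more permissive than the
  ranking method.

`simulateReference(truth, jitter)` produces per-epoch reference rates plus
a respiratory-effort waveform and an ECG-like impulse train consistent with
them, so the reference path can be exercised end to end (including through
EDF files).

What the simulator does *not* model: multipath and moving clutter,
antenna-pattern and range-dependent SNR roll-off, posture changes that
relocate body segments across bins mid-night, arrhythmic beats, apnoeas,
and bed-exit intervals. Passing the synthetic acceptance suite therefore
demonstrates correctness of the processing chain and the qualitative
method contrast, not clinical performance.

## Problem sizes and numerical choices

The shipped test and acceptance runs use 30-minute scenes (349 epochs of
60 s at 5 s steps, 52 range bins, 20 chirps per frame at 20 Hz — about
37 M complex samples per scene), which exercise every stage at full width
while a complete clean-plus-restless evaluation finishes in a few minutes.
Sublevel persistence and the chirp-median are compiled; the Rips reduction
uses bitset columns over the edge filtration; Rips is only reached by bins
that already passed the (cheap) sublevel count gate. Tie-breaks are by
index everywhere (filtration order, coherence ranking, quality choice), so
every stage is deterministic; reruns with the same seed are identical.
Filtering uses zero-phase `signal::filtfilt` with fifth-order Butterworth
designs; epochs shorter than two sub-windows, constant series and empty
selections all return explicit "no rate" values rather than errors.

## Known limitations

* The temporal-phase-coherence ranking collapses on epochs in which the
  rate changes by more than about one cycle over the window (a 1 BPM
  breathing step or any realistic heart-rate step); on such epochs single
  selection falls back to whatever noise bin ranks highest, which is the
  main source of its larger errors.
* The mean-threshold motion exclusion over-excludes on quiet nights (see
  above); a bed-presence or sleep-staging front end would be the proper
  fix.
* The multiple-selection thresholds are absolute displacements calibrated
  on the synthetic scene; clinical radars with different gain or noise
  floors would need the calibration sweep rerun.
* Uncovered-duration and recall figures are computed on the analyzed axis
  (after cropping and motion exclusion); they are not comparable across
  recordings with different exclusion fractions.

```{r example, eval = FALSE}
# A complete small run:
scene <- sceneConfig(seed = 1, durationS = 600,
                     config = radarConfig(nRangeBins = 16, chirpsPerFrame = 8),
                     heartbeatBins = 4:6, breathingBins = 9:13)
sim <- simulateScene(scene)
res <- runPipeline(sim$cube, reference = sim$truth,
                   config = pipelineConfig(crop = FALSE))
res$reports$multiple_breathing$mae
```
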