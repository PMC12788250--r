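# radarvitals

Contactless breathing- and heart-rate monitoring from FMCW radar sleep
recordings.

A 60 GHz frequency-modulated continuous-wave (FMCW) radar at the foot end
of a bed resolves the space in front of it into ~5 cm range bins and sees
body-surface motion as phase modulation of the reflected carrier: breathing
moves the thorax by 1–5 mm in bins farther from the radar, the heartbeat
moves the body surface by 0.287–0.568 mm in bins nearer to it
(displacement d ↔ phase φ = 4π d / λ, λ ≈ 5 mm). This package implements
the full overnight processing chain for such recordings and is aimed at
researchers in contactless physiological monitoring who want a complete,
testable reference pipeline:

* **Radar front end** — range transform, chirp-median phase summarisation
  (median of the 20 per-chirp phases per frame, wrap-aligned), temporal
  unwrapping, and phase→displacement conversion, giving a 20 Hz
  displacement series per range bin.
* **Motion exclusion** — a Doppler-FFT motion parameter per 60 s epoch
  (55 s overlap), 5-min moving-average smoothing, and exclusion of epochs
  above the overnight mean; recordings are cropped to the 22:00–06:00
  sleep window first.
* **Range-bin selection**, the scientific core, in two flavours:
  *single* selection ranks bins by temporal phase coherence
  (|mean of sub-window phasors| at the epoch's dominant in-band frequency)
  and keeps the highest-quality of the top five; *multiple* selection
  accepts every bin whose band-limited signal has the *shape* of a vital
  sign under persistence homology — the 0-dimensional sublevel-set diagram
  must show the right number of sufficiently persistent cycles, and for
  breathing the phase-plane embedding must carry a strong 1-dimensional
  Vietoris–Rips loop — then fuses the accepted bins' rates by their
  median. Single selection is permissive (high coverage, occasional
  nonsense); multiple selection is strict (lower coverage, accurate when
  it speaks).
* **Rate estimation** — autocorrelation breathing rates (6–30 BPM) with a
  half-epoch consistency check, peak-detection heart rates (40–150 BPM)
  with inter-beat-interval regularity gating; the same estimators serve
  the reference polysomnography channels (respiratory effort, ECG via a
  derivative–energy R-peak detector; minimal EDF I/O included).
* **Agreement evaluation** — MAE, MAPE, Spearman correlation, per-side
  recall with counts, the <±1 BPM ratio, uncovered duration under epoch
  overlap, and Bland–Altman limits of agreement.
* **A synthetic bed scene** — a deterministic simulator producing full
  radar cubes with ground-truth rate tracks, spatially separated body
  segments, motion bursts, drift, noise, and non-vital oscillatory clutter,
  so every stage is testable without clinical data.

The persistence-homology primitives (union-find sublevel filtration,
Vietoris–Rips boundary reduction) are implemented in compiled code inside
the package and are cross-checked against brute-force oracles in the test
suite.

## Worked example

Simulate a 10-minute scene on a 16-bin radar (heartbeat in bins 4–6,
breathing in bins 9–13) and run the full pipeline against the simulator's
own ground truth:

```r
library(radarvitals)

cfg <- radarConfig(nRangeBins = 16, chirpsPerFrame = 8)
scene <- sceneConfig(seed = 3, durationS = 600, config = cfg,
                     heartbeatBins = 4:6, breathingBins = 9:13)
sim <- simulateScene(scene)
sim$cube
#> RadarCube: 12000 frames x 8 chirps x 16 bins, start 2026-01-01 23:00:00 (600.0 s)

res <- runPipeline(sim$cube, reference = sim$truth,
                   config = pipelineConfig(crop = FALSE))
res
#> PipelineResult: 109 epochs, 39 retained after motion exclusion
#>   single_breathing     39 epochs with a rate
#>   multiple_breathing   39 epochs with a rate
#>   single_heartbeat     39 epochs with a rate
#>   multiple_heartbeat   28 epochs with a rate

r <- res$reports$multiple_breathing
round(c(mae = r$mae, recall_pct = r$recall_radar$percent,
        rho = r$spearman_rho), 3)
#>        mae recall_pct        rho
#>      0.032    100.000      0.933
```

Reading the output: of the 109 overlapping 60 s epochs, 39 survive the
motion-based exclusion. Both selection methods produce a breathing rate for
every retained epoch here, but the strict multiple method produces a heart
rate for 28 epochs against 39 for the permissive single method — the
characteristic coverage gap, since the ~0.3 mm heartbeat repeatedly falls
below the persistence gate while the ranking method still reads it. The
multiple-selection breathing rates differ from the true track by 0.03 BPM
on average (MAE) with rank correlation 0.93.

The methods vignette (`vignettes/radar-vitals-methods.Rmd`) documents the
model, every tunable parameter, the design decisions and the simulator's
scope; `inst/exec/radarvitals` provides a command-line front end
(`simulate`, `convert`, `motion`, `select`, `rates`, `evaluate`, `run`).

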