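## Bed-scene simulator: radar cubes with ground-truth breathing/heart-rate
## tracks, spatially separated body-segment motion, phase noise, baseline
## drift and whole-body motion bursts; plus synthetic reference channels.

#' Synthetic bed-scene configuration
#'
#' Describes a radar at the foot end of a bed: breathing motion (1--5 mm
#' half-amplitude) concentrated in range bins farther from the radar,
#' heartbeat motion (0.287--0.568 mm) in bins nearer the radar, additive
#' phase noise, per-bin baseline drift and optional whole-body motion
#' bursts. Rate tracks are piecewise-constant per `trackBlockS` block with
#' bounded jumps and are perturbed by a slow rate jitter of up to 2%.
#'
#' @slot seed RNG seed; the simulation is deterministic given the seed.
#' @slot durationS scene duration (s).
#' @slot config the [RadarConfig-class] of the simulated radar.
#' @slot heartbeatBins range-bin indices carrying heartbeat motion
#'   (proximal: nearer the radar than the breathing bins).
#' @slot breathingBins range-bin indices carrying breathing motion (distal).
#' @slot artifactBins range-bin indices carrying non-vital oscillatory
#'   clutter (bedding flutter in the breathing band, a weak mechanical
#'   resonance in the heartbeat band) that shares spectral characteristics
#'   with the vital signs without their shape.
#' @slot breathingAmpMm half-amplitude range (mm), default `c(1, 5)`.
#' @slot heartbeatAmpMm half-amplitude range (mm), default
#'   `c(0.287, 0.568)`.
#' @slot breathingTrackBpm optional fixed piecewise-constant track (one
#'   value per block); empty = drawn from the seed within 6--30 BPM.
#' @slot heartTrackBpm as above, within 40--150 BPM.
#' @slot trackBlockS rate-track block length (s).
#' @slot phaseNoiseSdRad frame-level phase noise SD (rad).
#' @slot noiseSd additive complex sample noise SD (per chirp).
#' @slot driftMmPerMin baseline drift scale (mm/min).
#' @slot vibrationMmRange range of the per-bin body-surface micro-vibration
#'   SD (mm); fusion across bins suppresses this independent component.
#' @slot motionBursts `data.frame(start_s, duration_s, amplitude_mm)` of
#'   whole-body motion bursts.
#' @export
setClass("SceneConfig", representation(
  seed = "integer",
  durationS = "numeric",
  config = "RadarConfig",
  heartbeatBins = "integer",
  breathingBins = "integer",
  artifactBins = "integer",
  breathingAmpMm = "numeric",
  heartbeatAmpMm = "numeric",
  breathingTrackBpm = "numeric",
  heartTrackBpm = "numeric",
  trackBlockS = "numeric",
  phaseNoiseSdRad = "numeric",
  noiseSd = "numeric",
  driftMmPerMin = "numeric",
  vibrationMmRange = "numeric",
  motionBursts = "data.frame"
))

setValidity("SceneConfig", function(object) {
  msg <- character()
  if (length(object@heartbeatBins) && length(object@breathingBins) &&
      max(object@heartbeatBins) >= min(object@breathingBins))
    msg <- c(msg, "heartbeat bins must lie nearer the radar than breathing bins")
  if (max(c(object@heartbeatBins, object@breathingBins,
            object@artifactBins, 0)) > object@config@nRangeBins)
    msg <- c(msg, "body bins exceed the configured range-bin count")
  if (length(intersect(object@artifactBins,
                       c(object@heartbeatBins, object@breathingBins))))
    msg <- c(msg, "artifact bins must be disjoint from body bins")
  if (length(msg)) msg else TRUE
})

#' Construct a scene configuration
#'
#' Defaults describe a 30-minute night-time scene with the package's default
#' radar configuration, heartbeat motion in bins 8--12 (0.35--0.6 m) and
#' breathing motion in bins 18--26 (0.85--1.3 m), mild phase noise and no
#' motion bursts.
#'
#' @param seed RNG seed.
#' @param durationS scene duration (s).
#' @param config a [RadarConfig-class].
#' @param heartbeatBins,breathingBins body-segment bin indices.
#' @param artifactBins non-vital oscillatory clutter bins; `NULL` places
#'   them in bins 30--34 when the configuration has room, otherwise none.
#'   Pass `integer()` to disable explicitly.
#' @param breathingAmpMm,heartbeatAmpMm half-amplitude ranges (mm).
#' @param breathingTrackBpm,heartTrackBpm optional fixed rate tracks.
#' @param trackBlockS rate-track block length (s).
#' @param phaseNoiseSdRad frame-level phase noise SD (rad).
#' @param noiseSd additive complex noise SD.
#' @param driftMmPerMin baseline drift scale (mm/min).
#' @param vibrationMmRange per-bin micro-vibration SD range (mm).
#' @param motionBursts burst table `data.frame(start_s, duration_s,
#'   amplitude_mm)`.
#' @return A [SceneConfig-class].
#' @export
sceneConfig <- function(seed = 1, durationS = 1800, config = radarConfig(),
                        heartbeatBins = 8:12, breathingBins = 18:26,
                        artifactBins = NULL,
                        breathingAmpMm = c(1, 5),
                        heartbeatAmpMm = c(0.287, 0.568),
                        breathingTrackBpm = numeric(),
                        heartTrackBpm = numeric(),
                        trackBlockS = 120,
                        phaseNoiseSdRad = 0.05,
                        noiseSd = 0.1,
                        driftMmPerMin = 0.3,
                        vibrationMmRange = c(0.02, 0.1),
                        motionBursts = data.frame(start_s = numeric(),
                                                  duration_s = numeric(),
                                                  amplitude_mm = numeric())) {
  if (is.null(artifactBins))
    artifactBins <- if (config@nRangeBins >= 34) 30:34 else integer()
  new("SceneConfig", seed = as.integer(seed), durationS = durationS,
      config = config, heartbeatBins = as.integer(heartbeatBins),
      breathingBins = as.integer(breathingBins),
      artifactBins = as.integer(artifactBins),
      breathingAmpMm = breathingAmpMm, heartbeatAmpMm = heartbeatAmpMm,
      breathingTrackBpm = breathingTrackBpm, heartTrackBpm = heartTrackBpm,
      trackBlockS = trackBlockS, phaseNoiseSdRad = phaseNoiseSdRad,
      noiseSd = noiseSd, driftMmPerMin = driftMmPerMin,
      vibrationMmRange = vibrationMmRange, motionBursts = motionBursts)
}

#' @describeIn sceneConfig a restless-night variant of the default scene:
#'   periodic whole-body motion bursts, stronger baseline drift and sample
#'   noise, emulating the disturbed sleep that motivates motion exclusion.
#' @export
noisyScene <- function(seed = 1, durationS = 1800, config = radarConfig()) {
  burstStarts <- seq(150, durationS - 60, by = 300)
  sceneConfig(seed = seed, durationS = durationS, config = config,
              phaseNoiseSdRad = 0.05, noiseSd = 0.1, driftMmPerMin = 1.5,
              motionBursts = data.frame(
                start_s = burstStarts,
                duration_s = rep(12, length(burstStarts)),
                amplitude_mm = rep(25, length(burstStarts))))
}

# asymmetric raised-cosine breathing cycle, peak-to-peak 2: the inhale
# (rising limb) takes `inhaleFrac` of the cycle, the exhale the rest
.breathWave <- function(psi, inhaleFrac = 0.35) {
  u <- psi %% 1
  g <- ifelse(u < inhaleFrac, u / (2 * inhaleFrac),
              0.5 + (u - inhaleFrac) / (2 * (1 - inhaleFrac)))
  -cos(2 * pi * g)
}

# heartbeat cycle: narrow systolic spike over `spikeFrac` of the cycle,
# flat diastole; peak-to-peak 2
.heartWave <- function(psi, spikeFrac = 0.25, sharp = 3) {
  u <- psi %% 1
  s <- ifelse(u < spikeFrac,
              (0.5 * (1 - cos(2 * pi * u / spikeFrac)))^sharp, 0)
  2 * s - 1
}

# piecewise-constant rate track with bounded jumps, one value per frame
.rateTrack <- function(n, fr, blockS, fixed, lo, hi, startRange, jumpMax) {
  nBlocks <- ceiling(n / (blockS * fr))
  if (length(fixed)) {
    vals <- rep(fixed, length.out = nBlocks)
  } else {
    vals <- numeric(nBlocks)
    vals[1] <- stats::runif(1, startRange[1], startRange[2])
    for (i in seq_len(nBlocks - 1))
      vals[i + 1] <- min(hi, max(lo, vals[i] +
                                   stats::runif(1, -jumpMax, jumpMax)))
  }
  rep(vals, each = blockS * fr)[seq_len(n)]
}

# slow amplitude envelope in [lo, hi]: posture and coupling changes make the
# effective vital-sign displacement wax and wane over minutes
.slowEnvelope <- function(n, fr, lo, hi, knotS = 15, phi = 0.9) {
  nk <- max(3L, ceiling(n / (knotS * fr)) + 1L)
  z <- numeric(nk)
  z[1] <- stats::rnorm(1)
  innov <- stats::rnorm(nk - 1, 0, sqrt(1 - phi^2))
  for (k in 2:nk) z[k] <- phi * z[k - 1] + innov[k - 1]
  level <- 1 / (1 + exp(-1.2 * z))             # logistic squash to (0, 1)
  tk <- seq(0, n - 1, length.out = nk)
  lo + (hi - lo) * stats::approx(tk, level, xout = 0:(n - 1))$y
}

# beat-scale multiplicative rate jitter, bounded by `frac`
.rateJitter <- function(n, fr, frac = 0.02) {
  w <- max(1L, round(1 * fr))
  z <- as.numeric(stats::filter(stats::rnorm(n + 2 * w), rep(1 / w, w),
                                sides = 2))[(w + 1):(w + n)]
  z[is.na(z)] <- 0
  if (stats::sd(z) > 0) z <- z / (3 * stats::sd(z))
  1 + frac * pmin(1, pmax(-1, z))
}

#' Simulate a bed scene
#'
#' Generates a radar cube and aligned ground truth, deterministically from
#' the scene seed. Per-bin displacement is the assigned quasi-sinusoidal
#' vital motion (asymmetric raised-cosine cycles with bounded rate jitter)
#' plus baseline drift and burst transients; displacement is converted to
#' phase by the inverse of [phaseToDisplacement()] and embedded as complex
#' samples whose per-chirp micro-phase follows the frame-to-frame velocity
#' (so [dopplerMap()] sees bursts), with additive complex noise.
#'
#' @param scene a [SceneConfig-class].
#' @param startTime wall-clock start of the recording.
#' @return List with `cube` (a [RadarCube-class]), `truth` (a `data.frame`
#'   of per-epoch true breathing/heart BPM -- the median instantaneous rate
#'   over the epoch, the counterpart of the median-interval estimators --
#'   and a motion flag, aligned to the default 60 s / 5 s [epochGrid()]),
#'   and `tracks` (per-frame true rates).
#' @export
simulateScene <- function(scene,
                          startTime = as.POSIXct("2026-01-01 23:00:00",
                                                 tz = "UTC")) {
  oldSeed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv()))
  set.seed(scene@seed)

  cfg <- scene@config
  fr <- cfg@frameRateHz
  n <- round(scene@durationS * fr)
  nb <- cfg@nRangeBins
  nc <- cfg@chirpsPerFrame
  t <- (seq_len(n) - 1) / fr

  rateB <- .rateTrack(n, fr, scene@trackBlockS, scene@breathingTrackBpm,
                      6, 30, c(12, 16), 2) * .rateJitter(n, fr)
  rateH <- .rateTrack(n, fr, scene@trackBlockS, scene@heartTrackBpm,
                      40, 150, c(55, 72), 5) * .rateJitter(n, fr)
  psiB <- cumsum(rateB / 60) / fr
  psiH <- cumsum(rateH / 60) / fr

  # slow amplitude envelope: the mechanical coupling of the heartbeat to
  # the bed surface waxes and wanes with posture; breathing, a far larger
  # motion, stays fully coupled
  envH <- .slowEnvelope(n, fr, 0.15, 1)
  disp <- matrix(0, n, nb)                              # mm
  for (b in scene@breathingBins) {
    amp <- stats::runif(1, scene@breathingAmpMm[1], scene@breathingAmpMm[2])
    disp[, b] <- amp * .breathWave(psiB + stats::runif(1, 0, 0.05))
  }
  for (b in scene@heartbeatBins) {
    amp <- stats::runif(1, scene@heartbeatAmpMm[1], scene@heartbeatAmpMm[2])
    disp[, b] <- amp * envH * .heartWave(psiH + stats::runif(1, 0, 0.05)) +
      0.15 * .breathWave(psiB)                          # breathing leakage
  }
  # oscillatory clutter sharing the vital-sign bands without their shape:
  # breathing-band bedding flutter (narrowband Gaussian, no stable loop or
  # cycle structure) and a weak heart-band mechanical resonance whose
  # amplitude sits below the persistence floor of a genuine heartbeat
  nArt <- length(scene@artifactBins)
  for (i in seq_len(nArt)) {
    b <- scene@artifactBins[i]
    if (i <= ceiling(nArt * 0.6)) {
      flutter <- .bandPass(stats::rnorm(n), fr, c(0.18, 0.5), order = 2)
      disp[, b] <- disp[, b] +
        stats::runif(1, 0.5, 1.0) * flutter / stats::sd(flutter)
    } else {
      f0 <- stats::runif(1, 0.9, 2.4)
      wander <- cumsum(stats::rnorm(n, 0, 0.05))
      disp[, b] <- disp[, b] + stats::runif(1, 0.10, 0.17) *
        sin(2 * pi * f0 * t + wander)
    }
  }
  # per-bin body-surface micro-vibration: independent in-band noise on the
  # body bins (sd drawn per bin), the component that median fusion across
  # accepted bins can actually suppress
  for (b in c(scene@breathingBins, scene@heartbeatBins)) {
    sdV <- stats::runif(1, scene@vibrationMmRange[1],
                        scene@vibrationMmRange[2])
    ar <- stats::rnorm(n)
    for (k in 2:n) ar[k] <- 0.7 * ar[k - 1] + ar[k]
    disp[, b] <- disp[, b] + sdV * ar / stats::sd(ar)
  }
  # per-bin baseline drift
  slopes <- stats::runif(nb, -1, 1) * scene@driftMmPerMin
  disp <- disp + outer(t / 60, slopes)
  # whole-body motion bursts: smooth random-walk displacement on body bins
  bodyBins <- sort(unique(c(scene@heartbeatBins, scene@breathingBins)))
  reflective <- sort(unique(c(bodyBins, scene@artifactBins)))
  bursts <- scene@motionBursts
  for (i in seq_len(nrow(bursts))) {
    idx <- which(t >= bursts$start_s[i] &
                   t < bursts$start_s[i] + bursts$duration_s[i])
    if (length(idx) < 2) next
    walk <- cumsum(stats::rnorm(length(idx)))
    walk <- walk - seq(walk[1], walk[length(walk)],
                       length.out = length(idx))    # return to baseline
    peak <- max(abs(walk), 1e-9)
    for (b in bodyBins)
      disp[idx, b] <- disp[idx, b] + bursts$amplitude_mm[i] * walk / peak
  }

  lambdaM <- .C_LIGHT / cfg@carrierFreqHz
  theta <- disp / 1000 * (4 * pi / lambdaM) +
    matrix(stats::rnorm(n * nb, 0, scene@phaseNoiseSdRad), n, nb)
  phi0 <- matrix(stats::runif(nb, 0, 2 * pi), n, nb, byrow = TRUE)
  # per-chirp micro-phase consistent with the frame's velocity
  dtheta <- rbind(diff(theta), 0)
  ampBin <- rep(0.8, nb)
  ampBin[reflective] <- 1
  samples <- array(0i, dim = c(n, nc, nb))
  for (ci in seq_len(nc)) {
    ph <- phi0 + theta + dtheta * (ci - 1) / nc
    noise <- complex(real = stats::rnorm(n * nb, 0, scene@noiseSd),
                     imaginary = stats::rnorm(n * nb, 0, scene@noiseSd))
    samples[, ci, ] <- matrix(rep(ampBin, each = n) * exp(1i * ph) + noise,
                              n, nb)
  }
  cube <- radarCube(samples, cfg, startTime)

  grid <- epochGrid(scene@durationS)
  truth <- data.frame(
    epoch = seq_len(nEpochs(grid)),
    start_s = grid@epochStarts,
    breathing_bpm = vapply(grid@epochStarts, function(s)
      stats::median(rateB[t >= s & t < s + grid@windowS]), numeric(1)),
    heart_bpm = vapply(grid@epochStarts, function(s)
      stats::median(rateH[t >= s & t < s + grid@windowS]), numeric(1)),
    motion = vapply(grid@epochStarts, function(s)
      any(bursts$start_s < s + grid@windowS &
            bursts$start_s + bursts$duration_s > s), logical(1)))
  list(cube = cube,
       truth = truth,
       tracks = data.frame(t = t, breathing_bpm = rateB, heart_bpm = rateH))
}

#' Simulate reference channels consistent with a ground truth
#'
#' Builds per-epoch reference rates (`truth +/- N(0, jitter^2)` applied as a
#' slow modulation of the underlying rate tracks) together with a
#' respiratory-effort waveform and an ECG-like impulse train consistent with
#' those rates, so that [referenceRates()] recovers them.
#'
#' @param tracks per-frame rate tracks as returned by [simulateScene()].
#' @param jitterBpm SD of the reference-rate deviation from truth (BPM).
#' @param fsEffort,fsEcg sampling rates of the synthetic waveforms (Hz).
#' @param grid the [EpochGrid-class] the per-epoch rates are reported on;
#'   defaults to the 60 s / 5 s grid over the track duration.
#' @param seed RNG seed for the jitter and waveform noise.
#' @return List with `rates` (`data.frame(epoch, breathing_bpm,
#'   heart_bpm)`), `effort` and `ecg` (`list(fs, signal)`).
#' @export
simulateReference <- function(tracks, jitterBpm = 0, fsEffort = 32,
                              fsEcg = 128, grid = NULL, seed = 1) {
  stopifnot(jitterBpm >= 0)
  oldSeed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv()))
  set.seed(seed)

  durS <- max(tracks$t) + diff(tracks$t[1:2])
  if (is.null(grid)) grid <- epochGrid(durS)
  frIn <- 1 / diff(tracks$t[1:2])

  jitterize <- function(rate) {
    if (jitterBpm == 0) return(rate)
    nBlocks <- ceiling(durS / 120)
    dev <- rep(stats::rnorm(nBlocks, 0, jitterBpm), each = 120 * frIn)
    rate + dev[seq_along(rate)]
  }
  rateB <- jitterize(tracks$breathing_bpm)
  rateH <- jitterize(tracks$heart_bpm)

  resample <- function(rate, fs) {
    tNew <- seq(0, durS - 1 / fs, by = 1 / fs)
    stats::approx(tracks$t, rate, xout = tNew, rule = 2)$y
  }
  rB <- resample(rateB, fsEffort)
  psiB <- cumsum(rB / 60) / fsEffort
  effort <- 10 * .breathWave(psiB) +
    0.5 * sin(2 * pi * 0.01 * seq_along(psiB) / fsEffort) +
    stats::rnorm(length(psiB), 0, 0.05)

  rH <- resample(rateH, fsEcg)
  psiH <- cumsum(rH / 60) / fsEcg
  beats <- which(diff(floor(psiH)) == 1)
  ecg <- 0.15 * sin(2 * pi * 0.08 * seq_along(psiH) / fsEcg) +
    stats::rnorm(length(psiH), 0, 0.01)
  halfw <- max(1L, round(0.012 * fsEcg))
  for (bt in beats) {
    idx <- max(1, bt - halfw):min(length(ecg), bt + halfw)
    ecg[idx] <- ecg[idx] + exp(-0.5 * ((idx - bt) / (halfw / 2))^2)
  }

  t <- tracks$t
  rates <- data.frame(
    epoch = seq_len(nEpochs(grid)),
    breathing_bpm = vapply(grid@epochStarts, function(s)
      stats::median(rateB[t >= s & t < s + grid@windowS]), numeric(1)),
    heart_bpm = vapply(grid@epochStarts, function(s)
      stats::median(rateH[t >= s & t < s + grid@windowS]), numeric(1)))
  list(rates = rates,
       effort = list(fs = fsEffort, signal = effort),
       ecg = list(fs = fsEcg, signal = ecg))
}
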