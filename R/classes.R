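## Central S4 containers: radar acquisition configuration, raw radar cube,
## per-bin displacement series, epoch grid, motion series, persistence
## diagram, bin selection, and rate bounds.

#' Radar acquisition configuration
#'
#' Describes the FMCW radar acquisition geometry: carrier frequency, sweep
#' bandwidth, range resolution, chirps per frame, frame rate, ADC samples per
#' chirp and the number of range bins kept after the range transform. Under
#' this package's convention the maximal range equals
#' `nRangeBins * rangeResolutionM` and range bin `k` (0-based) starts at
#' distance `k * rangeResolutionM`.
#'
#' @slot carrierFreqHz carrier frequency in Hz.
#' @slot bandwidthHz sweep bandwidth in Hz.
#' @slot rangeResolutionM range-bin depth in metres.
#' @slot chirpsPerFrame chirps acquired per frame.
#' @slot frameRateHz frame rate in Hz (the displacement sampling rate).
#' @slot adcSamplesPerChirp ADC samples per chirp.
#' @slot nRangeBins number of range bins kept.
#' @slot maxRangeM maximal range in metres (`nRangeBins * rangeResolutionM`).
#' @export
setClass("RadarConfig", representation(
  carrierFreqHz = "numeric",
  bandwidthHz = "numeric",
  rangeResolutionM = "numeric",
  chirpsPerFrame = "integer",
  frameRateHz = "numeric",
  adcSamplesPerChirp = "integer",
  nRangeBins = "integer",
  maxRangeM = "numeric"
))

setValidity("RadarConfig", function(object) {
  msg <- character()
  if (object@chirpsPerFrame < 1L) msg <- c(msg, "chirpsPerFrame must be >= 1")
  if (object@frameRateHz <= 0) msg <- c(msg, "frameRateHz must be > 0")
  if (object@nRangeBins < 1L) msg <- c(msg, "nRangeBins must be >= 1")
  if (object@adcSamplesPerChirp < 1L) msg <- c(msg, "adcSamplesPerChirp must be >= 1")
  if (abs(object@maxRangeM - object@nRangeBins * object@rangeResolutionM) >
      1e-9 * max(1, object@maxRangeM))
    msg <- c(msg, "maxRangeM must equal nRangeBins * rangeResolutionM")
  if (length(msg)) msg else TRUE
})

#' Construct a radar configuration
#'
#' Defaults describe a 60 GHz FMCW radar sweeping 60-63 GHz with 0.05 m range
#' resolution, 20 chirps per frame at a 20 Hz frame rate and 64 ADC samples
#' per chirp. The number of retained range bins is exposed as configuration
#' (default 52, i.e. a 2.6 m maximal range at 0.05 m resolution) rather than
#' derived from the ADC sample count.
#'
#' @param carrierFreqHz carrier frequency (Hz).
#' @param bandwidthHz sweep bandwidth (Hz).
#' @param rangeResolutionM range resolution (m).
#' @param chirpsPerFrame chirps per frame.
#' @param frameRateHz frame rate (Hz).
#' @param adcSamplesPerChirp ADC samples per chirp.
#' @param nRangeBins number of range bins kept after the range transform.
#' @return A [RadarConfig-class] object.
#' @examples
#' cfg <- radarConfig()
#' maxRange(cfg)
#' @export
radarConfig <- function(carrierFreqHz = 60e9,
                        bandwidthHz = 3e9,
                        rangeResolutionM = 0.05,
                        chirpsPerFrame = 20,
                        frameRateHz = 20,
                        adcSamplesPerChirp = 64,
                        nRangeBins = 52) {
  new("RadarConfig",
      carrierFreqHz = as.numeric(carrierFreqHz),
      bandwidthHz = as.numeric(bandwidthHz),
      rangeResolutionM = as.numeric(rangeResolutionM),
      chirpsPerFrame = as.integer(chirpsPerFrame),
      frameRateHz = as.numeric(frameRateHz),
      adcSamplesPerChirp = as.integer(adcSamplesPerChirp),
      nRangeBins = as.integer(nRangeBins),
      maxRangeM = as.numeric(nRangeBins) * as.numeric(rangeResolutionM))
}

#' @describeIn radarConfig maximal range of a configuration (m).
#' @param config a [RadarConfig-class].
#' @export
maxRange <- function(config) config@maxRangeM

#' @describeIn radarConfig number of range bins.
#' @export
nRangeBins <- function(config) config@nRangeBins

#' @describeIn radarConfig frame rate (Hz).
#' @export
frameRate <- function(config) config@frameRateHz

setMethod("show", "RadarConfig", function(object) {
  cat("RadarConfig:", object@carrierFreqHz / 1e9, "GHz carrier,",
      object@chirpsPerFrame, "chirps/frame @", object@frameRateHz, "Hz,",
      object@nRangeBins, "range bins x", object@rangeResolutionM, "m (max",
      object@maxRangeM, "m)\n")
})

#' Radar cube: complex samples indexed frame x chirp x range bin
#'
#' The raw substrate of the pipeline after the range transform: one complex
#' sample per (frame, chirp, range bin). Frame `i` (1-based) is acquired at
#' `startTime + (i - 1) / frameRate`.
#'
#' @slot config the [RadarConfig-class] the cube was acquired with.
#' @slot samples complex array `[frame, chirp, range_bin]`.
#' @slot startTime wall-clock time of the first frame (`POSIXct`).
#' @export
setClass("RadarCube", representation(
  config = "RadarConfig",
  samples = "array",
  startTime = "POSIXct"
))

setValidity("RadarCube", function(object) {
  d <- dim(object@samples)
  msg <- character()
  if (length(d) != 3L) msg <- c(msg, "samples must be a 3-d array")
  else {
    if (d[2] != object@config@chirpsPerFrame)
      msg <- c(msg, "chirp dimension inconsistent with config")
    if (d[3] != object@config@nRangeBins)
      msg <- c(msg, "range-bin dimension inconsistent with config")
  }
  if (!is.complex(object@samples)) msg <- c(msg, "samples must be complex")
  if (length(object@startTime) != 1L) msg <- c(msg, "startTime must be length 1")
  if (length(msg)) msg else TRUE
})

#' Construct a radar cube
#'
#' @param samples complex array `[frame, chirp, range_bin]`.
#' @param config a [RadarConfig-class] consistent with the array dimensions.
#' @param startTime wall-clock time of the first frame.
#' @return A [RadarCube-class].
#' @export
radarCube <- function(samples, config,
                      startTime = as.POSIXct("2026-01-01 23:00:00", tz = "UTC")) {
  storage.mode(samples) <- "complex"
  new("RadarCube", config = config, samples = samples,
      startTime = as.POSIXct(startTime))
}

#' @describeIn radarCube number of frames in a cube.
#' @param cube a [RadarCube-class].
#' @export
nFrames <- function(cube) dim(cube@samples)[1]

#' @describeIn radarCube frame timestamps (`POSIXct`).
#' @export
frameTimes <- function(cube) {
  cube@startTime + (seq_len(nFrames(cube)) - 1) / cube@config@frameRateHz
}

setMethod("show", "RadarCube", function(object) {
  d <- dim(object@samples)
  cat("RadarCube:", d[1], "frames x", d[2], "chirps x", d[3], "bins,",
      "start", format(object@startTime, "%Y-%m-%d %H:%M:%OS"),
      sprintf("(%.1f s)\n", d[1] / object@config@frameRateHz))
})

#' Per-range-bin displacement (or phase) time series
#'
#' One real value per frame and range bin, sampled at the radar frame rate.
#' Units are radians (unwrapped phase) straight after chirp-median
#' summarisation, or millimetres after [phaseToDisplacement()].
#'
#' @slot config the originating [RadarConfig-class].
#' @slot values real matrix `[frame, range_bin]`.
#' @slot samplingRateHz sampling rate, equal to the config's frame rate.
#' @slot units `"rad"` or `"mm"`.
#' @slot startTime wall-clock time of the first sample.
#' @export
setClass("DisplacementSeries", representation(
  config = "RadarConfig",
  values = "matrix",
  samplingRateHz = "numeric",
  units = "character",
  startTime = "POSIXct"
))

setValidity("DisplacementSeries", function(object) {
  msg <- character()
  if (!object@units %in% c("rad", "mm"))
    msg <- c(msg, 'units must be "rad" or "mm"')
  if (abs(object@samplingRateHz - object@config@frameRateHz) > 1e-9)
    msg <- c(msg, "samplingRateHz must equal config frame rate")
  if (ncol(object@values) != object@config@nRangeBins)
    msg <- c(msg, "range-bin dimension inconsistent with config")
  if (length(msg)) msg else TRUE
})

displacementSeries <- function(values, config, units,
                               startTime = as.POSIXct("2026-01-01 23:00:00",
                                                      tz = "UTC")) {
  new("DisplacementSeries", config = config, values = values,
      samplingRateHz = config@frameRateHz, units = units,
      startTime = as.POSIXct(startTime))
}

setMethod("show", "DisplacementSeries", function(object) {
  cat("DisplacementSeries:", nrow(object@values), "samples x",
      ncol(object@values), "bins @", object@samplingRateHz, "Hz [",
      object@units, "]\n")
})

#' @describeIn displacementValues sampling rate of a displacement series (Hz).
#' @export
samplingRate <- function(series) series@samplingRateHz

#' Accessors for displacement series
#'
#' @param series a [DisplacementSeries-class].
#' @return `displacementValues`: the `[frame, bin]` matrix;
#'   `displacementUnits`: `"rad"` or `"mm"`; `samplingRate`: Hz.
#' @export
displacementValues <- function(series) series@values

#' @describeIn displacementValues units flag.
#' @export
displacementUnits <- function(series) series@units

#' Epoch grid: sliding analysis windows
#'
#' Epochs of `windowS` seconds advanced by `stepS` seconds (defaults 60 s
#' windows with a 5 s step, i.e. 55 s overlap).
#'
#' @slot windowS epoch length (s).
#' @slot stepS step between epoch starts (s).
#' @slot epochStarts start times of the epochs (s, relative to the start of
#'   the analyzed recording).
#' @export
setClass("EpochGrid", representation(
  windowS = "numeric",
  stepS = "numeric",
  epochStarts = "numeric"
))

setValidity("EpochGrid", function(object) {
  msg <- character()
  if (object@stepS <= 0 || object@stepS > object@windowS)
    msg <- c(msg, "need 0 < stepS <= windowS")
  if (is.unsorted(object@epochStarts, strictly = TRUE) &&
      length(object@epochStarts) > 1)
    msg <- c(msg, "epochStarts must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Construct an epoch grid covering a recording
#'
#' The number of epochs is `floor((durationS - windowS) / stepS) + 1` when
#' `durationS >= windowS` and 0 otherwise; epochs never extend past the end
#' of the recording.
#'
#' @param durationS recording duration (s).
#' @param windowS epoch length (s), default 60.
#' @param stepS step between epochs (s), default 5 (55 s overlap).
#' @return An [EpochGrid-class].
#' @examples
#' length(epochStarts(epochGrid(300))) # 49
#' @export
epochGrid <- function(durationS, windowS = 60, stepS = 5) {
  n <- if (durationS >= windowS) floor((durationS - windowS) / stepS) + 1 else 0
  new("EpochGrid", windowS = windowS, stepS = stepS,
      epochStarts = if (n > 0) (seq_len(n) - 1) * stepS else numeric())
}

#' @describeIn epochGrid epoch start times (s).
#' @param grid an [EpochGrid-class].
#' @export
epochStarts <- function(grid) grid@epochStarts

#' @describeIn epochGrid number of epochs.
#' @export
nEpochs <- function(grid) length(grid@epochStarts)

setMethod("show", "EpochGrid", function(object) {
  cat("EpochGrid:", length(object@epochStarts), "epochs of", object@windowS,
      "s, step", object@stepS, "s\n")
})

#' Per-epoch motion parameter with exclusion mask
#'
#' Holds the raw Doppler-FFT motion parameter per epoch, its 5-min moving
#' average, the overnight-mean threshold and the exclusion mask
#' (`excluded[n]` iff `smoothed[n] > threshold`, strictly).
#'
#' @slot grid the [EpochGrid-class] the parameter was computed on.
#' @slot raw raw per-epoch motion parameter.
#' @slot smoothed moving-average-smoothed parameter.
#' @slot threshold overnight mean of `smoothed`.
#' @slot excluded logical exclusion mask.
#' @export
setClass("MotionSeries", representation(
  grid = "EpochGrid",
  raw = "numeric",
  smoothed = "numeric",
  threshold = "numeric",
  excluded = "logical"
))

setValidity("MotionSeries", function(object) {
  msg <- character()
  n <- length(object@grid@epochStarts)
  if (length(object@raw) != n || length(object@smoothed) != n ||
      length(object@excluded) != n)
    msg <- c(msg, "raw, smoothed and excluded must match the grid length")
  if (n > 0 && !identical(object@excluded,
                          object@smoothed > object@threshold))
    msg <- c(msg, "excluded must equal smoothed > threshold")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MotionSeries", function(object) {
  cat("MotionSeries:", length(object@raw), "epochs,",
      sum(object@excluded), "excluded (threshold",
      signif(object@threshold, 4), ")\n")
})

#' @describeIn motionSeries exclusion mask accessor.
#' @param motion a [MotionSeries-class].
#' @export
excludedEpochs <- function(motion) motion@excluded

#' @describeIn motionSeries motion threshold accessor.
#' @export
motionThreshold <- function(motion) motion@threshold

#' Persistence diagram
#'
#' Finite (birth, death, dim) triples plus essential classes (birth, dim)
#' that never die, summarising the topology of a filtration. Produced by
#' [sublevelDiagram()] (dimension 0 of the sublevel-set filtration of a 1-D
#' series) and [ripsDiagram()] (Vietoris--Rips up to dimension 1).
#'
#' @slot pairs `data.frame` with columns `birth`, `death`, `dim`
#'   (`death > birth` for every row).
#' @slot essential `data.frame` with columns `birth`, `dim`.
#' @export
setClass("PersistenceDiagram", representation(
  pairs = "data.frame",
  essential = "data.frame"
))

setValidity("PersistenceDiagram", function(object) {
  msg <- character()
  if (!all(c("birth", "death", "dim") %in% names(object@pairs)))
    msg <- c(msg, "pairs needs columns birth, death, dim")
  else if (nrow(object@pairs) && any(object@pairs$death <= object@pairs$birth))
    msg <- c(msg, "death must exceed birth for every finite pair")
  if (!all(c("birth", "dim") %in% names(object@essential)))
    msg <- c(msg, "essential needs columns birth, dim")
  if (length(msg)) msg else TRUE
})

persistenceDiagram <- function(pairs, essential) {
  new("PersistenceDiagram",
      pairs = as.data.frame(pairs), essential = as.data.frame(essential))
}

setMethod("show", "PersistenceDiagram", function(object) {
  cat("PersistenceDiagram:", nrow(object@pairs), "finite pairs,",
      nrow(object@essential), "essential\n")
})

#' @describeIn persistencePairs essential classes of a diagram.
#' @export
essentialClasses <- function(diagram) diagram@essential

#' Finite pairs of a persistence diagram
#'
#' @param diagram a [PersistenceDiagram-class].
#' @param dim optional dimension filter (0 or 1).
#' @return A `data.frame` with columns `birth`, `death`, `dim`.
#' @export
persistencePairs <- function(diagram, dim = NULL) {
  p <- diagram@pairs
  if (!is.null(dim)) p <- p[p$dim == dim, , drop = FALSE]
  p
}

#' Physiological rate bounds
#'
#' Minimal and maximal rates the estimators consider: 6--30 breaths/min for
#' breathing and 40--150 beats/min for heartbeats by default.
#'
#' @slot kind `"breathing"` or `"heartbeat"`.
#' @slot minBpm lower bound (per minute).
#' @slot maxBpm upper bound (per minute).
#' @export
setClass("RateBounds", representation(
  kind = "character", minBpm = "numeric", maxBpm = "numeric"))

setValidity("RateBounds", function(object) {
  msg <- character()
  if (!object@kind %in% c("breathing", "heartbeat"))
    msg <- c(msg, 'kind must be "breathing" or "heartbeat"')
  if (!(object@minBpm > 0 && object@minBpm < object@maxBpm))
    msg <- c(msg, "need 0 < minBpm < maxBpm")
  if (length(msg)) msg else TRUE
})

#' Construct rate bounds
#'
#' @param kind `"breathing"` or `"heartbeat"`.
#' @param minBpm,maxBpm bounds in events per minute; defaults are 6--30
#'   (breathing) and 40--150 (heartbeat).
#' @return A [RateBounds-class].
#' @export
rateBounds <- function(kind = c("breathing", "heartbeat"),
                       minBpm = NULL, maxBpm = NULL) {
  kind <- match.arg(kind)
  if (is.null(minBpm)) minBpm <- if (kind == "breathing") 6 else 40
  if (is.null(maxBpm)) maxBpm <- if (kind == "breathing") 30 else 150
  new("RateBounds", kind = kind, minBpm = as.numeric(minBpm),
      maxBpm = as.numeric(maxBpm))
}

setMethod("show", "RateBounds", function(object) {
  cat("RateBounds:", object@kind, object@minBpm, "-", object@maxBpm, "BPM\n")
})

#' Range-bin selection for one epoch
#'
#' Result of single (temporal-phase-coherence) or multiple
#' (persistence-homology) range-bin selection: the accepted bins, the rate
#' each accepted bin yielded and the fused epoch rate (median over bins).
#' An empty `bins` set with `NA` fused rate is a valid outcome, not an
#' error.
#'
#' @slot epochIndex epoch index (1-based).
#' @slot kind `"breathing"` or `"heartbeat"`.
#' @slot method `"single"` or `"multiple"`.
#' @slot bins accepted range-bin indices (1-based; at most one for single).
#' @slot perBinRate named numeric, rate (BPM) per accepted bin.
#' @slot fusedRate epoch rate in BPM, or `NA`.
#' @export
setClass("BinSelection", representation(
  epochIndex = "integer",
  kind = "character",
  method = "character",
  bins = "integer",
  perBinRate = "numeric",
  fusedRate = "numeric"
))

setValidity("BinSelection", function(object) {
  msg <- character()
  if (object@method == "single" && length(object@bins) > 1)
    msg <- c(msg, "single selection yields at most one bin")
  if (!is.na(object@fusedRate) &&
      (length(object@bins) == 0 || !length(object@perBinRate)))
    msg <- c(msg, "fused rate requires accepted bins with rates")
  if (length(msg)) msg else TRUE
})

binSelection <- function(epochIndex, kind, method,
                         bins = integer(), perBinRate = numeric(),
                         fusedRate = NA_real_) {
  new("BinSelection", epochIndex = as.integer(epochIndex), kind = kind,
      method = method, bins = as.integer(bins),
      perBinRate = perBinRate, fusedRate = as.numeric(fusedRate))
}

setMethod("show", "BinSelection", function(object) {
  cat("BinSelection [", object@method, "/", object@kind, "] epoch",
      object@epochIndex, ": bins {", paste(object@bins, collapse = ","),
      "}, fused", signif(object@fusedRate, 4), "BPM\n")
})

#' @describeIn binSelection accepted bins.
#' @param sel a [BinSelection-class].
#' @export
selectedBins <- function(sel) sel@bins

#' @describeIn binSelection fused rate (BPM or `NA`).
#' @export
fusedRate <- function(sel) sel@fusedRate
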