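## Range transform, chirp-median phase extraction, phase-to-displacement
## conversion and the cube container I/O.

#' Range transform: raw ADC samples to a radar cube
#'
#' Applies a discrete Fourier transform along the ADC-sample axis of every
#' chirp and keeps the first `nRangeBins` output bins. Bin `k` (0-based)
#' represents the range slice starting at `k * rangeResolutionM`.
#'
#' @param rawAdc real or complex array `[frame, chirp, adc_sample]`.
#' @param config a [RadarConfig-class]; the sample axis must have
#'   `adcSamplesPerChirp` entries and `nRangeBins` must not exceed it.
#' @param startTime wall-clock time of the first frame.
#' @return A [RadarCube-class].
#' @export
rangeTransform <- function(rawAdc, config,
                           startTime = as.POSIXct("2026-01-01 23:00:00",
                                                  tz = "UTC")) {
  d <- dim(rawAdc)
  if (length(d) != 3L)
    stop("rawAdc must be a 3-d array [frame, chirp, adc_sample]")
  if (d[3] != config@adcSamplesPerChirp)
    stop("configuration error: rawAdc has ", d[3],
         " samples per chirp, config expects ", config@adcSamplesPerChirp)
  if (d[2] != config@chirpsPerFrame)
    stop("configuration error: rawAdc has ", d[2],
         " chirps per frame, config expects ", config@chirpsPerFrame)
  if (config@nRangeBins > config@adcSamplesPerChirp)
    stop("configuration error: nRangeBins exceeds adcSamplesPerChirp")
  ns <- d[3]
  # FFT along the sample axis: fold the (frame, chirp) axes into columns
  m <- matrix(aperm(rawAdc, c(3, 1, 2)), nrow = ns)
  ft <- stats::mvfft(m)
  kept <- array(t(ft[seq_len(config@nRangeBins), , drop = FALSE]),
                dim = c(d[1], d[2], config@nRangeBins))
  radarCube(kept, config, startTime)
}

# unwrap a phase series: correct jumps > pi by +/- 2*pi
.unwrapPhase <- function(p) {
  if (length(p) < 2) return(p)
  p + cumsum(c(0, -2 * pi * round(diff(p) / (2 * pi))))
}

#' Chirp-median phase summarisation
#'
#' Summarises each frame by the median of its per-chirp phase angles, per
#' range bin. Phases within a frame are first wrap-aligned to the first
#' chirp's phase (shifted by multiples of 2 pi so all lie within +/- pi of
#' it) so the ordinary median is meaningful at the +/- pi boundary; the
#' median of an even chirp count is the mean of the two central order
#' statistics. The resulting one-phase-per-frame series (sampling rate =
#' frame rate) is then unwrapped over time per bin (jumps > pi corrected by
#' +/- 2 pi).
#'
#' @param cube a [RadarCube-class].
#' @return A [DisplacementSeries-class] in radians.
#' @export
chirpMedianPhase <- function(cube) {
  d <- dim(cube@samples)
  if (d[1] == 0) stop("empty cube")
  med <- cpp_chirp_median_phase(as.vector(cube@samples), as.integer(d))
  unwrapped <- apply(med, 2, .unwrapPhase)
  if (is.null(dim(unwrapped))) unwrapped <- matrix(unwrapped, nrow = d[1])
  displacementSeries(unwrapped, cube@config, "rad", cube@startTime)
}

#' Convert unwrapped phase to displacement
#'
#' Displacement in millimetres is `phase * lambda / (4 * pi)` with
#' `lambda = c / carrierFreqHz`: a full 4 pi phase excursion corresponds to
#' one wavelength of radial motion (two-way path).
#'
#' @param series a [DisplacementSeries-class] in radians (unwrapped).
#' @param config radar configuration providing the carrier frequency;
#'   defaults to the series' own config.
#' @return A [DisplacementSeries-class] in mm.
#' @export
phaseToDisplacement <- function(series, config = series@config) {
  if (series@units != "rad")
    stop("input series must be in radians")
  if (config@carrierFreqHz <= 0)
    stop("configuration error: carrierFreqHz must be > 0")
  lambdaM <- .C_LIGHT / config@carrierFreqHz
  out <- series
  out@values <- series@values * (lambdaM / (4 * pi)) * 1000
  out@units <- "mm"
  out
}

## ---------------------------------------------------------------------------
## Cube container: a simple self-describing binary layout with three named
## members -- "config" (the RadarConfig fields), "start_time" (ISO-8601
## string) and "samples" (little-endian doubles, Re/Im interleaved, in
## frame-major array order). An 8-byte magic/version prefix is followed by a
## length-prefixed JSON header naming the members and array dimensions.
## ---------------------------------------------------------------------------

.CUBE_MAGIC <- charToRaw("RVCUBE01")

#' Write / read a radar cube container
#'
#' `writeCube()` stores a cube losslessly in the package's binary container
#' (members `"config"`, `"start_time"`, `"samples"`); `readCube()` restores
#' it. The round trip is bitwise exact on the samples; a file missing one of
#' the named members raises a format error naming the missing member.
#'
#' @param cube a [RadarCube-class].
#' @param path file path.
#' @return `readCube()` returns a [RadarCube-class]; `writeCube()` returns
#'   `path` invisibly.
#' @export
writeCube <- function(cube, path) {
  cfg <- cube@config
  header <- list(
    config = list(
      carrier_freq_hz = cfg@carrierFreqHz,
      bandwidth_hz = cfg@bandwidthHz,
      range_resolution_m = cfg@rangeResolutionM,
      chirps_per_frame = cfg@chirpsPerFrame,
      frame_rate_hz = cfg@frameRateHz,
      adc_samples_per_chirp = cfg@adcSamplesPerChirp,
      n_range_bins = cfg@nRangeBins,
      max_range_m = cfg@maxRangeM),
    start_time = format(cube@startTime, "%Y-%m-%dT%H:%M:%OS6%z", tz = "UTC"),
    samples = list(dims = dim(cube@samples), dtype = "complex128"))
  hjson <- charToRaw(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(.CUBE_MAGIC, con)
  writeBin(length(hjson), con, size = 4L, endian = "little")
  writeBin(hjson, con)
  inter <- as.numeric(rbind(Re(as.vector(cube@samples)),
                            Im(as.vector(cube@samples))))
  writeBin(inter, con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname writeCube
#' @export
readCube <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = length(.CUBE_MAGIC))
  if (!identical(magic, .CUBE_MAGIC))
    stop("format error: not a radar cube container")
  hlen <- readBin(con, "integer", size = 4L, endian = "little")
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", n = hlen)))
  for (member in c("config", "start_time", "samples"))
    if (is.null(header[[member]]))
      stop('format error: missing member "', member, '"')
  hc <- header$config
  for (fld in c("carrier_freq_hz", "chirps_per_frame", "frame_rate_hz",
                "n_range_bins", "range_resolution_m", "adc_samples_per_chirp"))
    if (is.null(hc[[fld]]))
      stop('format error: missing member "config/', fld, '"')
  cfg <- radarConfig(
    carrierFreqHz = hc$carrier_freq_hz,
    bandwidthHz = if (is.null(hc$bandwidth_hz)) 0 else hc$bandwidth_hz,
    rangeResolutionM = hc$range_resolution_m,
    chirpsPerFrame = hc$chirps_per_frame,
    frameRateHz = hc$frame_rate_hz,
    adcSamplesPerChirp = hc$adc_samples_per_chirp,
    nRangeBins = hc$n_range_bins)
  dims <- as.integer(header$samples$dims)
  inter <- readBin(con, "numeric", n = 2 * prod(dims), size = 8L,
                   endian = "little")
  z <- complex(real = inter[c(TRUE, FALSE)], imaginary = inter[c(FALSE, TRUE)])
  startTime <- as.POSIXct(header$start_time, tz = "UTC",
                          format = "%Y-%m-%dT%H:%M:%OS%z")
  radarCube(array(z, dim = dims), cfg, startTime)
}
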