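## Breathing-rate (autocorrelation) and heart-rate (peak detection)
## estimation within physiological bounds; reference rates from
## respiratory-effort and ECG channels with the same estimators.

# remove a linear trend
.detrend <- function(x) {
  n <- length(x)
  t <- seq_len(n)
  stats::lsfit(t, x)$residuals
}

# prominence of a peak at index k of curve r: height above the higher of the
# two minima separating it from higher terrain (or the curve ends)
.peakProminence <- function(r, k) {
  n <- length(r)
  leftMin <- r[k]
  i <- k - 1
  while (i >= 1 && r[i] <= r[k]) { leftMin <- min(leftMin, r[i]); i <- i - 1 }
  if (i < 1) leftMin <- min(r[seq_len(k)])
  rightMin <- r[k]
  i <- k + 1
  while (i <= n && r[i] <= r[k]) { rightMin <- min(rightMin, r[i]); i <- i + 1 }
  if (i > n) rightMin <- min(r[k:n])
  r[k] - max(leftMin, rightMin)
}

# local maxima indices (strict rise, non-strict fall for plateaus)
.localMaxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer())
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

#' Autocorrelation-based breathing-rate estimate for one epoch
#'
#' Linearly detrends the epoch, computes the biased normalised
#' autocorrelation, and takes the first local maximum with prominence at
#' least `minProminence` whose lag lies in `[60/maxBpm, 60/minBpm]` seconds;
#' the rate is `60 / lag`. A cycle-consistency check recomputes the rate on
#' the two epoch halves and rejects the epoch (returns no rate) when either
#' half yields no peak or the half-rates differ by more than
#' `consistencyBpm`. The lag grid is the native sampling grid (no
#' interpolation), so estimates are quantised to one lag step. Returning no
#' rate is a valid outcome, not an error.
#'
#' @param series numeric epoch signal (one range bin), >= 30 s at >= 10 Hz.
#' @param fs sampling rate (Hz).
#' @param bounds a [RateBounds-class], default breathing 6--30 BPM.
#' @param minProminence minimal autocorrelation peak prominence.
#' @param consistencyBpm maximal allowed difference between half-epoch rates.
#' @param .check internal: disable the consistency recursion.
#' @return List with `value_bpm` (BPM or `NA`), `quality` (half the peak
#'   prominence, in `[0, 1]`).
#' @export
breathingRate <- function(series, fs, bounds = rateBounds("breathing"),
                          minProminence = 0.15, consistencyBpm = 2,
                          .check = TRUE) {
  none <- list(value_bpm = NA_real_, quality = 0)
  n <- length(series)
  if (n < 4 || stats::sd(series) == 0) return(none)
  x <- .detrend(series)
  lagMin <- max(2L, ceiling(fs * 60 / bounds@maxBpm))
  lagMax <- floor(fs * 60 / bounds@minBpm)
  if (lagMax >= n) lagMax <- n - 1L
  if (lagMin > lagMax) return(none)
  r <- as.numeric(stats::acf(x, lag.max = lagMax + 1L, plot = FALSE,
                             demean = FALSE)$acf)  # r[1] = lag 0
  peaks <- .localMaxima(r)
  lags <- peaks - 1L                                # in samples
  inBand <- peaks[lags >= lagMin & lags <= lagMax]
  best <- NA_integer_
  for (k in inBand) {
    if (.peakProminence(r, k) >= minProminence) { best <- k; break }
  }
  if (is.na(best)) return(none)
  lag <- (best - 1L) / fs
  rate <- 60 / lag
  if (rate < bounds@minBpm - 1e-9 || rate > bounds@maxBpm + 1e-9) return(none)
  # the autocorrelation peak prominence lies in [0, 2]; half of it maps the
  # quality to [0, 1] without saturating clean signals and noise alike
  quality <- min(1, max(0, .peakProminence(r, best) / 2))
  if (.check) {
    half <- floor(n / 2)
    r1 <- breathingRate(series[seq_len(half)], fs, bounds, minProminence,
                        consistencyBpm, .check = FALSE)
    r2 <- breathingRate(series[(half + 1):n], fs, bounds, minProminence,
                        consistencyBpm, .check = FALSE)
    if (is.na(r1$value_bpm) || is.na(r2$value_bpm) ||
        abs(r1$value_bpm - r2$value_bpm) > consistencyBpm)
      return(none)
  }
  list(value_bpm = rate, quality = quality)
}

# zero-phase Butterworth band-pass; band in Hz
.bandPass <- function(x, fs, band, order = 5) {
  ny <- fs / 2
  lo <- max(band[1] / ny, 1e-4)
  hi <- min(band[2] / ny, 0.999)
  bf <- signal::butter(order, c(lo, hi), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

# greedy min-distance peak picking: local maxima above `thr`, highest first,
# keeping peaks at least `minDist` samples apart
.pickPeaks <- function(x, minDist, thr) {
  cand <- .localMaxima(x)
  cand <- cand[x[cand] >= thr]
  if (!length(cand)) return(integer())
  cand <- cand[order(x[cand], decreasing = TRUE)]
  kept <- integer()
  for (p in cand)
    if (!length(kept) || all(abs(kept - p) >= minDist)) kept <- c(kept, p)
  sort(kept)
}

# sub-sample peak refinement by parabolic interpolation
.refinePeaks <- function(x, peaks) {
  vapply(peaks, function(p) {
    if (p <= 1 || p >= length(x)) return(as.numeric(p))
    den <- x[p - 1] - 2 * x[p] + x[p + 1]
    if (den == 0) return(as.numeric(p))
    p + 0.5 * (x[p - 1] - x[p + 1]) / den
  }, numeric(1))
}

# dominant frequency of a detrended signal at/above `fMin` Hz
.dominantFreq <- function(x, fs, fMin) {
  n <- length(x)
  spec <- Mod(stats::fft(x * .hammingWindow(n)))[seq_len(floor(n / 2))]
  freqs <- (seq_len(floor(n / 2)) - 1) * fs / n
  ok <- freqs >= fMin
  if (!any(ok)) return(NA_real_)
  freqs[ok][which.max(spec[ok])]
}

#' Peak-detection heart-rate estimate for one epoch
#'
#' Zero-phase Butterworth band-pass at the bounds-implied frequencies,
#' followed by peak detection with minimum inter-peak distance
#' `60 / maxBpm` seconds and an adaptive amplitude threshold
#' (`median + k * MAD` of the filtered signal). Peak positions are refined
#' by parabolic interpolation before inter-beat intervals (IBIs) are formed;
#' the rate is `60 / median(IBI)`. The epoch is rejected (no rate) when
#' fewer than `minBeats` beats per 60 s are detected, when the IBI
#' coefficient of variation exceeds `cvMax`, when the rate falls outside the
#' bounds, or when the dominant spectral frequency of the epoch (searched
#' from just below the band upward) lies above the band -- a guard against
#' out-of-band oscillations aliasing through the minimum-distance peak
#' picking. Quality is `1 - CV`.
#'
#' @param series numeric epoch signal, >= 30 s at >= 10 Hz.
#' @param fs sampling rate (Hz).
#' @param bounds a [RateBounds-class], default heartbeat 40--150 BPM.
#' @param minBeats minimal beat count per 60 s.
#' @param cvMax maximal IBI coefficient of variation.
#' @param k MAD multiplier of the adaptive threshold.
#' @return List with `value_bpm` (BPM or `NA`) and `quality` (`1 - CV`).
#' @export
heartRate <- function(series, fs, bounds = rateBounds("heartbeat"),
                      minBeats = 20, cvMax = 0.25, k = 1) {
  none <- list(value_bpm = NA_real_, quality = 0)
  n <- length(series)
  if (n < 4 || stats::sd(series) == 0) return(none)
  x <- .detrend(series)
  fLow <- bounds@minBpm / 60
  fHigh <- bounds@maxBpm / 60
  fDom <- .dominantFreq(x, fs, 0.8 * fLow)
  if (!is.na(fDom) && fDom > 1.15 * fHigh) return(none)
  xf <- .bandPass(x, fs, c(fLow, fHigh))
  thr <- stats::median(xf) + k * stats::mad(xf)
  minDist <- ceiling(fs * 60 / bounds@maxBpm)
  peaks <- .pickPeaks(xf, minDist, thr)
  durS <- n / fs
  if (length(peaks) < 2) return(none)
  ibi <- diff(.refinePeaks(xf, peaks)) / fs
  .ibiRate(ibi, durS, bounds, minBeats, cvMax)
}

# shared IBI-to-rate logic with count / regularity / bounds rejection
.ibiRate <- function(ibi, durS, bounds, minBeats, cvMax) {
  none <- list(value_bpm = NA_real_, quality = 0)
  nBeats <- length(ibi) + 1
  if (nBeats < minBeats * durS / 60) return(none)
  cv <- stats::sd(ibi) / mean(ibi)
  if (!is.finite(cv) || cv > cvMax) return(none)
  rate <- 60 / stats::median(ibi)
  if (rate < bounds@minBpm - 1e-9 || rate > bounds@maxBpm + 1e-9) return(none)
  list(value_bpm = rate, quality = max(0, 1 - cv))
}

#' Reference rates from polysomnography channels
#'
#' Applies the same estimators as the radar path to reference channels: a
#' respiratory-effort waveform goes through [breathingRate()]; an ECG
#' waveform goes through a classical derivative--energy R-peak detector
#' (differentiate, square, moving-window integrate over 150 ms, adaptive
#' `median + k * MAD` threshold, minimum inter-peak distance `60 / maxBpm`)
#' followed by the identical IBI count / regularity / bounds rejection
#' rules. The reference may also yield no rate for an epoch.
#'
#' @param channel numeric epoch waveform.
#' @param fs sampling rate (Hz); >= 50 Hz for ECG, >= 10 Hz for effort.
#' @param kind `"effort"` or `"ecg"`.
#' @param bounds a [RateBounds-class]; defaults to breathing bounds for
#'   effort, heartbeat bounds for ECG.
#' @param minBeats,cvMax rejection parameters of the IBI logic (ECG only).
#' @return List with `value_bpm` (BPM or `NA`) and `quality`.
#' @export
referenceRates <- function(channel, fs, kind = c("effort", "ecg"),
                           bounds = NULL, minBeats = 20, cvMax = 0.25) {
  if (!is.character(kind) || !kind[1] %in% c("effort", "ecg"))
    stop("format error: unsupported channel type ", kind[1])
  kind <- match.arg(kind)
  if (kind == "effort") {
    if (is.null(bounds)) bounds <- rateBounds("breathing")
    return(breathingRate(channel, fs, bounds))
  }
  if (is.null(bounds)) bounds <- rateBounds("heartbeat")
  none <- list(value_bpm = NA_real_, quality = 0)
  n <- length(channel)
  if (n < 4 || stats::sd(channel) == 0) return(none)
  x <- .detrend(channel)
  energy <- c(0, diff(x))^2
  win <- max(1L, round(0.150 * fs))
  integ <- as.numeric(stats::filter(energy, rep(1 / win, win), sides = 2))
  integ[is.na(integ)] <- 0
  thr <- stats::median(integ) + 2 * stats::mad(integ)
  minDist <- ceiling(fs * 60 / bounds@maxBpm)
  peaks <- .pickPeaks(integ, minDist, thr)
  if (length(peaks) < 2) return(none)
  ibi <- diff(.refinePeaks(integ, peaks)) / fs
  .ibiRate(ibi, n / fs, bounds, minBeats, cvMax)
}
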