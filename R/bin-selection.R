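## Per-epoch range-bin selection: single (temporal-phase-coherence ranking,
## top-5 preselection, quality choice) and multiple (persistence-homology
## accept/reject per bin with median fusion).

#' Temporal phase coherence of one bin's epoch signal
#'
#' The epoch is split into `K` equal sub-windows; in each, the discrete
#' Fourier phase at the epoch's dominant in-band frequency is measured on a
#' common time axis, and the coherence is the modulus of the mean unit
#' phasor, `| mean(exp(i theta_k)) |`. A phase-locked periodic signal scores
#' close to 1; white noise scores around `sqrt(pi) / (2 sqrt(K))` (about
#' 0.36 at `K = 6`). An all-zero (or constant) signal returns 0.
#'
#' @param series numeric epoch signal.
#' @param fs sampling rate (Hz).
#' @param band in-band frequency range in Hz, e.g. `c(0.1, 0.5)` for
#'   breathing.
#' @param K number of sub-windows (default 6).
#' @return Coherence in `[0, 1]`.
#' @export
tpc <- function(series, fs, band, K = 6) {
  n <- length(series)
  if (n < 2 * K || stats::sd(series) == 0) return(0)
  x <- .detrend(series)
  freqs <- (seq_len(n) - 1) * fs / n
  inBand <- which(freqs >= band[1] & freqs <= band[2])
  if (!length(inBand)) return(0)
  spec <- stats::fft(x)
  fDom <- freqs[inBand[which.max(Mod(spec[inBand]))]]
  sub <- floor(n / K)
  t <- (seq_len(n) - 1) / fs
  carrier <- exp(-2i * pi * fDom * t)
  theta <- vapply(seq_len(K), function(j) {
    idx <- ((j - 1) * sub + 1):(j * sub)
    Arg(sum(x[idx] * carrier[idx]))
  }, numeric(1))
  Mod(mean(exp(1i * theta)))
}

# frames belonging to an epoch interval [start_s, end_s)
.epochFrames <- function(nFrames, fs, epoch) {
  t <- (seq_len(nFrames) - 1) / fs
  which(t >= epoch[1] & t < epoch[2])
}

# single selection on prepared epoch matrices (band-limited + raw)
.epochSingle <- function(xBand, xRaw, fs, kind, bounds, epochIndex = 1L,
                         topN = 5L, tpcK = 20L) {
  nb <- ncol(xRaw)
  band <- c(bounds@minBpm, bounds@maxBpm) / 60
  # coherence is ranked on the raw (internally detrended) signal: tpc's
  # dominant-frequency restriction already band-limits, while pre-filtering
  # would make noise bins narrowband and spuriously phase-coherent; the
  # driver uses more sub-windows than the tpc default: the noise coherence
  # ceiling falls as 1/sqrt(K) while a vital-sign bin -- even across a
  # rate-track step, where its phasors form two clusters -- stays near or
  # above 0.5
  coh <- vapply(seq_len(nb), function(b) tpc(xRaw[, b], fs, band, K = tpcK),
                numeric(1))
  top <- order(-coh, seq_len(nb))[seq_len(min(topN, nb))]
  best <- NULL
  for (b in top) {
    # breathing rates are estimated on the band-limited signal so that
    # heartbeat content sharing the bin cannot masquerade as a harmonic
    # breathing peak; the heart estimator band-passes internally
    est <- if (kind == "breathing") breathingRate(xBand[, b], fs, bounds)
           else heartRate(xRaw[, b], fs, bounds)
    if (is.na(est$value_bpm)) next
    if (is.null(best) || est$quality > best$quality ||
        (est$quality == best$quality && b < best$bin))
      best <- list(bin = b, rate = est$value_bpm, quality = est$quality)
  }
  if (is.null(best))
    return(binSelection(epochIndex, kind, "single"))
  binSelection(epochIndex, kind, "single", bins = best$bin,
               perBinRate = stats::setNames(best$rate, best$bin),
               fusedRate = best$rate)
}

#' Default thresholds for multiple range-bin selection
#'
#' The persistence-diagram acceptance thresholds were calibrated once on the
#' package's synthetic bed scene and are exposed as configuration: `tau` is
#' the minimal 0-dimensional persistence (mm of band-limited displacement)
#' for a pair to count as a vital-sign cycle; `countSlack` widens the
#' bound-implied admissible cycle-count range by that many counts on each
#' side; `rhoMin` is the minimal death/birth ratio of the strongest
#' 1-dimensional Vietoris--Rips pair (breathing only); `decimTarget` bounds
#' the phase-plane point cloud size; `embedDim` is the embedding dimension
#' of [delayEmbed()] for callers that use an explicit delay embedding.
#'
#' @param kind `"breathing"` or `"heartbeat"`.
#' @return Named list of thresholds.
#' @export
multipleThresholds <- function(kind = c("breathing", "heartbeat")) {
  kind <- match.arg(kind)
  if (kind == "breathing")
    list(tau = 0.6, countSlack = 2, rhoMin = 1.5, decimTarget = 56,
         embedDim = 2)
  else
    list(tau = 0.2, countSlack = 3, rhoMin = NA, decimTarget = 56,
         embedDim = 2)
}

# analytic signal via the FFT construction
.analyticSignal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) { h[2:(n / 2)] <- 2; h[n / 2 + 1] <- 1 }
  else h[2:((n + 1) / 2)] <- 2
  stats::fft(X * h, inverse = TRUE) / n
}

# phase-plane point cloud of a band-limited epoch: the analytic-signal
# embedding (x, Hilbert[x]) traces the oscillation's loop with an exact
# quarter-period offset at every in-band frequency, unlike an integer
# delay, whose granularity can collapse the loop for part of the rate band;
# fractional-stride decimation bounds the cloud size
.phasePlaneCloud <- function(x, target) {
  z <- .analyticSignal(x)
  idx <- unique(round(seq(1, length(x), length.out = min(target, length(x)))))
  cbind(Re(z)[idx], Im(z)[idx])
}

# multiple selection on prepared epoch matrices
.epochMultiple <- function(xBand, xRaw, fs, kind, bounds, thresholds,
                           epochIndex = 1L) {
  nb <- ncol(xRaw)
  durS <- nrow(xRaw) / fs
  countLo <- max(1, floor(durS * bounds@minBpm / 60) - thresholds$countSlack)
  countHi <- ceiling(durS * bounds@maxBpm / 60) + thresholds$countSlack
  accepted <- integer()
  for (b in seq_len(nb)) {
    x <- xBand[, b]
    if (stats::sd(x) == 0) next
    d0 <- sublevelDiagram(x)
    s0 <- periodicityScores(d0, tau = thresholds$tau)
    if (s0$persistence_count_0 < countLo ||
        s0$persistence_count_0 > countHi) next
    if (kind == "breathing") {
      cloud <- .phasePlaneCloud(x, thresholds$decimTarget)
      if (nrow(cloud) < 3) next
      d1 <- ripsDiagram(cloud, maxDim = 1)
      s1 <- periodicityScores(d0, d1, tau = thresholds$tau)
      if (s1$persistence_ratio_1 < thresholds$rhoMin) next
    }
    accepted <- c(accepted, b)
  }
  rates <- numeric()
  for (b in accepted) {
    est <- if (kind == "breathing") breathingRate(xBand[, b], fs, bounds)
           else heartRate(xRaw[, b], fs, bounds)
    if (!is.na(est$value_bpm))
      rates[as.character(b)] <- est$value_bpm
  }
  if (!length(rates))
    return(binSelection(epochIndex, kind, "multiple"))
  binSelection(epochIndex, kind, "multiple",
               bins = as.integer(names(rates)), perBinRate = rates,
               fusedRate = stats::median(rates))
}

#' Single range-bin selection for one epoch
#'
#' Ranks range bins by temporal phase coherence of their band-limited epoch
#' signal (band = the kind's rate bounds), computes the kind's rate for the
#' five highest-ranked bins, and keeps the bin with the highest quality
#' (breathing: autocorrelation peak prominence; heartbeat: `1 - CV` of the
#' inter-beat intervals). Ties in coherence and quality resolve to the lower
#' bin index. If no candidate yields a rate the selection is empty -- a
#' valid outcome. The method is deliberately permissive: it ranks rather
#' than rejects, so some rate is produced for most epochs.
#'
#' @param disp a [DisplacementSeries-class] in mm.
#' @param epoch numeric `c(start_s, end_s)` relative to the series start.
#' @param kind `"breathing"` or `"heartbeat"`.
#' @param bounds a [RateBounds-class] (defaults to the kind's bounds).
#' @param epochIndex index used to label the result.
#' @return A [BinSelection-class].
#' @export
selectSingle <- function(disp, epoch, kind = c("breathing", "heartbeat"),
                         bounds = NULL, epochIndex = 1L) {
  kind <- match.arg(kind)
  if (is.null(bounds)) bounds <- rateBounds(kind)
  fs <- disp@samplingRateHz
  idx <- .epochFrames(nrow(disp@values), fs, epoch)
  xRaw <- disp@values[idx, , drop = FALSE]
  xBand <- apply(xRaw, 2, .bandPass, fs = fs,
                 band = c(bounds@minBpm, bounds@maxBpm) / 60)
  .epochSingle(xBand, xRaw, fs, kind, bounds, epochIndex)
}

#' Multiple range-bin selection for one epoch
#'
#' Accepts every range bin whose band-limited epoch signal looks like a
#' vital-sign oscillation in the persistence-homology sense: the number of
#' 0-dimensional sublevel-set pairs with persistence at least `tau` must
#' fall in the cycle-count range implied by the rate bounds, and for
#' breathing the phase-plane (analytic-signal) embedding of the signal must
#' additionally carry a strong 1-dimensional Vietoris--Rips loop (death/birth
#' ratio at least `rhoMin`);
#' heart-rate selection uses the sublevel-set criterion only. Accepted bins
#' each yield a rate and the epoch rate is their median. The method is
#' deliberately strict: an empty acceptance set means no rate for the
#' epoch, trading coverage for a low false-positive rate.
#'
#' @inheritParams selectSingle
#' @param thresholds acceptance thresholds, see [multipleThresholds()].
#' @return A [BinSelection-class].
#' @export
selectMultiple <- function(disp, epoch, kind = c("breathing", "heartbeat"),
                           bounds = NULL, thresholds = NULL,
                           epochIndex = 1L) {
  kind <- match.arg(kind)
  if (is.null(bounds)) bounds <- rateBounds(kind)
  if (is.null(thresholds)) thresholds <- multipleThresholds(kind)
  fs <- disp@samplingRateHz
  idx <- .epochFrames(nrow(disp@values), fs, epoch)
  xRaw <- disp@values[idx, , drop = FALSE]
  xBand <- apply(xRaw, 2, .bandPass, fs = fs,
                 band = c(bounds@minBpm, bounds@maxBpm) / 60)
  .epochMultiple(xBand, xRaw, fs, kind, bounds, thresholds, epochIndex)
}

#' Range-bin selection across a whole recording
#'
#' Driver that band-limits each bin's full series once (zero-phase
#' fifth-order Butterworth at the kind's bounds) and then runs the chosen
#' per-epoch selection on every retained epoch of the grid.
#'
#' @param disp a [DisplacementSeries-class] in mm.
#' @param grid an [EpochGrid-class].
#' @param kind `"breathing"` or `"heartbeat"`.
#' @param method `"single"` or `"multiple"`.
#' @param bounds optional [RateBounds-class].
#' @param thresholds optional thresholds for the multiple method.
#' @param retained optional logical mask of epochs to process (e.g. from
#'   [retainedEpochs()]); skipped epochs yield empty selections.
#' @return List of [BinSelection-class], one per epoch of the grid.
#' @export
selectBins <- function(disp, grid, kind = c("breathing", "heartbeat"),
                       method = c("single", "multiple"), bounds = NULL,
                       thresholds = NULL, retained = NULL) {
  kind <- match.arg(kind)
  method <- match.arg(method)
  if (is.null(bounds)) bounds <- rateBounds(kind)
  if (is.null(thresholds)) thresholds <- multipleThresholds(kind)
  fs <- disp@samplingRateHz
  if (is.null(retained)) retained <- rep(TRUE, nEpochs(grid))
  xBandFull <- apply(disp@values, 2, .bandPass, fs = fs,
                     band = c(bounds@minBpm, bounds@maxBpm) / 60)
  lapply(seq_len(nEpochs(grid)), function(e) {
    if (!retained[e])
      return(binSelection(e, kind, method))
    epoch <- grid@epochStarts[e] + c(0, grid@windowS)
    idx <- .epochFrames(nrow(disp@values), fs, epoch)
    xRaw <- disp@values[idx, , drop = FALSE]
    xBand <- xBandFull[idx, , drop = FALSE]
    if (method == "single")
      .epochSingle(xBand, xRaw, fs, kind, bounds, e)
    else
      .epochMultiple(xBand, xRaw, fs, kind, bounds, thresholds, e)
  })
}

#' Histogram of selected range bins
#'
#' Counts, per range bin, how many epochs selected that bin, separately per
#' recording, and reports the across-recording mean with a
#' normal-approximation 95% confidence interval. With a single recording
#' the interval collapses to the point estimate.
#'
#' @param selections either a list of [BinSelection-class] (one recording)
#'   or a list of such lists (one element per recording).
#' @param nBins number of range bins of the recording configuration.
#' @return A `data.frame` with columns `bin`, `mean`, `ciLow`, `ciHigh`,
#'   `total`.
#' @export
selectionHistogram <- function(selections, nBins) {
  if (length(selections) && is(selections[[1]], "BinSelection"))
    selections <- list(selections)
  counts <- t(vapply(selections, function(rec) {
    tab <- tabulate(unlist(lapply(rec, selectedBins)), nbins = nBins)
    as.numeric(tab)
  }, numeric(nBins)))
  m <- colMeans(counts)
  s <- if (nrow(counts) > 1) apply(counts, 2, stats::sd) else rep(0, nBins)
  half <- 1.96 * s / sqrt(nrow(counts))
  data.frame(bin = seq_len(nBins), mean = m, ciLow = m - half,
             ciHigh = m + half, total = colSums(counts))
}
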