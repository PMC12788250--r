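## Doppler-FFT motion parameter, epoch slicing, moving-average smoothing,
## overnight-mean exclusion and sleep-window cropping.

#' Doppler map of a single frame
#'
#' Discrete Fourier transform along the chirp axis per range bin, resolving
#' target velocity. Velocity bins are kept in natural (unshifted) FFT order,
#' so the zero-Doppler bin is bin 1 and the highest velocities sit in the
#' middle of the axis.
#'
#' @param frame complex matrix `[chirp, range_bin]` with at least 2 chirps.
#' @return Complex matrix `[velocity_bin, range_bin]`.
#' @export
dopplerMap <- function(frame) {
  if (!is.matrix(frame)) stop("frame must be a [chirp, range_bin] matrix")
  if (nrow(frame) < 2) stop("doppler map needs at least 2 chirps per frame")
  stats::mvfft(frame)
}

# velocity profiles for a block of frames: matrix [velocity_bin, frame],
# entry = sum over range bins of |doppler cell|
.velocityProfiles <- function(samples, frameIdx) {
  d <- dim(samples)
  nc <- d[2]; nb <- d[3]; nf <- length(frameIdx)
  # [chirp, bin * frame] layout so one mvfft handles every frame
  block <- aperm(samples[frameIdx, , , drop = FALSE], c(2, 3, 1))
  ft <- Mod(stats::mvfft(matrix(block, nrow = nc)))
  dim(ft) <- c(nc, nb, nf)
  apply(ft, c(1, 3), sum)
}

#' Doppler-FFT motion parameter of an epoch
#'
#' Implements the five-step velocity summary of an epoch: (1) Doppler FFT of
#' every frame; (2) reduction of each range--velocity frame to a velocity
#' profile by summing cell magnitudes over range bins; (3) clutter removal by
#' subtracting each velocity bin's median over the epoch's frames; (4) a
#' Hamming taper across velocity bins in unshifted order, so the zero-Doppler
#' bin receives the window's minimal weight and low-velocity clutter is
#' suppressed; (5) summation of all weighted cells over velocity bins and
#' frames into one scalar. Negative post-subtraction cells are kept as-is.
#' A perfectly static epoch yields exactly 0.
#'
#' @param cube a [RadarCube-class].
#' @param epoch numeric `c(start_s, end_s)` relative to the cube start;
#'   frames with time in `[start_s, end_s)` belong to the epoch.
#' @return Scalar motion parameter.
#' @export
motionParameter <- function(cube, epoch = c(0, nFrames(cube) /
                                              cube@config@frameRateHz)) {
  fr <- cube@config@frameRateHz
  t <- (seq_len(nFrames(cube)) - 1) / fr
  frameIdx <- which(t >= epoch[1] & t < epoch[2])
  if (length(frameIdx) < 2) stop("epoch must contain at least 2 frames")
  prof <- .velocityProfiles(cube@samples, frameIdx)      # [vbin, frame]
  med <- apply(prof, 1, stats::median)
  centred <- prof - med
  w <- .hammingWindow(nrow(prof))
  sum(centred * w)
}

# Hamming taper; in unshifted velocity-bin order its minimum falls on the
# zero-Doppler bin (bin 1) and the wrap-around low-velocity bin (bin n)
.hammingWindow <- function(n) {
  if (n == 1) return(0.08)
  0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
}

#' Epoch intervals covering a duration
#'
#' `floor((durationS - windowS) / stepS) + 1` epochs when
#' `durationS >= windowS`, none otherwise; epochs never extend past the end.
#'
#' @param durationS recording duration (s), >= 0.
#' @param windowS epoch length (s).
#' @param stepS epoch step (s).
#' @return A `data.frame` with columns `start_s`, `end_s`.
#' @export
epochSlices <- function(durationS, windowS = 60, stepS = 5) {
  stopifnot(durationS >= 0)
  g <- epochGrid(durationS, windowS, stepS)
  data.frame(start_s = g@epochStarts, end_s = g@epochStarts + windowS)
}

#' Moving-average smoothing of a per-epoch series
#'
#' Centred moving average over all epochs whose start lies within
#' `windowMin / 2` minutes of the target epoch's start (61 epochs at the
#' default 5-min window and 5-s epoch spacing); the effective window
#' shortens at the edges, where the mean is over the available epochs.
#'
#' @param raw per-epoch values.
#' @param grid the [EpochGrid-class] the values live on.
#' @param windowMin moving-average window length in minutes (default 5).
#' @return Smoothed series of the same length.
#' @export
smoothMotion <- function(raw, grid, windowMin = 5) {
  starts <- grid@epochStarts
  if (length(raw) != length(starts))
    stop("raw length must match the epoch grid")
  half <- windowMin * 60 / 2 + 1e-9
  cs <- cumsum(c(0, raw))
  lo <- findInterval(starts - half, starts) + 1
  hi <- findInterval(starts + half, starts)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Exclusion mask from the overnight-mean threshold
#'
#' Marks epochs whose smoothed motion parameter strictly exceeds the
#' threshold (by default the arithmetic mean of the smoothed series over the
#' analyzed window). On a constant series nothing strictly exceeds the mean,
#' so nothing is excluded; at least one epoch always survives.
#'
#' @param smoothed smoothed per-epoch motion parameter (non-empty).
#' @param threshold exclusion threshold; defaults to `mean(smoothed)`.
#' @return Logical mask, `TRUE` = excluded.
#' @export
exclusionMask <- function(smoothed, threshold = mean(smoothed)) {
  if (!length(smoothed)) stop("smoothed series must be non-empty")
  smoothed > threshold
}

#' Compute the full motion series of a recording
#'
#' Convenience wrapper: evaluates [motionParameter()] on every epoch of the
#' grid, smooths with [smoothMotion()] and derives the exclusion mask with
#' the overnight-mean threshold.
#'
#' @param cube a [RadarCube-class].
#' @param grid an [EpochGrid-class]; defaults to 60 s / 5 s epochs over the
#'   cube duration.
#' @param windowMin smoothing window (minutes).
#' @return A [MotionSeries-class].
#' @export
motionSeries <- function(cube, grid = NULL, windowMin = 5) {
  fr <- cube@config@frameRateHz
  durationS <- nFrames(cube) / fr
  if (is.null(grid)) grid <- epochGrid(durationS)
  raw <- vapply(grid@epochStarts, function(s)
    motionParameter(cube, c(s, s + grid@windowS)), numeric(1))
  smoothed <- smoothMotion(raw, grid, windowMin)
  thr <- mean(smoothed)
  new("MotionSeries", grid = grid, raw = raw, smoothed = smoothed,
      threshold = thr, excluded = exclusionMask(smoothed, thr))
}

# seconds past midnight of a "HH:MM" clock string
.clockSeconds <- function(clock) {
  parts <- as.numeric(strsplit(clock, ":", fixed = TRUE)[[1]])
  parts[1] * 3600 + parts[2] * 60 + if (length(parts) > 2) parts[3] else 0
}

#' Crop a recording to the nightly sleep window
#'
#' Retains frames whose wall-clock timestamps fall in
#' `[startClock, endClock)`, crossing midnight when the window does
#' (default 22:00--06:00). An empty result is allowed.
#'
#' @param x a [RadarCube-class] or [DisplacementSeries-class] carrying a
#'   wall-clock start time.
#' @param startClock,endClock clock times `"HH:MM"` (or `"HH:MM:SS"`).
#' @return Object of the same class restricted to the window.
#' @export
setGeneric("cropWindow", function(x, startClock = "22:00",
                                  endClock = "06:00") {
  standardGeneric("cropWindow")
})

.cropKeep <- function(startTime, n, fs, startClock, endClock) {
  if (length(startTime) != 1 || is.na(startTime))
    stop("format error: recording carries no wall-clock start time")
  t0 <- as.numeric(startTime)
  lt <- as.POSIXlt(startTime)
  midnight <- t0 - (lt$hour * 3600 + lt$min * 60 + lt$sec)
  sod <- (t0 + (seq_len(n) - 1) / fs - midnight) %% 86400
  a <- .clockSeconds(startClock); b <- .clockSeconds(endClock)
  if (a <= b) sod >= a & sod < b else sod >= a | sod < b
}

#' @rdname cropWindow
setMethod("cropWindow", "RadarCube", function(x, startClock, endClock) {
  keep <- .cropKeep(x@startTime, nFrames(x), x@config@frameRateHz,
                    startClock, endClock)
  idx <- which(keep)
  out <- x
  out@samples <- x@samples[idx, , , drop = FALSE]
  if (length(idx))
    out@startTime <- x@startTime + (idx[1] - 1) / x@config@frameRateHz
  out
})

#' @rdname cropWindow
setMethod("cropWindow", "DisplacementSeries", function(x, startClock,
                                                       endClock) {
  keep <- .cropKeep(x@startTime, nrow(x@values), x@samplingRateHz,
                    startClock, endClock)
  idx <- which(keep)
  out <- x
  out@values <- x@values[idx, , drop = FALSE]
  if (length(idx))
    out@startTime <- x@startTime + (idx[1] - 1) / x@samplingRateHz
  out
})

#' Retained rate epochs after motion exclusion
#'
#' Rate epochs share the motion grid; a rate epoch is discarded when its
#' `[start, start + window)` interval overlaps any excluded motion epoch.
#'
#' @param motion a [MotionSeries-class].
#' @return Logical vector, `TRUE` = epoch retained for rate computation.
#' @export
retainedEpochs <- function(motion) {
  starts <- motion@grid@epochStarts
  w <- motion@grid@windowS
  exc <- starts[motion@excluded]
  if (!length(exc)) return(rep(TRUE, length(starts)))
  vapply(starts, function(s) !any(exc < s + w & exc + w > s), logical(1))
}
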