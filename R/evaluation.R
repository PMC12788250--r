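## Agreement metrics between reference (PSG) and radar rate series.
## Every metric operates on the epochs where both rates are present
## (complete pairs); recall uses each side independently against the full
## epoch count. Undefined metrics propagate as NA, never as 0.

.completePairs <- function(ref, est) {
  ok <- !is.na(ref) & !is.na(est)
  list(ref = ref[ok], est = est[ok], n = sum(ok))
}

#' Mean absolute error between reference and radar rates
#'
#' `(1/N) * sum(|ref - est|)` over the `N` epochs where both rates are
#' present. `NA` when there are no complete pairs.
#'
#' @param ref,est per-epoch rates in BPM; `NA` marks epochs without a rate.
#' @return MAE in BPM, or `NA`.
#' @export
mae <- function(ref, est) {
  p <- .completePairs(ref, est)
  if (p$n < 1) return(NA_real_)
  mean(abs(p$ref - p$est))
}

#' Mean absolute percent error
#'
#' `100 * (1/N) * sum(|ref - est| / ref)` over complete pairs; the
#' denominator is always the reference. `NA` when there are no complete
#' pairs; an error when any reference value is 0.
#'
#' @inheritParams mae
#' @return MAPE in percent, or `NA`.
#' @export
mape <- function(ref, est) {
  p <- .completePairs(ref, est)
  if (p$n < 1) return(NA_real_)
  if (any(p$ref == 0)) stop("undefined metric: reference rate of 0")
  100 * mean(abs(p$ref - p$est) / p$ref)
}

#' Spearman rank correlation of complete pairs
#'
#' Pearson correlation of mid-ranks (average ranks for ties). `NA` when
#' fewer than 3 complete pairs exist or either side has zero rank variance.
#'
#' @inheritParams mae
#' @return Correlation in `[-1, 1]`, or `NA`.
#' @export
spearmanRho <- function(ref, est) {
  p <- .completePairs(ref, est)
  if (p$n < 3) return(NA_real_)
  rx <- rank(p$ref); ry <- rank(p$est)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  stats::cor(rx, ry)
}

#' Recall: percentage of epochs with a computed rate
#'
#' `100 * nWithRate / nTotal`; rounding to 2 decimals happens only at
#' presentation.
#'
#' @param nWithRate number of epochs with a rate.
#' @param nTotal total number of analyzed epochs (> 0).
#' @return List with `percent` (exact) and `count`.
#' @export
recallPercent <- function(nWithRate, nTotal) {
  if (nTotal <= 0) stop("undefined metric: no analyzed epochs")
  stopifnot(nWithRate >= 0, nWithRate <= nTotal)
  list(percent = 100 * nWithRate / nTotal, count = nWithRate)
}

#' Fraction of complete pairs with error inside a tolerance
#'
#' Percentage of complete pairs with `|ref - est| < tol` (strict), relative
#' to the epochs in which both rates were computed.
#'
#' @inheritParams mae
#' @param tol tolerance in BPM (default 1).
#' @return List with `percent` and `count`, or `NA` without complete pairs.
#' @export
withinTolerance <- function(ref, est, tol = 1) {
  p <- .completePairs(ref, est)
  if (p$n < 1) return(list(percent = NA_real_, count = NA_integer_))
  hits <- sum(abs(p$ref - p$est) < tol)
  list(percent = 100 * hits / p$n, count = hits)
}

# total measure of a union of intervals given as a 2-column matrix
.intervalUnion <- function(starts, ends) {
  if (!length(starts)) return(0)
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  tot <- 0; curS <- starts[1]; curE <- ends[1]
  for (i in seq_along(starts)[-1]) {
    if (starts[i] > curE) { tot <- tot + (curE - curS); curS <- starts[i]; curE <- ends[i] }
    else curE <- max(curE, ends[i])
  }
  tot + (curE - curS)
}

#' Duration not covered by rate-bearing epochs
#'
#' Because epochs overlap, the uncovered duration is not simply the count of
#' rate-less epochs times the step: it is the measure of the analyzed time
#' axis (the union of all analyzed epoch intervals) not covered by the union
#' of the `[start, start + window)` intervals of the epochs that do carry a
#' rate.
#'
#' @param hasRate logical per epoch, `TRUE` where a rate was computed.
#' @param grid the [EpochGrid-class] of the epochs.
#' @param analyzed optional logical mask of the epochs forming the analyzed
#'   axis (default: all epochs of the grid).
#' @return Uncovered duration in seconds.
#' @export
uncoveredDuration <- function(hasRate, grid, analyzed = NULL) {
  starts <- grid@epochStarts
  w <- grid@windowS
  if (is.null(analyzed)) analyzed <- rep(TRUE, length(starts))
  total <- .intervalUnion(starts[analyzed], starts[analyzed] + w)
  covered <- .intervalUnion(starts[hasRate & analyzed],
                            starts[hasRate & analyzed] + w)
  total - covered
}

#' Bland--Altman agreement statistics
#'
#' Differences are reference minus radar. Returns the mean difference, the
#' 95% limits of agreement `mean +/- 1.96 * sd` (sample standard deviation,
#' denominator `N - 1`), and the percentages of points strictly outside the
#' lower and upper limits.
#'
#' @inheritParams mae
#' @return List with `mean_diff`, `loa_low`, `loa_high`, `pct_below`,
#'   `pct_above`; all `NA` with fewer than 2 complete pairs.
#' @export
blandAltman <- function(ref, est) {
  p <- .completePairs(ref, est)
  if (p$n < 2)
    return(list(mean_diff = NA_real_, loa_low = NA_real_,
                loa_high = NA_real_, pct_below = NA_real_,
                pct_above = NA_real_))
  d <- p$ref - p$est
  m <- mean(d); s <- stats::sd(d)
  lo <- m - 1.96 * s; hi <- m + 1.96 * s
  list(mean_diff = m, loa_low = lo, loa_high = hi,
       pct_below = 100 * mean(d < lo), pct_above = 100 * mean(d > hi))
}

#' Full agreement report for one rate series pair
#'
#' Bundles every agreement metric: per-side recall (with counts), MAE,
#' MAPE, Spearman correlation, the within-1-BPM ratio, per-side uncovered
#' duration and the Bland--Altman statistics.
#'
#' @inheritParams mae
#' @param grid the [EpochGrid-class] both series live on.
#' @param analyzed optional logical mask of analyzed epochs (e.g. epochs
#'   retained after motion exclusion).
#' @param tol tolerance of the within-tolerance ratio (BPM).
#' @return Named list; undefined entries are `NA`.
#' @export
agreementReport <- function(ref, est, grid, analyzed = NULL, tol = 1) {
  if (is.null(analyzed)) analyzed <- rep(TRUE, length(ref))
  stopifnot(length(ref) == length(est),
            length(ref) == nEpochs(grid))
  refA <- ifelse(analyzed, ref, NA_real_)
  estA <- ifelse(analyzed, est, NA_real_)
  nTotal <- sum(analyzed)
  if (nTotal == 0) {
    na2 <- list(percent = NA_real_, count = NA_integer_)
    return(list(n_total_epochs = 0L, recall_psg = na2, recall_radar = na2,
                mae = NA_real_, mape = NA_real_, spearman_rho = NA_real_,
                within_tol = na2, uncovered_psg_s = NA_real_,
                uncovered_radar_s = NA_real_,
                bland_altman = blandAltman(numeric(), numeric())))
  }
  wt <- withinTolerance(refA, estA, tol)
  list(
    n_total_epochs = nTotal,
    recall_psg = recallPercent(sum(!is.na(refA)), nTotal),
    recall_radar = recallPercent(sum(!is.na(estA)), nTotal),
    mae = mae(refA, estA),
    mape = mape(refA, estA),
    spearman_rho = spearmanRho(refA, estA),
    within_tol = wt,
    uncovered_psg_s = uncoveredDuration(!is.na(refA), grid, analyzed),
    uncovered_radar_s = uncoveredDuration(!is.na(estA), grid, analyzed),
    bland_altman = blandAltman(refA, estA))
}
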