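## Minimal EDF (European Data Format) reader and writer for reference
## physiological channels. Covers the plain EDF layout used by effort and
## ECG exports: 256-byte ASCII header, 256 bytes per signal header block,
## then fixed-duration data records of 16-bit little-endian integers with
## linear physical scaling. Annotations and EDF+ discontinuities are out of
## scope.

.edfField <- function(con, width) trimws(rawToChar(readBin(con, "raw", width)))

#' Read reference channels from an EDF file
#'
#' @param path EDF file path.
#' @param channels optional character vector; keep channels whose label
#'   contains any of these substrings (case-insensitive). Default: all.
#' @return A list with `startTime` (`POSIXct`) and `channels`, a named list
#'   of `list(label, fs, signal)` entries (physical units).
#' @export
readEDF <- function(path, channels = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  version <- .edfField(con, 8)
  if (version != "0") stop("format error: not an EDF file")
  .edfField(con, 80); .edfField(con, 80)              # patient / recording id
  startDate <- .edfField(con, 8)
  startClock <- .edfField(con, 8)
  headerBytes <- as.integer(.edfField(con, 8))
  .edfField(con, 44)                                   # reserved
  nRecords <- as.integer(.edfField(con, 8))
  recordDur <- as.numeric(.edfField(con, 8))
  ns <- as.integer(.edfField(con, 4))
  rd <- function(width) vapply(seq_len(ns), function(i) .edfField(con, width),
                               character(1))
  labels <- rd(16)
  rd(80); rd(8)                                        # transducer, unit
  physMin <- as.numeric(rd(8)); physMax <- as.numeric(rd(8))
  digMin <- as.numeric(rd(8)); digMax <- as.numeric(rd(8))
  rd(80)                                               # prefiltering
  nSamp <- as.integer(rd(8))
  rd(32)                                               # reserved
  seek(con, headerBytes)
  raw <- readBin(con, "integer", n = nRecords * sum(nSamp), size = 2L,
                 signed = TRUE, endian = "little")
  recs <- matrix(raw, ncol = nRecords)                 # one record per column
  offsets <- cumsum(c(0, nSamp))
  out <- list()
  for (i in seq_len(ns)) {
    if (!is.null(channels) &&
        !any(vapply(channels, grepl, logical(1), x = labels[i],
                    ignore.case = TRUE, fixed = FALSE)))
      next
    dig <- as.numeric(recs[(offsets[i] + 1):offsets[i + 1], ])
    scale <- (physMax[i] - physMin[i]) / (digMax[i] - digMin[i])
    out[[labels[i]]] <- list(label = labels[i], fs = nSamp[i] / recordDur,
                             signal = (dig - digMin[i]) * scale + physMin[i])
  }
  startTime <- as.POSIXct(paste(startDate, startClock), tz = "UTC",
                          format = "%d.%m.%y %H.%M.%S")
  list(startTime = startTime, channels = out)
}

#' Write channels to a minimal EDF file
#'
#' Intended for building synthetic reference recordings (effort and ECG
#' waveforms) that [readEDF()] can restore; physical values are quantised to
#' the 16-bit digital range spanned by each channel.
#'
#' @param channels named list of `list(fs, signal)` entries; names become
#'   channel labels.
#' @param path output file.
#' @param startTime recording start (`POSIXct`).
#' @param recordDur data-record duration in seconds.
#' @return `path`, invisibly.
#' @export
writeEDF <- function(channels, path,
                     startTime = as.POSIXct("2026-01-01 23:00:00", tz = "UTC"),
                     recordDur = 1) {
  ns <- length(channels)
  nSamp <- vapply(channels, function(ch) as.integer(round(ch$fs * recordDur)),
                  integer(1))
  nRecords <- min(vapply(channels, function(ch)
    floor(length(ch$signal) / (ch$fs * recordDur)), numeric(1)))
  fmt8 <- function(v) {
    s <- format(signif(v, 5))
    if (nchar(s) > 8) s <- formatC(v, format = "g", digits = 2)
    s
  }
  physMin <- vapply(channels, function(ch) min(ch$signal), numeric(1))
  physMax <- vapply(channels, function(ch) max(ch$signal), numeric(1))
  physMax <- ifelse(physMax > physMin, physMax, physMin + 1)
  # quantise against the values as actually written to the header
  physMin <- as.numeric(vapply(physMin, fmt8, character(1)))
  physMax <- as.numeric(vapply(physMax, fmt8, character(1)))
  physMax <- ifelse(physMax > physMin, physMax, physMin + 1)
  digMin <- rep(-32768L, ns); digMax <- rep(32767L, ns)
  pad <- function(x, width) formatC(as.character(x), width = width,
                                    flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeBin(charToRaw(pad(x, width)), con)
  headerBytes <- 256L + 256L * ns
  wr("0", 8); wr("synthetic", 80); wr("synthetic", 80)
  wr(format(startTime, "%d.%m.%y"), 8)
  wr(format(startTime, "%H.%M.%S"), 8)
  wr(headerBytes, 8); wr("", 44); wr(nRecords, 8)
  wr(format(recordDur), 8); wr(ns, 4)
  for (lab in names(channels)) wr(lab, 16)
  for (i in seq_len(ns)) wr("synthetic", 80)
  for (i in seq_len(ns)) wr("au", 8)
  for (v in physMin) wr(format(v), 8)
  for (v in physMax) wr(format(v), 8)
  for (v in digMin) wr(v, 8)
  for (v in digMax) wr(v, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (v in nSamp) wr(v, 8)
  for (i in seq_len(ns)) wr("", 32)
  pm <- physMin; px <- physMax
  for (r in seq_len(nRecords)) {
    for (i in seq_len(ns)) {
      idx <- ((r - 1) * nSamp[i] + 1):(r * nSamp[i])
      x <- channels[[i]]$signal[idx]
      dig <- round((x - pm[i]) / (px[i] - pm[i]) *
                     (digMax[i] - digMin[i]) + digMin[i])
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con, size = 2L,
               endian = "little")
    }
  }
  invisible(path)
}
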