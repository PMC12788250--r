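test_that("range transform is the per-chirp DFT over the sample axis", {
  cfg <- radarConfig(adcSamplesPerChirp = 64, nRangeBins = 16,
                     chirpsPerFrame = 2)
  # all-zero input stays zero
  zero <- array(0, dim = c(3, 2, 64))
  expect_true(all(rangeTransform(zero, cfg)@samples == 0))
  # a complex tone at normalized frequency k/N concentrates in range bin k
  k <- 5
  tone <- exp(2i * pi * k * (0:63) / 64)
  raw <- array(rep(tone, each = 3 * 2), dim = c(3, 2, 64))
  cube <- rangeTransform(raw, cfg)
  mags <- Mod(cube@samples[1, 1, ])
  expect_equal(which.max(mags), k + 1)   # 0-based bin k
  expect_gt(mags[k + 1], 100 * max(mags[-(k + 1)]))
  # random chirps match the O(N^2) DFT oracle
  set.seed(1)
  rnd <- array(complex(real = rnorm(2 * 2 * 64),
                       imaginary = rnorm(2 * 2 * 64)), dim = c(2, 2, 64))
  got <- rangeTransform(rnd, cfg)@samples
  for (f in 1:2) for (ch in 1:2) {
    want <- bruteDft(rnd[f, ch, ])[1:16]
    expect_lt(max(Mod(got[f, ch, ] - want)) / max(Mod(want)), 1e-9)
  }
  # dimension mismatches are configuration errors
  expect_error(rangeTransform(array(0, dim = c(3, 2, 63)), cfg),
               "configuration error")
})

test_that("chirp-median phase summarises frames at the frame rate", {
  cfg <- radarConfig(nRangeBins = 1, chirpsPerFrame = 20, frameRateHz = 20)
  mkCube <- function(phases) {  # phases: [frame, chirp] for one bin
    radarCube(array(exp(1i * phases), dim = c(nrow(phases), ncol(phases), 1)),
              cfg)
  }
  # identical chirp phases pass through
  cube <- mkCube(matrix(0.7, 3, 20))
  expect_equal(as.numeric(chirpMedianPhase(cube)@values), rep(0.7, 3))
  # 20 phases 0.00..0.19 -> mean of the 10th/11th order statistics
  cube <- mkCube(matrix(seq(0, 0.19, by = 0.01), 1, 20, byrow = TRUE))
  expect_equal(as.numeric(chirpMedianPhase(cube)@values), 0.095)
  # output sampling rate equals the frame rate
  expect_equal(chirpMedianPhase(cube)@samplingRateHz, 20)
  # invariance under chirp permutation
  set.seed(2)
  ph <- matrix(runif(5 * 20, -0.5, 0.5), 5, 20)
  perm <- ph[, sample(20)]
  expect_equal(chirpMedianPhase(mkCube(ph))@values,
               chirpMedianPhase(mkCube(perm))@values)
  # a constant offset shifts the (pre-unwrap) output by that constant,
  # including across the +/- pi wrap boundary
  base <- matrix(runif(5 * 20, -0.2, 0.2), 5, 20)
  off <- 3.0   # pushes phases across the wrap boundary
  shifted <- chirpMedianPhase(mkCube(base + off))@values
  plain <- chirpMedianPhase(mkCube(base))@values
  delta <- (shifted - plain - off) %% (2 * pi)
  expect_true(all(pmin(delta, 2 * pi - delta) < 1e-9))
})

test_that("phase converts to displacement by lambda / (4 pi)", {
  cfg <- radarConfig(carrierFreqHz = 60e9, nRangeBins = 2)
  mkSeries <- function(vals)
    new("DisplacementSeries", config = cfg,
        values = matrix(vals, ncol = 2), samplingRateHz = 20,
        units = "rad", startTime = as.POSIXct("2026-01-01", tz = "UTC"))
  lambdaMm <- 299792458 / 60e9 * 1000
  expect_equal(lambdaMm, 4.9965, tolerance = 1e-4)
  got <- phaseToDisplacement(mkSeries(c(0, pi, 4 * pi, 2)))
  expect_equal(displacementUnits(got), "mm")
  vals <- as.numeric(displacementValues(got))
  expect_equal(vals[1], 0)
  expect_equal(vals[2], 1.2491, tolerance = 1e-4)      # pi at 60 GHz
  expect_equal(vals[3], lambdaMm)                      # 4 pi -> one wavelength
  # linearity
  expect_equal(as.numeric(displacementValues(
    phaseToDisplacement(mkSeries(3 * c(0, pi, 4 * pi, 2))))), 3 * vals)
  badCfg <- cfg; badCfg@carrierFreqHz <- -1
  expect_error(phaseToDisplacement(mkSeries(rep(0, 4)), badCfg),
               "configuration error")
})

test_that("cube container round-trips losslessly and names missing members", {
  sim <- simulateScene(sceneConfig(
    seed = 8, durationS = 5,
    config = radarConfig(nRangeBins = 8, chirpsPerFrame = 4),
    heartbeatBins = 2:3, breathingBins = 5:7))
  cube <- sim$cube
  path <- withr::local_tempfile(fileext = ".rvc")
  writeCube(cube, path)
  back <- readCube(path)
  expect_identical(back@samples, cube@samples)
  expect_equal(back@config@frameRateHz, cube@config@frameRateHz)
  expect_equal(back@config@nRangeBins, cube@config@nRangeBins)
  expect_lt(abs(as.numeric(back@startTime) - as.numeric(cube@startTime)),
            1e-5)
  expect_equal(as.numeric(frameTimes(back)), as.numeric(frameTimes(cube)),
               tolerance = 1e-9)
  # a container whose header lacks "config" raises a format error naming it
  raw <- readBin(path, "raw", file.info(path)$size)
  hlen <- readBin(raw[9:12], "integer", size = 4L, endian = "little")
  header <- jsonlite::fromJSON(rawToChar(raw[13:(12 + hlen)]))
  header$config <- NULL
  hjson <- charToRaw(jsonlite::toJSON(header, auto_unbox = TRUE))
  bad <- withr::local_tempfile(fileext = ".rvc")
  con <- file(bad, "wb")
  writeBin(raw[1:8], con)
  writeBin(length(hjson), con, size = 4L, endian = "little")
  writeBin(hjson, con)
  writeBin(raw[(13 + hlen):length(raw)], con)
  close(con)
  expect_error(readCube(bad), 'missing member "config"')
  expect_error(readCube(withr::local_tempfile(fileext = ".x",
                                              lines = "not a cube")),
               "format error")
})
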