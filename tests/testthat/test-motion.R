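test_that("doppler map is the DFT along the chirp axis", {
  # static frame: all chirps identical -> all energy in velocity bin 1
  frame <- matrix(complex(real = 1, imaginary = 1), nrow = 8, ncol = 3)
  dm <- dopplerMap(frame)
  expect_true(all(Mod(dm[-1, ]) < 1e-12))
  expect_equal(Mod(dm[1, 1]), 8 * sqrt(2))
  # chirp-axis tone at m/M lands in velocity bin m + 1; matches brute DFT
  m <- 3
  tone <- exp(2i * pi * m * (0:7) / 8)
  dm <- dopplerMap(matrix(tone, 8, 1))
  expect_equal(which.max(Mod(dm)), m + 1)
  set.seed(3)
  rnd <- matrix(complex(real = rnorm(16), imaginary = rnorm(16)), 8, 2)
  want <- apply(rnd, 2, bruteDft)
  expect_lt(max(Mod(dopplerMap(rnd) - want)), 1e-9)
  # linearity and the single-chirp precondition
  expect_equal(dopplerMap(3 * rnd), 3 * dopplerMap(rnd))
  expect_error(dopplerMap(rnd[1, , drop = FALSE]), "at least 2 chirps")
})

test_that("motion parameter follows the five-step velocity summary", {
  cfg <- radarConfig(nRangeBins = 1, chirpsPerFrame = 2, frameRateHz = 1)
  # perfectly static epoch -> exactly 0
  static <- radarCube(array(rep(c(1 + 2i, 1 + 2i), each = 4),
                            dim = c(4, 2, 1)), cfg)
  expect_equal(motionParameter(static, c(0, 4)), 0)

  # 3-frame toy fixture, 2 chirps, 1 range bin: literal hand computation
  s <- array(c(1 + 0i, 0 + 1i, 2 + 0i,      # chirp 1 of frames 1..3
               1 + 0i, 0 - 1i, 1 + 1i),     # chirp 2 of frames 1..3
             dim = c(3, 2, 1))
  toy <- radarCube(s, cfg)
  prof <- sapply(1:3, function(f) {         # step 1-2: DFT + |.| over bins
    dft <- c(s[f, 1, 1] + s[f, 2, 1], s[f, 1, 1] - s[f, 2, 1])
    Mod(dft)
  })                                        # [velocity bin, frame]
  centred <- prof - apply(prof, 1, median)  # step 3
  w <- 0.54 - 0.46 * cos(2 * pi * c(0, 1))  # step 4: Hamming, unshifted
  hand <- sum(centred * w)                  # step 5
  expect_equal(motionParameter(toy, c(0, 3)), hand)

  # an injected high-velocity transient strictly raises the parameter
  cfg8 <- radarConfig(nRangeBins = 2, chirpsPerFrame = 8, frameRateHz = 4)
  base <- array(1 + 0i, dim = c(12, 8, 2))
  quiet <- radarCube(base, cfg8)
  burst <- base
  burst[6, , 1] <- exp(2i * pi * 4 * (0:7) / 8)  # near-Nyquist Doppler tone
  expect_gt(motionParameter(radarCube(burst, cfg8), c(0, 3)),
            motionParameter(quiet, c(0, 3)))
  # static-clutter invariance: adding a frame-constant profile changes nothing
  clutter <- base
  clutter[, , 2] <- clutter[, , 2] + (3 - 4i)
  expect_equal(motionParameter(radarCube(clutter, cfg8), c(0, 3)),
               motionParameter(quiet, c(0, 3)))
})

test_that("epoch slicing matches the floor formula and an enumeration", {
  expect_equal(nrow(epochSlices(60)), 1)
  expect_equal(nrow(epochSlices(59)), 0)
  expect_equal(nrow(epochSlices(300)), 49)
  # enumeration oracle across durations
  for (L in c(0, 1, 59.9, 60, 61, 137, 500, 3600, 9999)) {
    starts <- seq(0, by = 5, length.out = 10000)
    nOracle <- sum(starts + 60 <= L + 1e-9)
    sl <- epochSlices(L)
    expect_equal(nrow(sl), nOracle)
    if (nrow(sl)) expect_true(all(sl$end_s <= L + 1e-9))
  }
})

test_that("motion smoothing is a centred edge-truncated moving average", {
  grid <- epochGrid(1800)                     # 349 epochs, 5 s spacing
  n <- nEpochs(grid)
  expect_equal(smoothMotion(rep(2.5, n), grid), rep(2.5, n))
  # unit impulse spreads into a 61-epoch plateau of height 1/61
  imp <- rep(0, n); imp[200] <- 1
  sm <- smoothMotion(imp, grid)
  expect_equal(sm[170:230], rep(1 / 61, 61))
  expect_equal(sm[169], 0)
  expect_equal(sm[231], 0)
  # direct averaging oracle on random data
  set.seed(4)
  raw <- rnorm(n)
  sm <- smoothMotion(raw, grid)
  starts <- epochStarts(grid)
  oracle <- vapply(seq_len(n), function(i)
    mean(raw[abs(starts - starts[i]) <= 150 + 1e-9]), numeric(1))
  expect_equal(sm, oracle)
})

test_that("exclusion marks epochs strictly above the overnight mean", {
  expect_false(any(exclusionMask(rep(3, 10))))
  expect_equal(exclusionMask(c(0, 0, 0, 10)), c(FALSE, FALSE, FALSE, TRUE))
  set.seed(5)
  for (i in 1:20) {
    s <- rnorm(50)
    expect_lt(mean(exclusionMask(s)), 1)
  }
  # Monte-Carlo: on iid symmetric noise the excluded fraction matches the
  # mass above the mean within 3 standard errors
  set.seed(6)
  x <- rnorm(1e4)
  frac <- mean(exclusionMask(x, mean(x)))
  se <- sqrt(0.5 * 0.5 / 1e4)
  expect_lt(abs(frac - 0.5), 3 * se)
})

test_that("sleep-window cropping retains 22:00-06:00 across midnight", {
  cfg <- radarConfig(nRangeBins = 2, chirpsPerFrame = 2, frameRateHz = 1)
  mk <- function(startClock, hours) {
    n <- hours * 3600
    radarCube(array(1 + 0i, dim = c(n, 2, 2)), cfg,
              as.POSIXct(paste("2026-01-01", startClock), tz = "UTC"))
  }
  # 18:00-07:00 recording crops to the 8-h window
  crop <- cropWindow(mk("18:00:00", 13))
  expect_equal(nFrames(crop), 8 * 3600)
  expect_equal(format(crop@startTime, "%H:%M:%S"), "22:00:00")
  # entirely outside -> empty
  expect_equal(nFrames(cropWindow(mk("10:00:00", 2))), 0)
  # entirely inside -> unchanged
  inside <- mk("23:00:00", 6)
  expect_equal(nFrames(cropWindow(inside)), nFrames(inside))
  expect_equal(cropWindow(inside)@startTime, inside@startTime)
})
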