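test_that("sublevel diagrams follow the elder rule", {
  # constant and monotone series: essential class only
  for (s in list(rep(2, 10), 1:10, seq(5, 1))) {
    d <- sublevelDiagram(s)
    expect_equal(nrow(persistencePairs(d)), 0)
    expect_equal(nrow(essentialClasses(d)), 1)
    expect_equal(essentialClasses(d)$birth, min(s))
  }
  # the worked example: one finite pair (1, 2), essential born at 0
  d <- sublevelDiagram(c(0, 2, 1, 3))
  expect_equal(persistencePairs(d)$birth, 1)
  expect_equal(persistencePairs(d)$death, 2)
  expect_equal(essentialClasses(d)$birth, 0)
})

test_that("sublevel diagrams match the union-find oracle exactly", {
  set.seed(10)
  for (i in 1:200) {
    x <- switch(1 + i %% 4,
                rnorm(50),
                round(rnorm(50), 1),          # heavy ties
                sin(seq(0, 7, length.out = 50)) + rnorm(50, 0, 0.2),
                sample(rep(1:5, 10)))         # plateaus
    got <- persistencePairs(sublevelDiagram(x))
    got <- got[order(got$birth, got$death), , drop = FALSE]
    want <- sublevelOracle(x)
    expect_equal(nrow(got), nrow(want$pairs))
    if (nrow(got)) {
      expect_equal(got$birth, want$pairs[, 1])
      expect_equal(got$death, want$pairs[, 2])
    }
    expect_equal(essentialClasses(sublevelDiagram(x))$birth, want$essential)
    # finite pair count = strict local minima - 1 (generic series)
    if (i %% 4 == 0) {
      y <- rnorm(50)
      mins <- sum(diff(sign(diff(y))) > 0) +
        (y[1] < y[2]) + (y[50] < y[49])
      expect_equal(nrow(persistencePairs(sublevelDiagram(y))), mins - 1)
    }
  }
  # shift invariance: diagram translates, persistences unchanged
  x <- rnorm(40)
  d0 <- persistencePairs(sublevelDiagram(x))
  d7 <- persistencePairs(sublevelDiagram(x + 7))
  expect_equal(d7$birth, d0$birth + 7)
  expect_equal(d7$death - d7$birth, d0$death - d0$birth)
})

test_that("delay embedding produces the expected point cloud", {
  expect_equal(nrow(delayEmbed(1:10, 2, 3)), 7)
  expect_equal(ncol(delayEmbed(1:10, 3, 2)), 3)
  cloud <- delayEmbed(rep(1, 10), 2, 2)
  expect_true(all(cloud == 1))
  # sinusoid with quarter-period lag traces a circle of radius = amplitude
  fs <- 100; f <- 1; a <- 2.5
  x <- a * sin(2 * pi * f * (0:399) / fs)
  cloud <- delayEmbed(x, 2, fs / (4 * f))
  radii <- sqrt(rowSums(cloud^2))
  expect_equal(radii, rep(a, length(radii)), tolerance = 1e-6)
  expect_error(delayEmbed(1:5, 2, 10), "too short")
})

test_that("Rips diagrams match boundary-matrix reduction on small clouds", {
  # unit square: one 1-dim pair (1, sqrt(2)); equilateral: none
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  p1 <- persistencePairs(ripsDiagram(sq), dim = 1)
  expect_equal(nrow(p1), 1)
  expect_equal(p1$birth, 1)
  expect_equal(p1$death, sqrt(2))
  eq <- rbind(c(0, 0), c(2, 0), c(1, sqrt(3)))
  expect_equal(nrow(persistencePairs(ripsDiagram(eq), dim = 1)), 0)
  # any cloud: n - 1 finite 0-dim pairs
  set.seed(11)
  for (n in c(2, 4, 6, 9)) {
    cloud <- matrix(rnorm(n * 3), ncol = 3)
    expect_equal(nrow(persistencePairs(ripsDiagram(cloud), dim = 0)), n - 1)
  }
  # exact agreement with the full reduction oracle for clouds of 3..6 points
  for (i in 1:30) {
    n <- 3 + i %% 4
    cloud <- matrix(round(rnorm(n * 2), 2), ncol = 2)
    got <- sortPairs(persistencePairs(ripsDiagram(cloud)))
    want <- ripsOracle(cloud)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$dim, want$dim)
    expect_equal(got$birth, want$birth, tolerance = 1e-9)
    expect_equal(got$death, want$death, tolerance = 1e-9)
  }
  expect_error(ripsDiagram(matrix(0, 1, 2)), "at least 2 points")
})

test_that("periodicity scores summarise diagrams as specified", {
  empty <- persistenceDiagram(
    data.frame(birth = numeric(), death = numeric(), dim = integer()),
    data.frame(birth = numeric(), dim = integer()))
  s <- periodicityScores(empty, empty)
  expect_equal(unname(unlist(s)), c(0, 0, 0, 0))
  # sinusoid of amplitude a over m periods: count within 1 of m,
  # max persistence close to 2a
  a <- 1.7; m <- 9
  x <- a * sin(2 * pi * m * seq(0, 1, length.out = 4000))
  s <- periodicityScores(sublevelDiagram(x), tau = a)
  expect_lte(abs(s$persistence_count_0 - m), 1)
  expect_equal(s$max_persistence_0, 2 * a, tolerance = 1e-3)
  # denser sampling converges the max persistence to 2a
  coarse <- a * sin(2 * pi * m * seq(0, 1, length.out = 200))
  sc <- periodicityScores(sublevelDiagram(coarse))
  expect_lte(sc$max_persistence_0, s$max_persistence_0 + 1e-12)
  # unit-square cloud: persistence ratio sqrt(2)
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  s1 <- periodicityScores(empty, ripsDiagram(sq))
  expect_equal(s1$persistence_ratio_1, sqrt(2))
})
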