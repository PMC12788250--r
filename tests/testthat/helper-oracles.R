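# Independent brute-force oracles used across the suite. These deliberately
# re-derive results by the most literal method available (O(N^2) DFT sums,
# full boundary-matrix reduction, all-pairs rank statistics) so that the
# package implementations are checked against an unrelated code path.

# direct O(N^2) discrete Fourier transform
bruteDft <- function(x) {
  n <- length(x)
  vapply(seq_len(n) - 1, function(k)
    sum(x * exp(-2i * pi * k * (seq_len(n) - 1) / n)), complex(1))
}

# 0-dim sublevel-set persistence by literal union-find over increasing
# values, elder rule, ties by index (earlier = older)
sublevelOracle <- function(x) {
  n <- length(x)
  ord <- order(x, seq_len(n))
  parent <- rep(NA_integer_, n)
  birth <- rep(NA_integer_, n)
  rankOf <- integer(n); rankOf[ord] <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  pairs <- NULL
  for (i in ord) {
    parent[i] <- i; birth[i] <- i
    for (j in c(i - 1, i + 1)) {
      if (j < 1 || j > n || is.na(parent[j])) next
      ri <- find(i); rj <- find(j)
      if (ri == rj) next
      older <- if (rankOf[birth[ri]] < rankOf[birth[rj]]) ri else rj
      younger <- if (older == ri) rj else ri
      if (x[i] > x[birth[younger]])
        pairs <- rbind(pairs, c(x[birth[younger]], x[i]))
      parent[younger] <- older
    }
  }
  essential <- x[ord[1]]
  if (is.null(pairs)) pairs <- matrix(numeric(), ncol = 2)
  list(pairs = pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE],
       essential = essential)
}

# Vietoris-Rips persistence (dims 0 and 1) by full boundary-matrix reduction
# over GF(2), feasible for <= 6 points
ripsOracle <- function(pts) {
  n <- nrow(pts)
  d <- as.matrix(dist(pts))
  # simplices: list(vertices, diam, dim)
  simp <- list()
  for (i in seq_len(n)) simp[[length(simp) + 1]] <- list(v = i, diam = 0, dim = 0L)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    simp[[length(simp) + 1]] <- list(v = c(i, j), diam = d[i, j], dim = 1L)
  if (n >= 3)
    for (i in seq_len(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n)
      simp[[length(simp) + 1]] <- list(v = c(i, j, k),
                                       diam = max(d[i, j], d[i, k], d[j, k]),
                                       dim = 2L)
  ord <- order(vapply(simp, `[[`, 0, "diam"),
               vapply(simp, `[[`, 0L, "dim"),
               vapply(simp, function(s) sum(s$v * n^(seq_along(s$v) - 1)), 0))
  simp <- simp[ord]
  m <- length(simp)
  key <- vapply(simp, function(s) paste(s$v, collapse = "-"), "")
  idxOf <- setNames(seq_len(m), key)
  # boundary columns as sorted index vectors
  cols <- lapply(simp, function(s) {
    if (s$dim == 0L) return(integer())
    faces <- combn(s$v, length(s$v) - 1, simplify = FALSE)
    sort(unname(idxOf[vapply(faces, paste, "", collapse = "-")]))
  })
  lowOf <- rep(NA_integer_, m)
  pairs <- NULL
  for (j in seq_len(m)) {
    col <- cols[[j]]
    repeat {
      if (!length(col)) break
      low <- max(col)
      prev <- which(lowOf == low)
      if (!length(prev)) break
      col <- sort(union(setdiff(col, cols[[prev]]), setdiff(cols[[prev]], col)))
      cols[[j]] <- col
    }
    if (length(col)) {
      low <- max(col)
      lowOf[j] <- low
      b <- simp[[low]]$diam; dd <- simp[[j]]$diam
      if (dd > b)
        pairs <- rbind(pairs, data.frame(birth = b, death = dd,
                                         dim = simp[[low]]$dim))
    }
  }
  if (is.null(pairs)) pairs <- data.frame(birth = numeric(), death = numeric(),
                                          dim = integer())
  pairs[order(pairs$dim, pairs$birth, pairs$death), , drop = FALSE]
}

# Spearman correlation by the literal all-pairs mid-rank formula
spearmanOracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  num <- mean((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(mean((rx - mean(rx))^2)) * sqrt(mean((ry - mean(ry))^2))
  num / den
}

# sort pairs data frame for multiset comparison
sortPairs <- function(p) p[order(p$dim, p$birth, p$death), , drop = FALSE]

# small deterministic scenes shared across tests (built once per run)
.fixtureEnv <- new.env(parent = emptyenv())

smallScene <- function() {
  if (is.null(.fixtureEnv$small)) {
    cfg <- radarConfig(nRangeBins = 16, chirpsPerFrame = 8)
    sc <- sceneConfig(seed = 3, durationS = 300, config = cfg,
                      heartbeatBins = 4:6, breathingBins = 9:13)
    .fixtureEnv$small <- simulateScene(sc)
  }
  .fixtureEnv$small
}

smallDisp <- function() {
  if (is.null(.fixtureEnv$smallDisp))
    .fixtureEnv$smallDisp <- phaseToDisplacement(
      chirpMedianPhase(smallScene()$cube))
  .fixtureEnv$smallDisp
}
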