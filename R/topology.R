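## Persistence-homology primitives: sublevel-set filtration of a 1-D series,
## delay embedding, Vietoris-Rips filtration and diagram summary scores.

#' 0-dimensional persistence of the sublevel-set filtration
#'
#' Processes the values of a 1-D series in increasing order and tracks
#' connected components of the sublevel sets with a union-find: a component
#' born at a (strict) local minimum dies when it merges into a component
#' with an older birth (elder rule). Ties between equal values are broken by
#' index, the earlier index being older. The global minimum yields the
#' single essential class. For an oscillating series each oscillation
#' trough/peak pair contributes one finite pair whose persistence is the
#' local peak-to-trough excursion, which is what makes the diagram a shape
#' detector for breathing and heartbeat cycles.
#'
#' @param series numeric vector, length >= 1.
#' @return A [PersistenceDiagram-class] with dimension-0 pairs.
#' @examples
#' persistencePairs(sublevelDiagram(c(0, 2, 1, 3)))  # one pair (1, 2)
#' @export
sublevelDiagram <- function(series) {
  stopifnot(length(series) >= 1)
  res <- cpp_sublevel_pairs(as.numeric(series))
  persistenceDiagram(
    pairs = data.frame(birth = res$birth, death = res$death,
                       dim = rep(0L, length(res$birth))),
    essential = data.frame(birth = res$essential_birth, dim = 0L))
}

#' Delay embedding of a series
#'
#' Point `i` of the embedding is
#' `(x_i, x_{i+lag}, ..., x_{i+(d-1)lag})`; a periodic series traces a
#' closed loop in the embedding space, which the Vietoris--Rips filtration
#' then detects as a persistent 1-cycle. At the default dimension 2 a lag of
#' a quarter period maximises the circularity of the loop.
#'
#' @param series numeric vector of length at least
#'   `(dimension - 1) * lagSamples + 1`.
#' @param dimension embedding dimension (>= 2).
#' @param lagSamples delay in samples (>= 1).
#' @return Numeric matrix with `length(series) - (dimension - 1) * lagSamples`
#'   rows and `dimension` columns.
#' @export
delayEmbed <- function(series, dimension = 2, lagSamples = 1) {
  stopifnot(dimension >= 2, lagSamples >= 1)
  n <- length(series) - (dimension - 1) * lagSamples
  if (n < 1)
    stop("series too short for the requested embedding")
  vapply(seq_len(dimension) - 1L,
         function(k) series[seq_len(n) + k * lagSamples],
         numeric(n))
}

#' Vietoris--Rips persistence of a point cloud
#'
#' Euclidean Vietoris--Rips filtration up to dimension `maxDim` (at most 1):
#' an edge enters at the pairwise distance of its endpoints, higher simplices
#' at their longest edge. Dimension-0 pairs are computed by union-find over
#' the sorted edges (every point is born at 0, giving `n - 1` finite pairs
#' for distinct points); dimension-1 pairs by boundary-matrix reduction over
#' GF(2). Zero-persistence pairs are dropped, so for example three
#' equilateral points yield no finite 1-dimensional pair (the cycle is born
#' and filled at the same scale), while the four corners of the unit square
#' yield the single pair (1, sqrt(2)).
#'
#' @param points numeric matrix, one point per row (>= 2 points).
#' @param maxDim maximal homology dimension, 0 or 1 (default 1).
#' @return A [PersistenceDiagram-class].
#' @export
ripsDiagram <- function(points, maxDim = 1) {
  points <- as.matrix(points)
  if (nrow(points) < 2)
    stop("Rips filtration needs at least 2 points")
  stopifnot(maxDim %in% c(0, 1))
  res <- cpp_rips_pairs(points)
  pairs <- data.frame(birth = res$d0_birth, death = res$d0_death,
                      dim = rep(0L, length(res$d0_birth)))
  if (maxDim >= 1 && length(res$d1_birth))
    pairs <- rbind(pairs, data.frame(birth = res$d1_birth,
                                     death = res$d1_death,
                                     dim = rep(1L, length(res$d1_birth))))
  persistenceDiagram(pairs,
                     essential = data.frame(birth = 0, dim = 0L))
}

#' Summary scores of persistence diagrams
#'
#' For a pair of diagrams computed from the same window (dimension 0 from
#' the sublevel filtration, optionally dimension 1 from a Vietoris--Rips
#' filtration of the delay embedding) returns:
#' `max_persistence_0` -- the largest `death - birth` over finite
#' dimension-0 pairs (0 if none); `persistence_count_0` -- the number of
#' finite dimension-0 pairs with persistence at least `tau`;
#' `max_persistence_1` -- the analogue in dimension 1; and
#' `persistence_ratio_1` -- `death / birth` of the most persistent
#' dimension-1 pair (0 if none). A sinusoid of amplitude `a` spanning `m`
#' periods has `persistence_count_0(a)` within 1 of `m` and
#' `max_persistence_0` close to `2 a`.
#'
#' @param d0 a [PersistenceDiagram-class] (dimension 0).
#' @param d1 optional [PersistenceDiagram-class] with dimension-1 pairs.
#' @param tau persistence threshold for `persistence_count_0`.
#' @return Named list of the four scores.
#' @export
periodicityScores <- function(d0, d1 = NULL, tau = 0) {
  p0 <- persistencePairs(d0, dim = 0)
  pers0 <- p0$death - p0$birth
  out <- list(
    max_persistence_0 = if (length(pers0)) max(pers0) else 0,
    persistence_count_0 = sum(pers0 >= tau),
    max_persistence_1 = 0,
    persistence_ratio_1 = 0)
  if (!is.null(d1)) {
    p1 <- persistencePairs(d1, dim = 1)
    if (nrow(p1)) {
      pers1 <- p1$death - p1$birth
      top <- which.max(pers1)
      out$max_persistence_1 <- pers1[top]
      out$persistence_ratio_1 <- p1$death[top] / p1$birth[top]
    }
  }
  out
}

#' Serialise a persistence diagram to CSV
#'
#' Writes the finite pairs (columns `birth`, `death`, `dim`) to a CSV file.
#'
#' @param diagram a [PersistenceDiagram-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeDiagramCsv <- function(diagram, path) {
  utils::write.csv(diagram@pairs, path, row.names = FALSE)
  invisible(path)
}
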