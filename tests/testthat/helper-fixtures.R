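# Shared fixture builders and independent oracles.
# Everything here is deliberately naive (enumeration, closed forms) so it
# stays independent of the implementation paths it checks.

# subinteractome list realizing the reference size distribution:
# 63 below 7 partners, 30 in [7,15), 40 in [15,30), 27 in [30,70),
# 6 in [70,100] and 11 above 100
referenceSizeFixture <- function() {
  sizes <- rep(c(3L, 10L, 20L, 50L, 85L, 120L),
               times = c(63L, 30L, 40L, 27L, 6L, 11L))
  lapply(seq_along(sizes), function(i)
    Subinteractome(sprintf("O%03d", i),
                   sprintf("O%03d_P%03d", i, seq_len(sizes[i]))))
}

# the eight direct ORF-ORF interactions reported for the roster
referenceOrfPairs <- function() {
  matrix(c("C1ORF94",  "C1ORF109",
           "C1ORF112", "C11ORF87",
           "C1ORF52",  "CXORF56",
           "C2ORF74",  "C20ORF27",
           "C5ORF24",  "C16ORF71",
           "C5ORF51",  "C10ORF82",
           "C1ORF131", "C16ORF87",
           "C1ORF131", "C20ORF197"),
         ncol = 2, byrow = TRUE)
}

# all permutations of 1..n, built independently of the package
permsOracle <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  do.call(rbind, lapply(seq_len(n), function(i) {
    sub <- permsOracle(n - 1L)
    cbind(i, matrix(setdiff(seq_len(n), i)[sub], nrow(sub)))
  }))
}

# tie-free Spearman via the classical rank-difference formula
spearmanFormulaOracle <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# exact hypergeometric upper tail by direct enumeration over overlaps
hyperTailOracle <- function(k, m, N, n) {
  js <- k:min(m, n)
  sum(choose(m, js) * choose(N - m, n - js)) / choose(N, n)
}

# shortest path length by exhaustive simple-path enumeration
bruteShortestPath <- function(edgeList, from, to) {
  if (from == to) return(0L)
  best <- Inf
  nbr <- function(v) unique(c(edgeList[edgeList[, 1] == v, 2],
                              edgeList[edgeList[, 2] == v, 1]))
  recurse <- function(v, visited, depth) {
    if (depth >= best) return()
    for (w in nbr(v)) {
      if (w == to) { best <<- min(best, depth + 1L); next }
      if (!(w %in% visited)) recurse(w, c(visited, w), depth + 1L)
    }
  }
  recurse(from, from, 0L)
  best
}

# mean silhouette width for a 2-cluster labelling on a score matrix
silhouetteOracle <- function(scores, labels) {
  dmat <- as.matrix(dist(scores))
  s <- vapply(seq_len(nrow(scores)), function(i) {
    own <- labels == labels[i]; own[i] <- FALSE
    a <- mean(dmat[i, own])
    b <- mean(dmat[i, labels != labels[i]])
    (b - a) / max(a, b)
  }, 0)
  mean(s)
}

# small random undirected graph as an edge-list matrix (symbols V1..Vn)
randomEdgeList <- function(nNodes, pEdge) {
  nodes <- sprintf("V%02d", seq_len(nNodes))
  pairs <- t(combn(nodes, 2))
  pairs[runif(nrow(pairs)) < pEdge, , drop = FALSE]
}
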