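# Independent oracles and small graph builders used across the suite.
# These deliberately avoid the package's own code paths: modularity by an
# explicit double loop over node pairs, BH by the hand-applied step-up,
# the hypergeometric tail by enumerating draws, max-Q by scanning every
# set partition.

# quick network from parallel endpoint vectors
mkNet <- function(a, b, nodes = character()) {
  interactionNetwork(data.frame(a = a, b = b, type = "pp"), nodes = nodes)
}

triangleNet <- function(nm = c("A", "B", "C")) {
  mkNet(nm[c(1, 2, 3)], nm[c(2, 3, 1)])
}

# two k-cliques joined by a single bridge between their first members
twoCliquesBridge <- function(k = 4) {
  nm1 <- paste0("a", seq_len(k)); nm2 <- paste0("b", seq_len(k))
  p1 <- combn(nm1, 2); p2 <- combn(nm2, 2)
  mkNet(c(p1[1, ], p2[1, ], nm1[1]), c(p1[2, ], p2[2, ], nm2[1]))
}

randomNet <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  nm <- paste0("n", sprintf("%02d", seq_len(n)))
  if (igraph::gsize(g) == 0) return(interactionNetwork(nodes = nm))
  el <- igraph::as_edgelist(g)
  mkNet(nm[el[, 1]], nm[el[, 2]], nodes = nm)
}

randomConnectedNet <- function(n, p, seed) {
  s <- seed
  repeat {
    net <- randomNet(n, p, s)
    if (numEdges(net) >= 1 &&
        largestComponent(net)$nodeCount == n) return(net)
    s <- s + 1000L
  }
}

# modularity by explicit double loop: (1/2L) sum_ij (A_ij - d_i d_j / 2L)
# over same-module ordered pairs
bruteModularity <- function(net, assignment) {
  g <- asIgraph(net)
  nm <- igraph::V(g)$name
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  d <- rowSums(A)
  L <- sum(A) / 2
  cl <- assignment[nm]
  q <- 0
  for (i in seq_along(nm)) for (j in seq_along(nm)) {
    if (cl[i] == cl[j]) q <- q + A[i, j] - d[i] * d[j] / (2 * L)
  }
  unname(q) / (2 * L)
}

# all set partitions of 1..n as membership vectors (restricted growth)
allPartitions <- function(n) {
  out <- list()
  rec <- function(prefix, mx) {
    if (length(prefix) == n) { out[[length(out) + 1L]] <<- prefix; return() }
    for (v in seq_len(mx + 1L)) rec(c(prefix, v), max(mx, v))
  }
  rec(integer(), 0L)
  out
}

# exhaustive maximum modularity over all set partitions (same double-sum
# formula as bruteModularity, evaluated on a precomputed matrix so the
# scan over all partitions stays fast)
exhaustiveMaxQ <- function(net) {
  g <- asIgraph(net)
  nm <- igraph::V(g)$name
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  d <- rowSums(A)
  L <- sum(A) / 2
  M <- A - outer(d, d) / (2 * L)
  best <- -Inf; bestAsn <- NULL
  for (p in allPartitions(length(nm))) {
    q <- sum(M[outer(p, p, "==")]) / (2 * L)
    if (q > best) { best <- q; bestAsn <- setNames(p, nm) }
  }
  list(Q = best, assignment = bestAsn)
}

# hand-applied BH step-up: q_(i) = min_{j >= i} p_(j) m / j, clipped to 1
bhStepUp <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  running <- Inf
  for (i in rev(seq_len(m))) {
    running <- min(running, ps[i] * m / i)
    q[i] <- min(1, running)
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# P(X >= k) by enumerating every n-subset of a population of N with K
# successes
hyperTailEnum <- function(k, K, N, n) {
  if (n == 0) return(as.numeric(k <= 0))
  subs <- combn(N, n)
  succ <- colSums(subs <= K)   # items 1..K are the successes
  mean(succ >= k)
}

# degree multiset of a network as a sorted named vector
degreeVec <- function(net) {
  g <- asIgraph(net)
  d <- igraph::degree(g)
  d[order(names(d))]
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
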