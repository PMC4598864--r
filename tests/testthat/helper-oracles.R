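# Brute-force oracles kept deliberately independent of the package's
# vectorized implementations.

# pairwise shared-gene counts by explicit set intersection
bruteWeights <- function(preSets, postSets) {
  w <- matrix(0L, length(postSets), length(preSets))
  for (j in seq_along(postSets))
    for (i in seq_along(preSets))
      w[j, i] <- length(intersect(postSets[[j]], preSets[[i]]))
  w
}

# local clustering by triple loop over an adjacency matrix
bruteClustering <- function(adj) {
  n <- nrow(adj)
  vals <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(adj[v, ])
    if (length(nb) < 2) next
    links <- 0
    for (a in seq_along(nb)) for (b in seq_along(nb))
      if (a < b && adj[nb[a], nb[b]]) links <- links + 1
    vals[v] <- links / choose(length(nb), 2)
  }
  mean(vals)
}

# all-pairs shortest paths by BFS; Inf for unreachable
brutePaths <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    depth <- 0
    while (length(frontier)) {
      depth <- depth + 1
      nxt <- integer(0)
      for (v in frontier) nxt <- union(nxt, which(adj[v, ]))
      nxt <- nxt[!is.finite(d[s, nxt])]
      d[s, nxt] <- depth
      frontier <- nxt
    }
  }
  d
}

adjacencyOf <- function(g) {
  as.matrix(igraph::as_adjacency_matrix(g)) > 0
}

# small random expression fixture
randomSets <- function(n, gr, ge, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) sample.int(gr, ge))
}
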