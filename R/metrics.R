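#' Collapse edge multiplicities to a simple graph
#'
#' For path-length and clustering calculations, multiple connections between
#' a neuron pair are considered a single connection: the result is an
#' undirected simple graph containing an edge exactly where the pair shares
#' at least one gene.
#'
#' @param gmn a [CircularGMN-class].
#' @return an undirected [igraph::igraph] graph on the same neurons.
#' @export
collapseMultiedges <- function(gmn) {
  stopifnot(methods::is(gmn, "CircularGMN"))
  igraph::graph_from_adjacency_matrix(gmn@adjacency > 0, mode = "undirected")
}

#' Average shortest path length
#'
#' Mean geodesic (hop) distance over all connected ordered node pairs.
#' Disconnected pairs are excluded from the mean; the fraction of connected
#' pairs is attached as attribute `connectedFraction` so sparse graphs can
#' be interpreted honestly.
#'
#' @param g an [igraph::igraph] graph (see [collapseMultiedges()]).
#' @return numeric path length with attribute `connectedFraction`.
#' @export
averageShortestPath <- function(g) {
  stopifnot(igraph::is_igraph(g))
  if (igraph::ecount(g) == 0)
    stop("average path length is undefined for a graph with no edges",
         call. = FALSE)
  d <- igraph::distances(g)
  d <- d[row(d) != col(d)]
  finite <- is.finite(d)
  out <- mean(d[finite])
  attr(out, "connectedFraction") <- mean(finite)
  out
}

#' Average local clustering coefficient
#'
#' Watts-Strogatz clustering: for each node, the fraction of its neighbor
#' pairs that are themselves connected, averaged over nodes. Nodes of degree
#' less than two contribute zero.
#'
#' @param g an [igraph::igraph] graph.
#' @return coefficient in \[0, 1\].
#' @export
clusteringCoefficient <- function(g) {
  stopifnot(igraph::is_igraph(g))
  if (igraph::vcount(g) == 0) return(NaN)
  mean(igraph::transitivity(g, type = "local", isolates = "zero"))
}

#' Edge-matched random and ring-lattice reference networks
#'
#' Builds the two standard comparison networks for small-world
#' characterization: a uniform random graph with exactly `nEdges` edges
#' (G(n, m)) and a ring lattice in which every node is linked to its
#' `k/2 = round(nEdges/nNodes)` nearest neighbors on each side. The lattice
#' realizes the nearest achievable edge count `nNodes * round(nEdges/nNodes)`;
#' that count is attached to the result.
#'
#' @param nNodes node count.
#' @param nEdges edge count to match; must not exceed `n(n-1)/2`.
#' @param seed integer seed for the random graph.
#' @return list with elements `random` and `lattice` (both
#'   [igraph::igraph]), and `latticeEdges`, the lattice's achieved edge
#'   count.
#' @export
makeReferenceNetworks <- function(nNodes, nEdges, seed = NULL) {
  nNodes <- assertScalarCount(nNodes, "nNodes")
  nEdges <- assertScalarCount(nEdges, "nEdges", min = 0L)
  if (nEdges > nNodes * (nNodes - 1) / 2)
    stop("'nEdges' exceeds the number of available node pairs", call. = FALSE)
  random <- withSeed(seed, igraph::sample_gnm(nNodes, nEdges, directed = FALSE))
  kHalf <- max(1L, roundHalfUp(nEdges / nNodes))
  if (kHalf >= nNodes / 2)
    stop("lattice degree would exceed the node count", call. = FALSE)
  from <- rep(seq_len(nNodes), each = kHalf)
  off <- rep(seq_len(kHalf), times = nNodes)
  to <- (from + off - 1L) %% nNodes + 1L
  lattice <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  list(random = random, lattice = lattice,
       latticeEdges = igraph::ecount(lattice))
}

#' Degree-sequence-matched random graph
#'
#' Random simple graph with exactly the degree sequence of `g`, for
#' comparisons that must preserve each node's connection count rather than
#' just the total.
#'
#' @param g an [igraph::igraph] graph.
#' @param seed integer seed.
#' @return an [igraph::igraph] graph with the same degree sequence.
#' @export
degreeMatchedRandom <- function(g, seed = NULL) {
  stopifnot(igraph::is_igraph(g))
  withSeed(seed,
    igraph::sample_degseq(igraph::degree(g), method = "vl"))
}

#' Small-world metrics of one circular network realization
#'
#' Convenience wrapper computing path length and clustering of a circular
#' gene-matched network and of its edge-matched random and lattice
#' references, as one CSV-ready row.
#'
#' @param gmn a [CircularGMN-class].
#' @param seed seed for the reference random graph.
#' @return one-row data.frame with columns `n`, `edges`, `pathGMN`,
#'   `clustGMN`, `pathRandom`, `clustRandom`, `pathLattice`, `clustLattice`.
#' @export
smallWorldMetrics <- function(gmn, seed = NULL) {
  g <- collapseMultiedges(gmn)
  m <- igraph::ecount(g)
  ref <- makeReferenceNetworks(igraph::vcount(g), m, seed = seed)
  data.frame(
    n = igraph::vcount(g), edges = m,
    pathGMN = as.numeric(averageShortestPath(g)),
    clustGMN = clusteringCoefficient(g),
    pathRandom = as.numeric(averageShortestPath(ref$random)),
    clustRandom = clusteringCoefficient(ref$random),
    pathLattice = as.numeric(averageShortestPath(ref$lattice)),
    clustLattice = clusteringCoefficient(ref$lattice))
}
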