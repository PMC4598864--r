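#' Number of neurons in an object
#' @param x a GeneExpressionTable, CircularGMN or LayeredGMN.
#' @param ... further arguments for methods.
#' @return integer neuron count (for LayeredGMN, a vector per layer).
#' @export
setGeneric("nNeurons", function(x, ...) standardGeneric("nNeurons"))

#' Gene repertoire size (GR)
#' @param x an object holding gene attributes.
#' @return integer, the number of distinct gene identifiers available.
#' @export
setGeneric("geneRepertoire", function(x) standardGeneric("geneRepertoire"))

#' Genes expressed per neuron (GE)
#' @param x an object holding gene attributes.
#' @return integer GE (the exact per-neuron count in full-assignment mode,
#'   the maximum in rotational-budget mode).
#' @export
setGeneric("genesPerNeuron", function(x) standardGeneric("genesPerNeuron"))

#' Per-neuron gene sets
#' @param x an object holding gene attributes.
#' @return list of sorted integer vectors of gene ids, one per neuron.
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' Total connection count
#'
#' Number of connections in a network. With `mode = "multi"` every shared
#' gene of a neuron pair counts as one connection (the default connection
#' granularity throughout the package); with `mode = "unique"` multiple
#' connections between a pair collapse to a single one.
#'
#' @param x a CircularGMN, InterLayerWeights or LayeredGMN.
#' @param mode `"multi"` or `"unique"`.
#' @return integer connection count.
#' @export
setGeneric("connectionCount",
  function(x, mode = c("multi", "unique")) standardGeneric("connectionCount"))

#' Randomly replace a fraction of connections
#'
#' Treats every unit of weight (every shared-gene connection) as one
#' connection, removes `round(fraction * total)` uniformly chosen units and
#' adds the same number back as unit increments on uniformly random
#' (pre, post) neuron pairs. The total connection count is conserved exactly.
#' Applied to a [LayeredGMN-class], every inter-layer weight matrix is
#' rewired independently (child seeds derived from `seed`).
#'
#' @param x an [InterLayerWeights-class], a plain weight matrix, or a
#'   [LayeredGMN-class].
#' @param fraction proportion of connections to replace, in \[0, 1\].
#' @param seed integer seed.
#' @return an object of the same class as `x` with rewired weights.
#' @export
setGeneric("replaceConnections",
  function(x, fraction, seed = NULL) standardGeneric("replaceConnections"))

#' Randomly remove a fraction of connections
#'
#' Removes `round(fraction * total)` uniformly chosen shared-gene connection
#' units; nothing is added back.
#'
#' @inheritParams replaceConnections
#' @param fraction proportion of connections to delete, in \[0, 1).
#' @return an object of the same class as `x` with thinned weights.
#' @export
setGeneric("removeConnections",
  function(x, fraction, seed = NULL) standardGeneric("removeConnections"))
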