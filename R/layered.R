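#' Realize a multi-layer gene-matched network
#'
#' Draws an independent full-assignment gene-expression table for every
#' layer of the architecture (child seeds split off the root seed, so each
#' layer is reproducible on its own) and computes the shared-gene weight
#' matrix of every inter-layer edge.
#'
#' @param arch an [ArchitectureSpec-class].
#' @param gr gene-repertoire size shared by all layers.
#' @param ge genes expressed per neuron.
#' @param seed integer root seed.
#' @return a [LayeredGMN-class].
#' @examples
#' net <- buildLayeredGMN(chainArchitecture(3, 16, 40), gr = 10, ge = 3,
#'                        seed = 1)
#' res <- propagate(net, runif(16))
#' geneArrays(res)[[3]]
#' @export
buildLayeredGMN <- function(arch, gr, ge, seed = NULL) {
  stopifnot(methods::is(arch, "ArchitectureSpec"))
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  ly <- arch@layers
  expressions <- lapply(seq_len(nrow(ly)), function(k)
    sampleExpression(ly$n[k], gr, ge, seed = childSeed(seed, k)))
  weights <- lapply(seq_len(nrow(arch@edges)), function(k) {
    s <- match(arch@edges$from[k], ly$layer)
    t <- match(arch@edges$to[k], ly$layer)
    interlayerWeights(expressions[[s]], expressions[[t]])@weights
  })
  new("LayeredGMN", architecture = arch, expressions = expressions,
      weights = weights)
}

#' @describeIn LayeredGMN-class per-layer neuron counts.
#' @param x,object a `LayeredGMN`.
#' @param ... unused.
#' @export
setMethod("nNeurons", "LayeredGMN", function(x, ...)
  vapply(x@expressions, nNeurons, integer(1)))

#' @describeIn LayeredGMN-class gene-repertoire size.
#' @export
setMethod("geneRepertoire", "LayeredGMN", function(x)
  geneRepertoire(x@expressions[[1]]))

#' @describeIn LayeredGMN-class total connections over all inter-layer
#'   edges.
#' @param mode `"multi"` or `"unique"`.
#' @export
setMethod("connectionCount", "LayeredGMN", function(x, mode = c("multi", "unique")) {
  mode <- match.arg(mode)
  sum(vapply(x@weights, function(w)
    if (mode == "multi") sum(w) else sum(w > 0), numeric(1)))
})

#' Expression table of one layer
#' @param network a [LayeredGMN-class].
#' @param layer layer id.
#' @return a [GeneExpressionTable-class].
#' @export
layerExpression <- function(network, layer) {
  stopifnot(methods::is(network, "LayeredGMN"))
  network@expressions[[match(layer, network@architecture@layers$layer)]]
}

#' Architecture of a layered network
#' @param network a [LayeredGMN-class].
#' @return the [ArchitectureSpec-class].
#' @export
architecture <- function(network) {
  stopifnot(methods::is(network, "LayeredGMN"))
  network@architecture
}

setMethod("show", "LayeredGMN", function(object) {
  cat(sprintf("LayeredGMN: %d layers (sizes %s), GR = %d, GE = %d\n",
              length(object@expressions),
              paste(nNeurons(object), collapse = ", "),
              geneRepertoire(object),
              genesPerNeuron(object@expressions[[1]])))
  cat(sprintf("  %d inter-layer edges, %d total connections\n",
              length(object@weights), connectionCount(object, "multi")))
})

#' Propagate one input through a layered network
#'
#' Evaluates the layers in topological order. Layer 1 transmits its raw
#' input values (pixel intensities in \[0, 1\]); every other layer receives,
#' over each incoming edge, the source layer's transmitted vector times the
#' edge polarity, weighted by the shared-gene connection counts, mixes
#' converging edges at their (normalized) combination ratios, and activates
#' the top AP% of neurons by summed input. An activated neuron transmits 1,
#' all others 0, so each hidden layer acts as a binarizing nonlinear filter.
#'
#' @param network a [LayeredGMN-class].
#' @param input numeric vector over layer 1.
#' @return a list with elements `states` (per-layer
#'   [ActivationState-class]) and `geneArrays` (per-layer integer gene-count
#'   vectors), both indexed by layer id.
#' @export
propagate <- function(network, input) {
  stopifnot(methods::is(network, "LayeredGMN"))
  arch <- network@architecture
  ly <- arch@layers
  ed <- arch@edges
  if (length(input) != ly$n[1])
    stop("'input' length must equal the size of layer 1", call. = FALSE)
  order <- topologicalOrder(arch)
  transmitted <- vector("list", nrow(ly))
  states <- vector("list", nrow(ly))
  arrays <- vector("list", nrow(ly))
  names(states) <- names(arrays) <- as.character(ly$layer)
  for (id in order) {
    k <- match(id, ly$layer)
    if (k == 1L) {
      transmitted[[k]] <- as.numeric(input)
      active <- input > 0
      states[[k]] <- new("ActivationState", summedInput = as.numeric(input),
                         active = active, ap = NA_real_)
    } else {
      inc <- which(ed$to == id)
      drives <- lapply(inc, function(e) {
        s <- match(ed$from[e], ly$layer)
        summedInput(applyPolarity(transmitted[[s]], ed$polarity[e]),
                    network@weights[[e]])
      })
      drive <- combineInputs(drives, ed$ratio[inc])
      active <- apThreshold(drive, ly$ap[k])
      transmitted[[k]] <- as.numeric(active)
      states[[k]] <- new("ActivationState", summedInput = drive,
                         active = active, ap = ly$ap[k])
    }
    arrays[[k]] <- activeGeneArray(states[[k]]@active,
                                   network@expressions[[k]])
  }
  list(states = states, geneArrays = arrays)
}

#' Gene arrays of a propagation result
#' @param result the list returned by [propagate()].
#' @return list of per-layer integer gene-count vectors.
#' @export
geneArrays <- function(result) result$geneArrays

#' Activation states of a propagation result
#' @param result the list returned by [propagate()].
#' @return list of per-layer [ActivationState-class] objects.
#' @export
activationStates <- function(result) result$states
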