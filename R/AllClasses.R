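#' @import methods
#' @importFrom Matrix sparseMatrix rowSums colSums crossprod tcrossprod t diag
NULL

#' GeneExpressionTable: per-neuron gene attributes
#'
#' Records which genes each neuron of one layer expresses. Connectivity in a
#' gene-matched network is derived entirely from this table: two neurons are
#' connected once per shared gene. Internally the table is a sparse binary
#' membership matrix (neurons x genes).
#'
#' @slot membership sparse binary matrix, `n_neurons x GR`; entry (i, g) is 1
#'   when neuron i expresses gene g.
#' @slot genesPerNeuron integer, the number of genes expressed per neuron
#'   (GE). In full-assignment mode every neuron expresses exactly GE distinct
#'   genes; in rotational-budget mode GE is the maximum attained and rows may
#'   hold fewer genes.
#' @slot full logical; TRUE for full-assignment tables (every row has exactly
#'   GE genes).
#'
#' @seealso [sampleExpression()], [sampleExpressionRotational()],
#'   [buildCircularGMN()], [interlayerWeights()]
#' @export
setClass("GeneExpressionTable",
  representation(
    membership = "Matrix",
    genesPerNeuron = "integer",
    full = "logical"
  )
)

setValidity("GeneExpressionTable", function(object) {
  m <- object@membership
  msgs <- character()
  if (any(m@x != 1)) msgs <- c(msgs, "membership entries must be 0/1")
  rs <- Matrix::rowSums(m)
  ge <- object@genesPerNeuron
  if (length(ge) != 1L || is.na(ge) || ge < 0L)
    msgs <- c(msgs, "genesPerNeuron must be a single non-negative integer")
  if (isTRUE(object@full) && nrow(m) > 0 && any(rs != ge))
    msgs <- c(msgs, "full-assignment table must have exactly GE genes per neuron")
  if (!isTRUE(object@full) && nrow(m) > 0 && any(rs > ge))
    msgs <- c(msgs, "no neuron may express more than GE genes")
  if (length(msgs)) msgs else TRUE
})

#' CircularGMN: single-layer gene-matched network
#'
#' Undirected network over one layer of neurons in which a pair of neurons is
#' connected once per shared gene; the edge multiplicity of a pair equals the
#' size of the intersection of their gene sets.
#'
#' @slot expression the [GeneExpressionTable-class] the network was built from.
#' @slot adjacency symmetric integer matrix of shared-gene counts with zero
#'   diagonal (no self-edges).
#'
#' @seealso [buildCircularGMN()], [collapseMultiedges()], [connectionCount()]
#' @export
setClass("CircularGMN",
  representation(
    expression = "GeneExpressionTable",
    adjacency = "Matrix"
  )
)

setValidity("CircularGMN", function(object) {
  a <- object@adjacency
  msgs <- character()
  if (nrow(a) != ncol(a)) msgs <- c(msgs, "adjacency must be square")
  if (nrow(a) != nNeurons(object@expression))
    msgs <- c(msgs, "adjacency dimension must match neuron count")
  if (any(Matrix::diag(a) != 0)) msgs <- c(msgs, "self-edges are not allowed")
  if (length(msgs)) msgs else TRUE
})

#' InterLayerWeights: shared-gene connection counts between two layers
#'
#' Integer weight matrix between a pre-synaptic and a post-synaptic layer.
#' `weights[j, i]` is the number of genes shared by pre-neuron i and
#' post-neuron j, i.e. the number of parallel connections between the pair;
#' it is the linear operator applied during feed-forward propagation.
#'
#' @slot pre,post the [GeneExpressionTable-class]s of the two layers.
#' @slot weights dense integer matrix, `n_post x n_pre`.
#'
#' @seealso [interlayerWeights()], [summedInput()]
#' @export
setClass("InterLayerWeights",
  representation(
    pre = "GeneExpressionTable",
    post = "GeneExpressionTable",
    weights = "matrix"
  )
)

setValidity("InterLayerWeights", function(object) {
  msgs <- character()
  if (nrow(object@weights) != nNeurons(object@post))
    msgs <- c(msgs, "weights must have one row per post-layer neuron")
  if (ncol(object@weights) != nNeurons(object@pre))
    msgs <- c(msgs, "weights must have one column per pre-layer neuron")
  if (geneRepertoire(object@pre) != geneRepertoire(object@post))
    msgs <- c(msgs, "pre and post layers must share one gene repertoire")
  if (any(object@weights < 0)) msgs <- c(msgs, "weights must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' ArchitectureSpec: layered network topology
#'
#' Directed acyclic layout of a multi-layer gene-matched network: one row per
#' layer (size and activation percentage) and one row per inter-layer edge
#' (transmission polarity and combination weight). Layer 1 is the input layer
#' and transmits its raw input values; every other layer applies top-k
#' (activation-percentage) thresholding to its combined drive.
#'
#' @slot layers data.frame with columns `layer` (integer id), `n` (neuron
#'   count) and `ap` (activation percentage in (0, 100]; `NA` for the input
#'   layer, which is never thresholded).
#' @slot edges data.frame with columns `from`, `to` (layer ids), `polarity`
#'   (+1 excitatory or -1 inhibitory) and `ratio` (positive combination
#'   weight; a layer's incoming ratios are normalized to sum to one).
#'
#' @seealso [architectureSpec()], [chainArchitecture()], [buildLayeredGMN()]
#' @export
setClass("ArchitectureSpec",
  representation(layers = "data.frame", edges = "data.frame")
)

setValidity("ArchitectureSpec", function(object) {
  ly <- object@layers; ed <- object@edges
  msgs <- character()
  if (!all(c("layer", "n", "ap") %in% names(ly)))
    msgs <- c(msgs, "layers needs columns layer, n, ap")
  if (!all(c("from", "to", "polarity", "ratio") %in% names(ed)))
    msgs <- c(msgs, "edges needs columns from, to, polarity, ratio")
  if (length(msgs)) return(msgs)
  if (anyDuplicated(ly$layer)) msgs <- c(msgs, "duplicate layer ids")
  if (any(ly$n < 1)) msgs <- c(msgs, "layer sizes must be >= 1")
  ap <- ly$ap[!is.na(ly$ap)]
  if (any(ap <= 0 | ap > 100)) msgs <- c(msgs, "AP must lie in (0, 100]")
  if (nrow(ed)) {
    if (!all(ed$from %in% ly$layer) || !all(ed$to %in% ly$layer))
      msgs <- c(msgs, "edges refer to unknown layers")
    if (!all(ed$polarity %in% c(-1, 1)))
      msgs <- c(msgs, "polarity must be +1 or -1")
    if (any(ed$ratio <= 0)) msgs <- c(msgs, "combination ratios must be positive")
  }
  noIn <- setdiff(ly$layer[-1], ed$to)
  if (nrow(ly) > 1 && length(noIn))
    msgs <- c(msgs, paste("non-input layers without incoming edge:",
                          paste(noIn, collapse = ", ")))
  if (is.null(tryCatch(topologicalOrder(object), error = function(e) NULL)))
    msgs <- c(msgs, "layer graph must be acyclic")
  if (length(msgs)) msgs else TRUE
})

#' ActivationState: one layer's response to one input
#'
#' The per-neuron summed input of a layer together with the binary active
#' set chosen by activation-percentage thresholding: the top `round(AP/100 *
#' n)` neurons by summed input are active (ties broken by ascending index).
#' The `active` vector is the layer's active-neuron array ("neuron code").
#'
#' @slot summedInput numeric vector of per-neuron drives.
#' @slot active logical vector marking active neurons.
#' @slot ap the activation percentage applied (NA for the raw input layer).
#'
#' @seealso [apThreshold()], [propagate()]
#' @export
setClass("ActivationState",
  representation(summedInput = "numeric", active = "logical", ap = "numeric")
)

setValidity("ActivationState", function(object) {
  if (length(object@summedInput) != length(object@active))
    return("summedInput and active must have equal length")
  TRUE
})

#' LayeredGMN: realized multi-layer gene-matched network
#'
#' An [ArchitectureSpec-class] together with one independently sampled
#' [GeneExpressionTable-class] per layer and the realized shared-gene weight
#' matrix of every inter-layer edge. This is the object signals are
#' propagated through and that perturbation experiments modify.
#'
#' @slot architecture the layer/edge layout.
#' @slot expressions list of per-layer expression tables (in layer order).
#' @slot weights list of `n_post x n_pre` integer matrices, one per edge row
#'   of the architecture.
#'
#' @seealso [buildLayeredGMN()], [propagate()], [crossLayerConsistency()]
#' @export
setClass("LayeredGMN",
  representation(
    architecture = "ArchitectureSpec",
    expressions = "list",
    weights = "list"
  )
)

setValidity("LayeredGMN", function(object) {
  arch <- object@architecture
  msgs <- character()
  if (length(object@expressions) != nrow(arch@layers))
    msgs <- c(msgs, "one expression table per layer required")
  if (length(object@weights) != nrow(arch@edges))
    msgs <- c(msgs, "one weight matrix per edge required")
  for (k in seq_along(object@weights)) {
    w <- object@weights[[k]]
    s <- match(arch@edges$from[k], arch@layers$layer)
    t <- match(arch@edges$to[k], arch@layers$layer)
    if (nrow(w) != nNeurons(object@expressions[[t]]) ||
        ncol(w) != nNeurons(object@expressions[[s]]))
      msgs <- c(msgs, sprintf("weight matrix %d has wrong dimensions", k))
  }
  if (length(msgs)) msgs else TRUE
})
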