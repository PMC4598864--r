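#' Build a circular gene-matched network
#'
#' Connects every pair of neurons that expresses one or more common genes;
#' the multiplicity of the edge between a pair equals the number of genes
#' the two neurons share. Neurons expressing a common gene therefore form a
#' complete subnetwork, and neurons expressing several genes create
#' shortcuts between subnetworks.
#'
#' @param expression a [GeneExpressionTable-class].
#' @return a [CircularGMN-class].
#' @examples
#' gmn <- buildCircularGMN(sampleExpression(30, gr = 30, ge = 2, seed = 7))
#' head(edgeTable(gmn))
#' @export
buildCircularGMN <- function(expression) {
  stopifnot(methods::is(expression, "GeneExpressionTable"))
  a <- Matrix::tcrossprod(expression@membership)
  Matrix::diag(a) <- 0
  new("CircularGMN", expression = expression, adjacency = Matrix::drop0(a))
}

#' Edge list of a circular network
#' @param gmn a [CircularGMN-class].
#' @return data.frame with columns `i`, `j` (`i < j`) and `multiplicity`
#'   (shared-gene count).
#' @export
edgeTable <- function(gmn) {
  stopifnot(methods::is(gmn, "CircularGMN"))
  a <- methods::as(gmn@adjacency, "TsparseMatrix")
  keep <- a@i < a@j
  out <- data.frame(i = a@i[keep] + 1L, j = a@j[keep] + 1L,
                    multiplicity = as.integer(a@x[keep]))
  out[order(out$i, out$j), , drop = FALSE]
}

#' @describeIn CircularGMN-class number of neurons.
#' @param x,object a `CircularGMN`.
#' @param ... unused.
#' @export
setMethod("nNeurons", "CircularGMN", function(x, ...) nrow(x@adjacency))

#' @describeIn CircularGMN-class total connections, with multiplicity
#'   (`"multi"`) or one per connected pair (`"unique"`).
#' @param mode `"multi"` or `"unique"`.
#' @export
setMethod("connectionCount", "CircularGMN", function(x, mode = c("multi", "unique")) {
  mode <- match.arg(mode)
  a <- x@adjacency
  if (mode == "multi") as.integer(sum(a) / 2) else as.integer(sum(a > 0) / 2)
})

setMethod("show", "CircularGMN", function(object) {
  cat(sprintf(
    "CircularGMN: %d neurons, GR = %d; %d connections (%d unique pairs)\n",
    nNeurons(object), geneRepertoire(object@expression),
    connectionCount(object, "multi"), connectionCount(object, "unique")))
})

#' Shared-gene weight matrix between two layers
#'
#' Computes, for every cross-layer neuron pair, the number of genes shared
#' by the pre-layer and post-layer neuron; this count is the number of
#' parallel connections between the pair and the multiplicative weight used
#' when signals are summed in the post layer. For two independent
#' full-assignment layers the expected total weight is
#' `n_pre * n_post * GE^2 / GR` (hypergeometric mean of the pairwise
#' overlap), e.g. 500,000 for two 1000-neuron layers at GR = 50, GE = 5.
#'
#' @param pre,post [GeneExpressionTable-class]s drawn from the same gene
#'   repertoire.
#' @return an [InterLayerWeights-class].
#' @export
interlayerWeights <- function(pre, post) {
  stopifnot(methods::is(pre, "GeneExpressionTable"),
            methods::is(post, "GeneExpressionTable"))
  if (geneRepertoire(pre) != geneRepertoire(post))
    stop("pre and post layers must use the same gene repertoire", call. = FALSE)
  w <- as.matrix(Matrix::tcrossprod(post@membership, pre@membership))
  storage.mode(w) <- "integer"
  new("InterLayerWeights", pre = pre, post = post, weights = w)
}

#' Weight matrix of an InterLayerWeights object
#' @param x an [InterLayerWeights-class].
#' @return integer matrix, `n_post x n_pre`.
#' @export
weightMatrix <- function(x) {
  stopifnot(methods::is(x, "InterLayerWeights"))
  x@weights
}

#' @describeIn InterLayerWeights-class total cross-layer connections.
#' @param x,object an `InterLayerWeights`.
#' @param mode `"multi"` (sum of shared-gene counts) or `"unique"`
#'   (connected pairs).
#' @export
setMethod("connectionCount", "InterLayerWeights",
  function(x, mode = c("multi", "unique")) {
    mode <- match.arg(mode)
    if (mode == "multi") sum(x@weights) else sum(x@weights > 0)
  })

setMethod("show", "InterLayerWeights", function(object) {
  cat(sprintf(
    "InterLayerWeights: %d pre -> %d post neurons, GR = %d; total weight %d\n",
    nNeurons(object@pre), nNeurons(object@post),
    geneRepertoire(object@pre), connectionCount(object, "multi")))
})
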