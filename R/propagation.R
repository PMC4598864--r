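#' Weighted summed input of a layer
#'
#' Each active pre-layer neuron sends its value once per connection; a post
#' neuron's summed input is therefore the source vector weighted by the
#' shared-gene counts: `out[j] = sum_i w[j, i] * source[i]`.
#'
#' @param source numeric vector over the pre layer (raw pixel values for the
#'   input layer, binary activations elsewhere).
#' @param w an [InterLayerWeights-class] or a plain `n_post x n_pre` matrix.
#' @return numeric vector over the post layer.
#' @export
summedInput <- function(source, w) {
  if (methods::is(w, "InterLayerWeights")) w <- w@weights
  if (length(source) != ncol(w))
    stop("'source' length must equal the pre-layer size", call. = FALSE)
  as.numeric(w %*% source)
}

#' Activation-percentage (top-k) thresholding
#'
#' Activates exactly the `k = round(ap/100 * n)` neurons with the largest
#' summed inputs (half-up rounding). Ties at the activation boundary are
#' broken deterministically by ascending neuron index.
#'
#' @param summed numeric vector of summed inputs.
#' @param ap activation percentage in (0, 100].
#' @return logical vector: the active-neuron array.
#' @examples
#' apThreshold(c(3, 1, 4, 1), ap = 50)   # neurons 1 and 3
#' @export
apThreshold <- function(summed, ap) {
  if (length(ap) != 1L || is.na(ap) || ap <= 0 || ap > 100)
    stop("'ap' must lie in (0, 100]", call. = FALSE)
  n <- length(summed)
  k <- roundHalfUp(ap / 100 * n)
  active <- logical(n)
  if (k > 0)
    active[order(-summed, seq_len(n))[seq_len(k)]] <- TRUE
  active
}

#' Apply transmission polarity
#'
#' Negative polarity models an inhibitory source layer: the transmitted
#' vector is multiplied by -1, so downstream thresholding activates the
#' neurons that would otherwise rank lowest.
#'
#' @param values numeric vector.
#' @param polarity `+1` or `-1`.
#' @return `values * polarity`.
#' @export
applyPolarity <- function(values, polarity) {
  if (!(length(polarity) == 1L && polarity %in% c(-1, 1)))
    stop("'polarity' must be +1 or -1", call. = FALSE)
  values * polarity
}

#' Mix converging inputs at a combination ratio
#'
#' When several source layers converge on one layer, their drive vectors are
#' mixed as a weighted sum with the given combination ratio; ratios are
#' normalized to sum to one, so `ratio = c(1, 2)` yields `v1/3 + 2*v2/3`.
#'
#' @param vectors list of equal-length numeric vectors.
#' @param ratios positive weights, one per vector.
#' @return numeric vector of the mixed drive.
#' @export
combineInputs <- function(vectors, ratios) {
  if (!length(vectors)) stop("no input vectors supplied", call. = FALSE)
  if (length(vectors) != length(ratios))
    stop("'ratios' must match the number of vectors", call. = FALSE)
  if (any(ratios <= 0)) stop("combination ratios must be positive", call. = FALSE)
  len <- lengths(vectors)
  if (length(unique(len)) != 1L)
    stop("input vectors must have equal length", call. = FALSE)
  ratios <- ratios / sum(ratios)
  out <- numeric(len[1])
  for (k in seq_along(vectors)) out <- out + ratios[k] * vectors[[k]]
  out
}

#' Active-gene array ("gene code") of a layer state
#'
#' Histogram over the gene repertoire counting, for every gene, how many
#' active neurons express it. This vector traces the relative activity of
#' the overlapping complete subnetworks and is the layer's gene-code
#' representation of the transmitted information. For a full-assignment
#' table its entries always sum to `n_active * GE`.
#'
#' @param active logical (or 0/1) vector over the layer's neurons.
#' @param expression the layer's [GeneExpressionTable-class].
#' @return integer vector of length GR.
#' @export
activeGeneArray <- function(active, expression) {
  stopifnot(methods::is(expression, "GeneExpressionTable"))
  if (length(active) != nNeurons(expression))
    stop("'active' length must equal the layer size", call. = FALSE)
  as.integer(Matrix::crossprod(expression@membership, as.numeric(active)))
}

#' Per-neuron drive of a gene-space input
#'
#' Feeds a gene-array-valued input directly into a layer: each neuron's
#' drive is the sum of the array values of the genes it expresses. This is
#' the gene-space dual of [summedInput()] — identical to propagating through
#' a virtual pre-layer holding one neuron per gene.
#'
#' @param array numeric vector of length GR (e.g. a random gene-array input).
#' @param expression the receiving layer's [GeneExpressionTable-class].
#' @return numeric drive vector over the layer's neurons.
#' @export
geneArrayDrive <- function(array, expression) {
  stopifnot(methods::is(expression, "GeneExpressionTable"))
  if (length(array) != geneRepertoire(expression))
    stop("'array' length must equal the gene repertoire", call. = FALSE)
  as.numeric(expression@membership %*% array)
}

setMethod("show", "ActivationState", function(object) {
  cat(sprintf("ActivationState: %d neurons, %d active (AP = %s)\n",
              length(object@active), sum(object@active),
              if (is.na(object@ap)) "input layer" else object@ap))
})

#' Active-neuron array of an ActivationState
#' @param state an [ActivationState-class].
#' @return logical vector.
#' @export
activeNeurons <- function(state) {
  stopifnot(methods::is(state, "ActivationState"))
  state@active
}

#' Summed inputs of an ActivationState
#' @param state an [ActivationState-class].
#' @return numeric vector.
#' @export
summedInputs <- function(state) {
  stopifnot(methods::is(state, "ActivationState"))
  state@summedInput
}
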