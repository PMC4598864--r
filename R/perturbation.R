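# sample `r` distinct connection units from a weight matrix and return the
# per-entry removal counts (same shape as w)
sampleUnits <- function(w, r) {
  total <- sum(w)
  if (r > total) stop("cannot remove more connections than exist", call. = FALSE)
  nz <- which(w > 0)
  unitEntry <- rep(nz, times = w[nz])
  picked <- unitEntry[sample.int(total, r)]
  dec <- tabulate(picked, nbins = length(w))
  matrix(as.integer(dec), nrow(w), ncol(w))
}

checkFraction <- function(fraction, allowOne) {
  if (length(fraction) != 1L || is.na(fraction) || fraction < 0 ||
      fraction > 1 || (!allowOne && fraction == 1))
    stop(sprintf("'fraction' must lie in [0, 1%s", if (allowOne) "]" else ")"),
         call. = FALSE)
  fraction
}

replaceConnectionsMatrix <- function(w, fraction, seed = NULL) {
  checkFraction(fraction, allowOne = TRUE)
  r <- roundHalfUp(fraction * sum(w))
  if (r == 0) return(w)
  withSeed(seed, {
    out <- w - sampleUnits(w, r)
    add <- tabulate(sample.int(length(w), r, replace = TRUE),
                    nbins = length(w))
    out <- out + matrix(as.integer(add), nrow(w), ncol(w))
  })
  out
}

removeConnectionsMatrix <- function(w, fraction, seed = NULL) {
  checkFraction(fraction, allowOne = FALSE)
  r <- roundHalfUp(fraction * sum(w))
  if (r == 0) return(w)
  withSeed(seed, w - sampleUnits(w, r))
}

#' @rdname replaceConnections
#' @export
setMethod("replaceConnections", "matrix", function(x, fraction, seed = NULL)
  replaceConnectionsMatrix(x, fraction, seed))

#' @rdname replaceConnections
#' @export
setMethod("replaceConnections", "InterLayerWeights",
  function(x, fraction, seed = NULL) {
    x@weights <- replaceConnectionsMatrix(x@weights, fraction, seed)
    x
  })

#' @rdname replaceConnections
#' @export
setMethod("replaceConnections", "LayeredGMN", function(x, fraction, seed = NULL) {
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  x@weights <- lapply(seq_along(x@weights), function(k)
    replaceConnectionsMatrix(x@weights[[k]], fraction,
                             seed = childSeed(seed, k)))
  x
})

#' @rdname removeConnections
#' @export
setMethod("removeConnections", "matrix", function(x, fraction, seed = NULL)
  removeConnectionsMatrix(x, fraction, seed))

#' @rdname removeConnections
#' @export
setMethod("removeConnections", "InterLayerWeights",
  function(x, fraction, seed = NULL) {
    x@weights <- removeConnectionsMatrix(x@weights, fraction, seed)
    x
  })

#' @rdname removeConnections
#' @export
setMethod("removeConnections", "LayeredGMN", function(x, fraction, seed = NULL) {
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  x@weights <- lapply(seq_along(x@weights), function(k)
    removeConnectionsMatrix(x@weights[[k]], fraction,
                            seed = childSeed(seed, k)))
  x
})

subsetExpression <- function(expression, keep) {
  newExpressionTable(expression@membership[keep, , drop = FALSE],
                     genesPerNeuron(expression), expression@full)
}

#' Randomly remove a fraction of neurons
#'
#' Independently removes `round(fraction * n)` uniformly chosen neurons from
#' every non-spared layer of a layered network. The input layer is always
#' spared so the input dimensionality is unchanged; degradation experiments
#' that measure consistency from a reference layer typically spare that
#' layer too, so the measurement probe itself is not damaged. Inter-layer
#' weight matrices are rebuilt from the surviving neurons' gene expression,
#' and the activation percentage thereafter applies to the reduced layer
#' sizes.
#'
#' Removal is nested in the fraction: for a fixed seed, the neurons removed
#' at a smaller fraction are a subset of those removed at a larger one, so a
#' fraction sweep progressively degrades the same original network.
#'
#' @param network a [LayeredGMN-class].
#' @param fraction proportion of neurons to remove, in \[0, 1).
#' @param seed integer seed.
#' @param spare layer ids never touched (always includes layer 1).
#' @return a [LayeredGMN-class] with shrunken layers.
#' @export
removeNeurons <- function(network, fraction, seed = NULL, spare = 1) {
  stopifnot(methods::is(network, "LayeredGMN"))
  checkFraction(fraction, allowOne = FALSE)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  arch <- network@architecture
  ly <- arch@layers
  spare <- union(ly$layer[1], spare)
  expressions <- network@expressions
  for (k in seq_len(nrow(ly))) {
    if (ly$layer[k] %in% spare) next
    n <- nNeurons(expressions[[k]])
    drop <- roundHalfUp(fraction * n)
    if (drop == 0) next
    gone <- withSeed(childSeed(seed, k), sample.int(n, drop))
    expressions[[k]] <- subsetExpression(expressions[[k]],
                                         setdiff(seq_len(n), gone))
    ly$n[k] <- n - drop
  }
  weights <- lapply(seq_len(nrow(arch@edges)), function(e) {
    s <- match(arch@edges$from[e], ly$layer)
    t <- match(arch@edges$to[e], ly$layer)
    interlayerWeights(expressions[[s]], expressions[[t]])@weights
  })
  new("LayeredGMN", architecture = architectureSpec(ly, arch@edges),
      expressions = expressions, weights = weights)
}
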