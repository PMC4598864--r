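#' L1 (Manhattan) distance
#' @param a,b equal-length numeric vectors.
#' @return `sum(abs(a - b))`.
#' @export
l1Distance <- function(a, b) {
  if (length(a) != length(b))
    stop("vectors must have equal length", call. = FALSE)
  sum(abs(a - b))
}

#' Reliability slope of paired distances
#'
#' Ordinary-least-squares slope of the target-layer distances regressed on
#' the reference-layer distances of the same input pairs (intercept
#' fitted, slope reported). A slope near 1 means pairwise dissimilarity is
#' preserved across layers — the information-transfer reliability score.
#'
#' @param reference,target equal-length non-negative distance vectors, one
#'   entry per input pair.
#' @return the OLS slope (dimensionless).
#' @export
consistencySlope <- function(reference, target) {
  if (length(reference) != length(target))
    stop("distance vectors must have equal length", call. = FALSE)
  if (length(reference) < 2L)
    stop("at least two pairs are required", call. = FALSE)
  v <- stats::var(reference)
  if (v == 0)
    stop("reference distances have zero variance; slope undefined",
         call. = FALSE)
  stats::cov(reference, target) / v
}

# Batched propagation: runs every input (rows of `inputs`) through the
# network with one matrix product per layer. Returns per-layer active-neuron
# matrices (inputs x neurons); gene arrays are derived on demand.
propagateBatch <- function(network, inputs) {
  arch <- network@architecture
  ly <- arch@layers
  ed <- arch@edges
  if (ncol(inputs) != ly$n[1])
    stop("input length must equal the size of layer 1", call. = FALSE)
  nIn <- nrow(inputs)
  order <- topologicalOrder(arch)
  transmitted <- vector("list", nrow(ly))
  active <- vector("list", nrow(ly))
  names(active) <- as.character(ly$layer)
  for (id in order) {
    k <- match(id, ly$layer)
    if (k == 1L) {
      transmitted[[k]] <- t(inputs)            # neurons x inputs
      active[[k]] <- inputs > 0
    } else {
      inc <- which(ed$to == id)
      ratios <- ed$ratio[inc] / sum(ed$ratio[inc])
      drive <- matrix(0, ly$n[k], nIn)
      for (q in seq_along(inc)) {
        e <- inc[q]
        s <- match(ed$from[e], ly$layer)
        drive <- drive + (ratios[q] * ed$polarity[e]) *
          (network@weights[[e]] %*% transmitted[[s]])
      }
      act <- matrix(FALSE, nIn, ly$n[k])
      for (i in seq_len(nIn)) act[i, ] <- apThreshold(drive[, i], ly$ap[k])
      transmitted[[k]] <- t(act) * 1
      active[[k]] <- act
    }
  }
  active
}

# run a batch of inputs through a network once, returning the code arrays
# (rows = inputs) at the requested layers
layerResponses <- function(network, inputs, layers,
                           code = c("gene", "neuron")) {
  code <- match.arg(code)
  if (is.list(inputs)) inputs <- do.call(rbind, inputs)
  active <- propagateBatch(network, inputs)
  out <- lapply(layers, function(l) {
    a <- active[[as.character(l)]]
    if (code == "neuron") return(a * 1)
    k <- match(l, network@architecture@layers$layer)
    m <- network@expressions[[k]]@membership
    as.matrix(a %*% m)                          # inputs x GR gene counts
  })
  names(out) <- as.character(layers)
  out
}

samplePairs <- function(nInputs, nPairs, seed = NULL) {
  total <- nInputs * (nInputs - 1) / 2
  if (nPairs > total)
    stop("not enough inputs to form the requested number of pairs",
         call. = FALSE)
  pick <- withSeed(seed, sample.int(total, nPairs))
  # unrank upper-triangle pair index (column-major over i < j)
  j <- ceiling((1 + sqrt(1 + 8 * pick)) / 2)
  i <- pick - (j - 1) * (j - 2) / 2
  cbind(i = as.integer(i), j = as.integer(j))
}

pairDistances <- function(mat, pairs) {
  vapply(seq_len(nrow(pairs)),
         function(p) sum(abs(mat[pairs[p, 1], ] - mat[pairs[p, 2], ])),
         numeric(1))
}

#' Cross-layer consistency of information transfer
#'
#' Runs every input through the network, samples random input pairs, and
#' regresses the pairs' L1 distances at the target layer on their distances
#' at the reference layer, using either the active-neuron arrays
#' (`code = "neuron"`) or the active-gene arrays (`code = "gene"`). The
#' returned slope is the reliability score: it stays high across many
#' layers in a gene-matched network and collapses in a randomly connected
#' one.
#'
#' @param network a [LayeredGMN-class].
#' @param inputs matrix of inputs, one row per input (columns = layer-1
#'   size), or a list of vectors.
#' @param code `"gene"` or `"neuron"`.
#' @param referenceLayer,targetLayer layer ids; the reference precedes the
#'   target (defaults 2 and the last layer).
#' @param nPairs number of distinct input pairs sampled (default 1000).
#' @param seed seed for the pair sampling.
#' @return the consistency slope, with attribute `nPairs`.
#' @export
crossLayerConsistency <- function(network, inputs, code = c("gene", "neuron"),
                                  referenceLayer = 2, targetLayer = NULL,
                                  nPairs = 1000, seed = NULL) {
  stopifnot(methods::is(network, "LayeredGMN"))
  code <- match.arg(code)
  ids <- network@architecture@layers$layer
  if (is.null(targetLayer)) targetLayer <- ids[length(ids)]
  if (!(referenceLayer %in% ids) || !(targetLayer %in% ids))
    stop("unknown layer id", call. = FALSE)
  if (match(referenceLayer, ids) > match(targetLayer, ids))
    stop("'referenceLayer' must not come after 'targetLayer'", call. = FALSE)
  if (is.list(inputs)) inputs <- do.call(rbind, inputs)
  resp <- layerResponses(network, inputs, c(referenceLayer, targetLayer),
                         code = code)
  pairs <- samplePairs(nrow(inputs), nPairs, seed = seed)
  dRef <- pairDistances(resp[[as.character(referenceLayer)]], pairs)
  dTar <- pairDistances(resp[[as.character(targetLayer)]], pairs)
  out <- if (referenceLayer == targetLayer) 1
         else consistencySlope(dRef, dTar)
  attr(out, "nPairs") <- nPairs
  out
}
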