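newExpressionTable <- function(membership, ge, full) {
  new("GeneExpressionTable",
      membership = methods::as(methods::as(membership, "CsparseMatrix"), "dMatrix"),
      genesPerNeuron = as.integer(ge), full = full)
}

#' Build an expression table from explicit gene sets
#'
#' Constructor for hand-specified layouts: `sets` lists each neuron's
#' expressed gene ids.
#'
#' @param sets list of integer vectors of distinct gene ids in `1..gr`.
#' @param gr gene-repertoire size.
#' @return a [GeneExpressionTable-class]; full-assignment when all sets have
#'   equal size.
#' @examples
#' expressionTable(list(c(1, 2), c(2, 3), c(1, 3)), gr = 4)
#' @export
expressionTable <- function(sets, gr) {
  gr <- assertScalarCount(gr, "gr")
  stopifnot(is.list(sets), length(sets) >= 1)
  if (any(vapply(sets, anyDuplicated, integer(1)) > 0))
    stop("gene sets must not contain duplicates", call. = FALSE)
  genes <- unlist(sets)
  if (length(genes) && (min(genes) < 1 || max(genes) > gr))
    stop("gene ids must lie in 1..gr", call. = FALSE)
  m <- Matrix::sparseMatrix(i = rep(seq_along(sets), lengths(sets)),
                            j = genes, x = 1,
                            dims = c(length(sets), gr))
  sizes <- lengths(sets)
  newExpressionTable(m, max(sizes), full = all(sizes == max(sizes)))
}

#' Sample a full-assignment gene-expression table
#'
#' Assigns to each of `nNeurons` neurons an independent uniform random subset
#' of `ge` distinct genes drawn (without replacement) from a repertoire of
#' `gr` gene identifiers. This is the standard construction for layers of a
#' gene-matched network: the canonical configuration uses GR = 50 and GE = 5.
#'
#' @param nNeurons number of neurons in the layer.
#' @param gr gene-repertoire size (GR).
#' @param ge genes expressed per neuron (GE); must satisfy `1 <= ge <= gr`.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return a [GeneExpressionTable-class].
#' @examples
#' tab <- sampleExpression(8, gr = 6, ge = 2, seed = 1)
#' geneSets(tab)
#' @export
sampleExpression <- function(nNeurons, gr, ge, seed = NULL) {
  nNeurons <- assertScalarCount(nNeurons, "nNeurons")
  gr <- assertScalarCount(gr, "gr")
  ge <- assertScalarCount(ge, "ge")
  if (ge > gr) stop("'ge' must not exceed 'gr'", call. = FALSE)
  withSeed(seed, {
    genes <- vapply(seq_len(nNeurons), function(i) sample.int(gr, ge),
                    integer(ge))
  })
  m <- Matrix::sparseMatrix(i = rep(seq_len(nNeurons), each = ge),
                            j = as.vector(genes), x = 1,
                            dims = c(nNeurons, gr))
  newExpressionTable(m, ge, full = TRUE)
}

#' Sample expression rotationally up to a connection budget
#'
#' Builds a layer's gene assignment the way circular networks with a fixed
#' connection count are constructed: genes are drawn uniformly at random from
#' the repertoire and assigned to neurons one by one in rotation (neuron 1,
#' 2, ..., n, 1, ...), skipping a draw when the neuron already expresses that
#' gene. Assignment stops with the first gene whose addition brings the
#' network's total connection count up to `connectionBudget`.
#'
#' Connections are counted with shared-gene multiplicity by default
#' (`countMode = "multi"`); `countMode = "unique"` counts each connected
#' neuron pair once regardless of how many genes it shares.
#'
#' @param nNeurons number of neurons.
#' @param gr gene-repertoire size.
#' @param connectionBudget target connection count (e.g. 500 for the
#'   100-neuron circular networks).
#' @param seed integer seed.
#' @param countMode connection-counting convention while the budget is
#'   tracked: `"multi"` (default) or `"unique"`.
#' @return a [GeneExpressionTable-class] with `full = FALSE`.
#' @export
sampleExpressionRotational <- function(nNeurons, gr, connectionBudget,
                                       seed = NULL,
                                       countMode = c("multi", "unique")) {
  nNeurons <- assertScalarCount(nNeurons, "nNeurons")
  gr <- assertScalarCount(gr, "gr")
  connectionBudget <- assertScalarCount(connectionBudget, "connectionBudget",
                                        min = 0L)
  countMode <- match.arg(countMode)
  sets <- lapply(seq_len(nNeurons), function(i) logical(gr))
  members <- lapply(seq_len(gr), function(g) integer(0))
  adjacent <- if (countMode == "unique") matrix(FALSE, nNeurons, nNeurons)
  filled <- 0L
  total <- 0
  neuron <- 0L
  withSeed(seed, {
    while (total < connectionBudget) {
      if (filled >= nNeurons * gr)
        stop("connection budget unreachable: every neuron expresses ",
             "the full repertoire", call. = FALSE)
      neuron <- neuron %% nNeurons + 1L
      if (all(sets[[neuron]])) next
      g <- sample.int(gr, 1L)
      if (sets[[neuron]][g]) next
      peers <- members[[g]]
      if (countMode == "multi") {
        total <- total + length(peers)
      } else if (length(peers)) {
        new <- peers[!adjacent[peers, neuron]]
        total <- total + length(new)
        adjacent[new, neuron] <- TRUE
        adjacent[neuron, new] <- TRUE
      }
      sets[[neuron]][g] <- TRUE
      members[[g]] <- c(peers, neuron)
      filled <- filled + 1L
    }
  })
  counts <- vapply(sets, sum, integer(1))
  idx <- which(do.call(rbind, sets))
  m <- Matrix::sparseMatrix(
    i = ((idx - 1L) %% nNeurons) + 1L,
    j = ((idx - 1L) %/% nNeurons) + 1L,
    x = 1, dims = c(nNeurons, gr))
  newExpressionTable(m, max(counts, 0L), full = FALSE)
}

#' @describeIn GeneExpressionTable-class number of neurons in the table.
#' @param x,object a `GeneExpressionTable`.
#' @export
setMethod("nNeurons", "GeneExpressionTable", function(x, ...) nrow(x@membership))

#' @describeIn GeneExpressionTable-class gene-repertoire size (GR).
#' @export
setMethod("geneRepertoire", "GeneExpressionTable",
          function(x) ncol(x@membership))

#' @describeIn GeneExpressionTable-class genes per neuron (GE).
#' @export
setMethod("genesPerNeuron", "GeneExpressionTable",
          function(x) x@genesPerNeuron)

#' @describeIn GeneExpressionTable-class list of per-neuron gene-id vectors.
#' @export
setMethod("geneSets", "GeneExpressionTable", function(x) {
  m <- methods::as(x@membership, "TsparseMatrix")
  unname(split(m@j + 1L, factor(m@i + 1L, levels = seq_len(nrow(m)))))
})

#' Binary neuron-by-gene membership matrix
#' @param x a [GeneExpressionTable-class].
#' @return sparse 0/1 matrix, neurons in rows, genes in columns.
#' @export
membershipMatrix <- function(x) {
  stopifnot(methods::is(x, "GeneExpressionTable"))
  x@membership
}

#' Neurons expressing one gene (a complete subnetwork)
#'
#' All neurons expressing a common gene are pairwise connected in a circular
#' gene-matched network, so this set spans one complete subnetwork.
#'
#' @param expression a [GeneExpressionTable-class].
#' @param gene gene id in `1..GR`.
#' @return sorted integer vector of neuron ids (possibly empty).
#' @export
subnetworkMembers <- function(expression, gene) {
  stopifnot(methods::is(expression, "GeneExpressionTable"))
  gene <- assertScalarCount(gene, "gene")
  if (gene > geneRepertoire(expression))
    stop("'gene' is outside the repertoire", call. = FALSE)
  which(expression@membership[, gene] > 0)
}

#' Mean complete-subnetwork size
#'
#' Average over all genes of the number of neurons expressing the gene. For
#' full-assignment tables this equals `nNeurons * GE / GR` exactly in every
#' realization (every neuron contributes GE memberships, spread over GR
#' genes), e.g. 100 for a 1000-neuron layer with GR = 50, GE = 5.
#'
#' @param expression a [GeneExpressionTable-class].
#' @return numeric mean subnetwork size.
#' @export
meanSubnetworkSize <- function(expression) {
  stopifnot(methods::is(expression, "GeneExpressionTable"))
  sum(expression@membership) / geneRepertoire(expression)
}

setMethod("show", "GeneExpressionTable", function(object) {
  cat(sprintf("GeneExpressionTable: %d neurons, GR = %d, GE = %d (%s)\n",
              nNeurons(object), geneRepertoire(object),
              genesPerNeuron(object),
              if (object@full) "full assignment" else "rotational budget"))
})
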