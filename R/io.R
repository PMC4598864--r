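#' Write an expression table to tab-separated text
#'
#' Two-column format with a header line: `neuron_id<TAB>gene_id`, one row
#' per expressed gene, 1-based ids.
#'
#' @param expression a [GeneExpressionTable-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeExpressionTable <- function(expression, path) {
  stopifnot(methods::is(expression, "GeneExpressionTable"))
  m <- methods::as(expression@membership, "TsparseMatrix")
  df <- data.frame(neuron_id = m@i + 1L, gene_id = m@j + 1L)
  df <- df[order(df$neuron_id, df$gene_id), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression table from tab-separated text
#'
#' @param path file written by [writeExpressionTable()].
#' @param nNeurons,gr layer size and repertoire size; defaults to the
#'   maxima present in the file.
#' @return a [GeneExpressionTable-class].
#' @export
readExpressionTable <- function(path, nNeurons = NULL, gr = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (is.null(nNeurons)) nNeurons <- max(df$neuron_id)
  if (is.null(gr)) gr <- max(df$gene_id)
  m <- Matrix::sparseMatrix(i = df$neuron_id, j = df$gene_id, x = 1,
                            dims = c(nNeurons, gr))
  counts <- Matrix::rowSums(m)
  newExpressionTable(m, max(counts), full = all(counts == max(counts)))
}

#' Serialize an expression table to JSON
#'
#' @param expression a [GeneExpressionTable-class].
#' @param path optional output path; when `NULL` the JSON string is
#'   returned.
#' @return `path` invisibly, or the JSON string.
#' @export
expressionToJSON <- function(expression, path = NULL) {
  stopifnot(methods::is(expression, "GeneExpressionTable"))
  obj <- list(n_neurons = nNeurons(expression),
              gr = geneRepertoire(expression),
              ge = genesPerNeuron(expression),
              full = expression@full,
              expression = geneSets(expression))
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE))
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' Restore an expression table from JSON
#' @param path file path or JSON string from [expressionToJSON()].
#' @return a [GeneExpressionTable-class].
#' @export
expressionFromJSON <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  sets <- obj$expression
  if (is.matrix(sets)) sets <- split(sets, row(sets))
  idx <- rep(seq_along(sets), times = lengths(sets))
  m <- Matrix::sparseMatrix(i = idx, j = unlist(sets), x = 1,
                            dims = c(obj$n_neurons, obj$gr))
  newExpressionTable(m, obj$ge, full = isTRUE(obj$full))
}

#' Export a circular network as an edge list
#'
#' Plain-text `i<TAB>j<TAB>multiplicity` rows with a header, loadable by
#' standard graph tools.
#'
#' @param gmn a [CircularGMN-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(gmn, path) {
  utils::write.table(edgeTable(gmn), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
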