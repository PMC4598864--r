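#' Construct an architecture specification
#'
#' @param layers data.frame with columns `layer`, `n`, `ap` (AP in (0, 100];
#'   use `NA` for the raw input layer).
#' @param edges data.frame with columns `from`, `to`, `polarity` (+1/-1) and
#'   `ratio` (positive combination weight).
#' @return a validated [ArchitectureSpec-class].
#' @export
architectureSpec <- function(layers, edges) {
  layers <- as.data.frame(layers)
  edges <- as.data.frame(edges)
  if (!nrow(edges))
    edges <- data.frame(from = integer(0), to = integer(0),
                        polarity = numeric(0), ratio = numeric(0))
  methods::new("ArchitectureSpec", layers = layers, edges = edges)
}

# Kahn topological sort over layer ids; errors on cycles.
topologicalOrder <- function(arch) {
  ids <- arch@layers$layer
  ed <- arch@edges
  indeg <- stats::setNames(integer(length(ids)), ids)
  for (t in ed$to) indeg[as.character(t)] <- indeg[as.character(t)] + 1L
  queue <- ids[indeg[as.character(ids)] == 0L]
  out <- integer(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    out <- c(out, v)
    down <- ed$to[ed$from == v]
    for (t in down) {
      key <- as.character(t)
      indeg[key] <- indeg[key] - 1L
      if (indeg[key] == 0L) queue <- c(queue, t)
    }
  }
  if (length(out) != length(ids))
    stop("architecture contains a cycle", call. = FALSE)
  out
}

#' Simple chain architecture
#'
#' The canonical multi-layer layout: an input layer feeding a linear chain
#' of equally sized hidden layers with one activation percentage throughout
#' and positive polarity, as used for the image-transfer experiments
#' (input layer of 144 pixel neurons, nine 1000-neuron layers, AP = 50).
#'
#' @param nLayers total number of layers including the input layer.
#' @param inputSize neuron count of layer 1.
#' @param layerSize neuron count of layers 2..nLayers.
#' @param ap activation percentage applied to every non-input layer.
#' @return an [ArchitectureSpec-class].
#' @export
chainArchitecture <- function(nLayers = 10, inputSize = 144,
                              layerSize = 1000, ap = 50) {
  nLayers <- assertScalarCount(nLayers, "nLayers", min = 2L)
  architectureSpec(
    layers = data.frame(layer = seq_len(nLayers),
                        n = c(inputSize, rep(layerSize, nLayers - 1L)),
                        ap = c(NA, rep(ap, nLayers - 1L))),
    edges = data.frame(from = seq_len(nLayers - 1L),
                       to = seq_len(nLayers - 1L) + 1L,
                       polarity = 1, ratio = 1))
}

#' Cerebellum-like bifurcating architecture
#'
#' Preset modeled on the cerebellar circuit: input and a common AP = 50
#' layer, then a main branch through pontine-, granule- and Purkinje-like
#' layers (AP = 25) whose inhibitory output converges with a direct side
#' branch onto a deep-nuclei-like layer (AP = 25), mixed at a main:side
#' combination ratio of 1:2.
#'
#' @param inputSize,layerSize layer sizes as in [chainArchitecture()].
#' @return an [ArchitectureSpec-class] with 6 layers.
#' @export
cerebellarArchitecture <- function(inputSize = 144, layerSize = 1000) {
  architectureSpec(
    layers = data.frame(layer = 1:6,
                        n = c(inputSize, rep(layerSize, 5)),
                        ap = c(NA, 50, 25, 25, 25, 25)),
    edges = data.frame(
      from     = c(1, 2, 3, 4, 5, 3),
      to       = c(2, 3, 4, 5, 6, 6),
      polarity = c(1, 1, 1, 1, -1, 1),
      ratio    = c(1, 1, 1, 1, 1, 2)))
}

#' Basal-ganglia-like architecture with inhibitory chains
#'
#' Preset modeled on the basal-ganglia circuit: cortex-like AP = 50 layer,
#' then striatum- (AP = 25), pallidum- (AP = 10), nigra- (AP = 25) and
#' thalamus-like (AP = 25) layers connected by inhibitory (-1) links, with
#' a direct-pathway side branch from the striatal layer mixed at a
#' main:side ratio of 1:2.
#'
#' @param inputSize,layerSize layer sizes as in [chainArchitecture()].
#' @return an [ArchitectureSpec-class] with 6 layers.
#' @export
basalGangliaArchitecture <- function(inputSize = 144, layerSize = 1000) {
  architectureSpec(
    layers = data.frame(layer = 1:6,
                        n = c(inputSize, rep(layerSize, 5)),
                        ap = c(NA, 50, 25, 10, 25, 25)),
    edges = data.frame(
      from     = c(1, 2, 3, 4, 3, 5),
      to       = c(2, 3, 4, 5, 5, 6),
      polarity = c(1, 1, -1, -1, -1, -1),
      ratio    = c(1, 1, 1, 1, 2, 1)))
}

#' @describeIn ArchitectureSpec-class per-layer neuron counts.
#' @param x,object an `ArchitectureSpec`.
#' @param ... unused.
#' @export
setMethod("nNeurons", "ArchitectureSpec", function(x, ...)
  stats::setNames(x@layers$n, x@layers$layer))

#' Layer table of an architecture
#' @param arch an [ArchitectureSpec-class].
#' @return the `layers` data.frame.
#' @export
architectureLayers <- function(arch) arch@layers

#' Edge table of an architecture
#' @param arch an [ArchitectureSpec-class].
#' @return the `edges` data.frame.
#' @export
architectureEdges <- function(arch) arch@edges

setMethod("show", "ArchitectureSpec", function(object) {
  cat(sprintf("ArchitectureSpec: %d layers, %d edges\n",
              nrow(object@layers), nrow(object@edges)))
  cat("  sizes:", paste(object@layers$n, collapse = ", "), "\n")
  cat("  AP:   ", paste(ifelse(is.na(object@layers$ap), "-",
                               object@layers$ap), collapse = ", "), "\n")
})

#' Read an architecture from a YAML or JSON config file
#'
#' The file holds two blocks: `layers`, a list of records with fields
#' `layer`, `n` and `ap` (`ap` omitted or null for the input layer), and
#' `edges`, records with `from`, `to`, `polarity` and `ratio`. Two presets
#' ship with the package under `inst/extdata/` (`arch-cerebellar.yaml`,
#' `arch-basal-ganglia.yaml`).
#'
#' @param path file path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return an [ArchitectureSpec-class].
#' @export
readArchitecture <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  toDF <- function(records, cols) {
    rows <- lapply(records, function(r) {
      vals <- lapply(cols, function(cl)
        if (is.null(r[[cl]])) NA else r[[cl]])
      names(vals) <- cols
      as.data.frame(vals)
    })
    do.call(rbind, rows)
  }
  architectureSpec(layers = toDF(cfg$layers, c("layer", "n", "ap")),
                   edges = toDF(cfg$edges, c("from", "to", "polarity", "ratio")))
}

#' Write an architecture to YAML
#' @param arch an [ArchitectureSpec-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeArchitecture <- function(arch, path) {
  stopifnot(methods::is(arch, "ArchitectureSpec"))
  rowRecords <- function(df) lapply(seq_len(nrow(df)), function(i) {
    r <- as.list(df[i, , drop = FALSE])
    lapply(r, function(v) if (is.na(v)) NULL else unname(v))
  })
  yaml::write_yaml(list(layers = rowRecords(arch@layers),
                        edges = rowRecords(arch@edges)), path)
  invisible(path)
}
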