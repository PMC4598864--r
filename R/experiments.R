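# Experiment drivers. Each returns a tidy data.frame carrying
# the seed and full parameter set, so emitted CSVs are self-describing and
# re-running from config + seed is byte-identical.

#' Patch corpus from a synthetic photograph
#'
#' Generates the standard input set of the image experiments: a seeded
#' synthetic photograph and `n` random 12 x 12 patches flattened to
#' 144-vectors.
#'
#' @param n number of patches.
#' @param seed root seed (photograph and patch origins use child seeds).
#' @param height,width,correlationLength photograph parameters, see
#'   [syntheticPhotograph()].
#' @param size patch side length.
#' @return `n x size^2` matrix of patches (attribute `origins` retained).
#' @export
patchCorpus <- function(n, seed, height = 553, width = 737,
                        correlationLength = 6, size = 12) {
  img <- syntheticPhotograph(height, width, correlationLength,
                             seed = childSeed(seed, 1))
  samplePatches(img, n, size = size, seed = childSeed(seed, 2))
}

#' Small-world characterization experiment
#'
#' For each seed, builds a circular gene-matched network by rotational gene
#' assignment up to a fixed connection budget and measures its average
#' shortest path length and clustering coefficient against an edge-matched
#' random graph and a ring lattice.
#'
#' @param n neurons in the circular network.
#' @param gr gene-repertoire size (one value or a vector to sweep).
#' @param connectionBudget connection budget for the rotational assignment.
#' @param seeds integer vector of seeds (one network per seed).
#' @param countMode connection-counting convention of the budget, see
#'   [sampleExpressionRotational()].
#' @return data.frame with one row per (gr, seed): network id, parameters
#'   and the six reference metrics of [smallWorldMetrics()].
#' @export
smallworldExperiment <- function(n = 100, gr = 50, connectionBudget = 500,
                                 seeds = 1:20,
                                 countMode = c("multi", "unique")) {
  countMode <- match.arg(countMode)
  rows <- lapply(gr, function(g) {
    do.call(rbind, lapply(seeds, function(s) {
      tab <- sampleExpressionRotational(n, g, connectionBudget,
                                        seed = childSeed(s, 1),
                                        countMode = countMode)
      gmn <- buildCircularGMN(tab)
      cbind(data.frame(gr = g, connectionBudget = connectionBudget,
                       seed = s),
            smallWorldMetrics(gmn, seed = childSeed(s, 2)))
    }))
  })
  do.call(rbind, rows)
}

# build the canonical image-transfer network and its input corpus for one
# seed; shared by the transfer / degrade / gr-sweep experiments
canonicalSetup <- function(seed, gr, ge, ap, nLayers, inputSize, layerSize,
                           nInputs) {
  net <- buildLayeredGMN(
    chainArchitecture(nLayers, inputSize, layerSize, ap),
    gr = gr, ge = ge, seed = childSeed(seed, 101))
  inputs <- patchCorpus(nInputs, seed = childSeed(seed, 102),
                        size = as.integer(sqrt(inputSize)))
  list(network = net, inputs = inputs)
}

slopeRow <- function(network, inputs, code, targetLayers, nPairs, seed) {
  ids <- architectureLayers(architecture(network))$layer
  resp <- layerResponses(network, inputs, unique(c(2, targetLayers)),
                         code = code)
  pairs <- samplePairs(nrow(inputs), nPairs, seed = seed)
  dRef <- pairDistances(resp[["2"]], pairs)
  vapply(targetLayers, function(l) {
    if (l == 2) return(1)
    consistencySlope(dRef, pairDistances(resp[[as.character(l)]], pairs))
  }, numeric(1))
}

#' Cross-layer information-transfer experiment
#'
#' The headline reliability experiment: image patches propagate through the
#' canonical chain network and the consistency slope from layer 2 to each
#' deeper layer is computed for the active-neuron and/or active-gene codes,
#' optionally alongside a connection-count-matched random network (the same
#' network with 100% of its connections randomly replaced).
#'
#' @param seeds one network realization per seed.
#' @param gr,ge,ap network parameters (defaults: GR = 50, GE = 5, AP = 50).
#' @param nLayers,inputSize,layerSize architecture sizes.
#' @param nInputs patch-corpus size per seed.
#' @param nPairs input pairs per slope.
#' @param targetLayers layers to regress against layer 2 (default: all of
#'   3..nLayers).
#' @param codes which codings to evaluate.
#' @param randomComparison also evaluate the rewired random network.
#' @return data.frame (seed, network, code, targetLayer, slope, parameters).
#' @export
transferExperiment <- function(seeds = 1:10, gr = 50, ge = 5, ap = 50,
                               nLayers = 10, inputSize = 144,
                               layerSize = 1000, nInputs = 200,
                               nPairs = 1000, targetLayers = NULL,
                               codes = c("gene", "neuron"),
                               randomComparison = TRUE) {
  if (is.null(targetLayers)) targetLayers <- seq(3, nLayers)
  codes <- match.arg(codes, several.ok = TRUE)
  out <- list()
  for (s in seeds) {
    setup <- canonicalSetup(s, gr, ge, ap, nLayers, inputSize, layerSize,
                            nInputs)
    nets <- list(gmn = setup$network)
    if (randomComparison)
      nets$random <- replaceConnections(setup$network, 1,
                                        seed = childSeed(s, 103))
    for (nm in names(nets)) for (code in codes) {
      slopes <- slopeRow(nets[[nm]], setup$inputs, code, targetLayers,
                         nPairs, seed = childSeed(s, 104))
      out[[length(out) + 1L]] <- data.frame(
        seed = s, network = nm, code = code, targetLayer = targetLayers,
        slope = slopes, gr = gr, ge = ge, ap = ap, layerSize = layerSize,
        nInputs = nInputs, nPairs = nPairs)
    }
  }
  do.call(rbind, out)
}

#' Structural-degradation experiment
#'
#' Applies one of the three perturbations — random neuron removal, random
#' connection replacement (count-conserving rewiring), or random connection
#' removal — at a range of fractions to the canonical network and measures
#' the layer-2-to-last consistency slope.
#'
#' Neuron removal damages every layer between (and including) the target
#' but spares the reference measurement layer as well as the input layer,
#' and is nested in the fraction (see [removeNeurons()]), so each seed's
#' curve tracks one progressively degraded network.
#'
#' @param perturbation `"neurons"`, `"replace"` or `"remove"`.
#' @param fractions perturbation fractions (defaults: 0 to 0.9 in steps of
#'   0.1).
#' @param seeds one base network per seed.
#' @param referenceLayer the consistency reference layer (spared by neuron
#'   removal).
#' @inheritParams transferExperiment
#' @return data.frame (perturbation, fraction, code, slope, seed, ...).
#' @export
degradeExperiment <- function(perturbation = c("neurons", "replace", "remove"),
                              fractions = seq(0, 0.9, by = 0.1),
                              seeds = 1:10, gr = 50, ge = 5, ap = 50,
                              nLayers = 10, inputSize = 144,
                              layerSize = 1000, nInputs = 200, nPairs = 1000,
                              codes = c("gene", "neuron"),
                              referenceLayer = 2) {
  perturbation <- match.arg(perturbation)
  codes <- match.arg(codes, several.ok = TRUE)
  perturb <- switch(perturbation,
    neurons = function(net, f, seed)
      removeNeurons(net, f, seed, spare = c(1, referenceLayer)),
    replace = replaceConnections,
    remove = removeConnections)
  out <- list()
  for (s in seeds) {
    setup <- canonicalSetup(s, gr, ge, ap, nLayers, inputSize, layerSize,
                            nInputs)
    for (f in fractions) {
      net <- if (f == 0) setup$network
             else perturb(setup$network, f, seed = childSeed(s, 105))
      for (code in codes) {
        slope <- slopeRow(net, setup$inputs, code, nLayers, nPairs,
                          seed = childSeed(s, 104))
        out[[length(out) + 1L]] <- data.frame(
          perturbation = perturbation, fraction = f, code = code,
          slope = slope, seed = s, gr = gr, ge = ge, ap = ap,
          layerSize = layerSize)
      }
    }
  }
  do.call(rbind, out)
}

#' Gene-repertoire-size sweep
#'
#' Measures the layer-2-to-last consistency slope of canonical networks
#' whose (GR, GE) pairs are chosen to keep the inter-layer connection count
#' comparable: GE = 3, 5, 7, 22, 71 for GR = 20, 50, 100, 1000, 10000.
#'
#' @param grs,ges parallel vectors of repertoire sizes and genes per neuron.
#' @inheritParams transferExperiment
#' @return data.frame (gr, ge, code, slope, seed, ...).
#' @export
grSweepExperiment <- function(grs = c(20, 50, 100, 1000, 10000),
                              ges = c(3, 5, 7, 22, 71),
                              seeds = 1:10, ap = 50, nLayers = 10,
                              inputSize = 144, layerSize = 1000,
                              nInputs = 200, nPairs = 1000,
                              codes = c("gene", "neuron")) {
  stopifnot(length(grs) == length(ges))
  codes <- match.arg(codes, several.ok = TRUE)
  out <- list()
  for (k in seq_along(grs)) for (s in seeds) {
    setup <- canonicalSetup(s, grs[k], ges[k], ap, nLayers, inputSize,
                            layerSize, nInputs)
    for (code in codes) {
      slope <- slopeRow(setup$network, setup$inputs, code, nLayers, nPairs,
                        seed = childSeed(s, 104))
      out[[length(out) + 1L]] <- data.frame(
        gr = grs[k], ge = ges[k], code = code, slope = slope, seed = s,
        ap = ap, layerSize = layerSize)
    }
  }
  do.call(rbind, out)
}

# average input-order-aligned output gene-array profile of one layer for a
# batch of gene-space inputs
alignedProfile <- function(expression, inputs, ap, polarity) {
  m <- membershipMatrix(expression)
  drive <- as.matrix(m %*% Matrix::t(inputs)) * polarity
  gr <- geneRepertoire(expression)
  acc <- numeric(gr)
  for (i in seq_len(ncol(drive))) {
    active <- apThreshold(drive[, i], ap)
    counts <- activeGeneArray(active, expression)
    acc <- acc + counts[inputOrder(inputs[i, ])]
  }
  acc / ncol(drive)
}

#' Gene-array transformation experiment (AP and polarity effects)
#'
#' Feeds random gene-array inputs (elementwise uniform on \[0, 1\]) directly
#' into single gene-matched layers, thresholds at a range of activation
#' percentages under positive or negative transmission polarity, and
#' averages the output active-gene arrays after re-aligning each one in its
#' input order. Restrictive APs with positive polarity augment high-ranking
#' genes; negative polarity augments the low-ranking genes.
#'
#' @param aps activation percentages to test.
#' @param polarities +1 and/or -1.
#' @param nInputs random gene-array inputs per network.
#' @param nNetworks independent layer realizations averaged over.
#' @param n,gr,ge layer parameters.
#' @param seed root seed.
#' @return data.frame (polarity, ap, rank, meanCount): `rank` is the
#'   position in the input order (1 = highest input value), `meanCount` the
#'   averaged aligned output count.
#' @export
transformExperiment <- function(aps = c(5, 25, 50, 75, 95),
                                polarities = c(1, -1), nInputs = 1000,
                                nNetworks = 10, n = 1000, gr = 50, ge = 5,
                                seed = 1) {
  out <- list()
  profiles <- array(0, c(length(polarities), length(aps), gr))
  for (k in seq_len(nNetworks)) {
    expr <- sampleExpression(n, gr, ge, seed = childSeed(seed, 2 * k))
    inputs <- withSeed(childSeed(seed, 2 * k + 1),
                       matrix(stats::runif(nInputs * gr), nInputs, gr))
    for (p in seq_along(polarities)) for (a in seq_along(aps))
      profiles[p, a, ] <- profiles[p, a, ] +
        alignedProfile(expr, inputs, aps[a], polarities[p])
  }
  profiles <- profiles / nNetworks
  for (p in seq_along(polarities)) for (a in seq_along(aps))
    out[[length(out) + 1L]] <- data.frame(
      polarity = polarities[p], ap = aps[a], rank = seq_len(gr),
      meanCount = profiles[p, a, ], n = n, gr = gr, ge = ge,
      nInputs = nInputs, nNetworks = nNetworks)
  do.call(rbind, out)
}

#' Gene-array image-search experiment
#'
#' Propagates a patch corpus through a chain network, takes the final-layer
#' active-gene array of each template patch, retrieves the `k` layer-2
#' candidate arrays closest in L1 distance, and reports how pixel-similar
#' the retrieved patches are to the template patch (mean Pearson
#' correlation), against the corpus-wide baseline. With
#' `finalPolarity = -1` the last edge is inhibitory, so templates retrieve
#' negative (anticorrelated) images.
#'
#' @param nPatches corpus size.
#' @param nTemplates number of template patches (the first `nTemplates`
#'   corpus entries).
#' @param k retrieval depth.
#' @param finalPolarity polarity of the last inter-layer edge.
#' @inheritParams transferExperiment
#' @param seed root seed.
#' @return data.frame (template, meanTopCorrelation, meanCorpusCorrelation,
#'   parameters).
#' @export
searchExperiment <- function(nPatches = 300, nTemplates = 5, k = 10,
                             nLayers = 10, layerSize = 1000, inputSize = 144,
                             gr = 50, ge = 5, ap = 50, finalPolarity = 1,
                             seed = 1) {
  arch <- chainArchitecture(nLayers, inputSize, layerSize, ap)
  ed <- architectureEdges(arch)
  ed$polarity[nrow(ed)] <- finalPolarity
  arch <- architectureSpec(architectureLayers(arch), ed)
  net <- buildLayeredGMN(arch, gr, ge, seed = childSeed(seed, 101))
  patches <- patchCorpus(nPatches, seed = childSeed(seed, 102),
                         size = as.integer(sqrt(inputSize)))
  last <- architectureLayers(arch)$layer[nLayers]
  resp <- layerResponses(net, patches, c(2, last), code = "gene")
  out <- lapply(seq_len(nTemplates), function(tpl) {
    hits <- imageSearch(resp[[as.character(last)]][tpl, ],
                        resp[["2"]][-tpl, , drop = FALSE], k = k)
    candidates <- seq_len(nPatches)[-tpl][hits]
    corrWith <- function(idx) mean(vapply(idx, function(i)
      stats::cor(patches[i, ], patches[tpl, ]), numeric(1)))
    data.frame(template = tpl,
               meanTopCorrelation = corrWith(candidates),
               meanCorpusCorrelation = corrWith(seq_len(nPatches)[-tpl]),
               k = k, nPatches = nPatches, finalPolarity = finalPolarity)
  })
  do.call(rbind, out)
}

#' Mean optimum-image contrast of a layer
#'
#' Contrast (pixel standard deviation) of every neuron's optimum image at
#' one layer, averaged over neurons that were active for at least one
#' patch. Deep gene-matched layers keep high contrast; randomly rewired
#' networks wash out to uniform gray.
#'
#' @param network a [LayeredGMN-class].
#' @param patches patch matrix (rows = inputs).
#' @param layer layer id.
#' @return mean pixel standard deviation over neurons.
#' @export
optimumImageContrast <- function(network, patches, layer) {
  active <- propagateBatch(network, patches)[[as.character(layer)]]
  perNeuron <- vapply(seq_len(ncol(active)), function(j) {
    rows <- which(active[, j])
    if (!length(rows)) return(NA_real_)
    stats::sd(colMeans(patches[rows, , drop = FALSE]))
  }, numeric(1))
  mean(perNeuron, na.rm = TRUE)
}

#' Run a config-driven experiment
#'
#' Dispatches a plain-text (YAML or JSON) configuration to one of the
#' experiment drivers and writes its result table as CSV plus a JSON run
#' log. Recognized `experiment` values: `smallworld`, `transfer`,
#' `transform`, `degrade`, `gr_sweep`, `search`. All other top-level config
#' fields are passed to the driver as arguments; a `seed` field seeds
#' drivers that take `seeds`/`seed` arguments unless those are given
#' explicitly.
#'
#' @param config path to a YAML/JSON file, or an equivalent named list.
#' @param outdir output directory (created if missing).
#' @return invisibly, the result data.frame (also written to
#'   `<outdir>/<experiment>.csv`).
#' @export
runExperiment <- function(config, outdir = ".") {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE))
      yaml::read_yaml(config)
    else jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  name <- config$experiment
  drivers <- list(smallworld = smallworldExperiment,
                  transfer = transferExperiment,
                  transform = transformExperiment,
                  degrade = degradeExperiment,
                  gr_sweep = grSweepExperiment,
                  search = searchExperiment)
  if (is.null(name) || !name %in% names(drivers))
    stop("config field 'experiment' must be one of: ",
         paste(names(drivers), collapse = ", "), call. = FALSE)
  driver <- drivers[[name]]
  args <- config[setdiff(names(config), c("experiment", "outdir", "seed"))]
  formalNames <- names(formals(driver))
  unknown <- setdiff(names(args), formalNames)
  if (length(unknown))
    stop(sprintf("unknown parameter(s) for experiment '%s': %s", name,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  args <- lapply(args, function(v) if (is.list(v)) unlist(v) else v)
  if (!is.null(config$seed)) {
    if ("seeds" %in% formalNames && is.null(args$seeds))
      args$seeds <- seq_len(10) + as.integer(config$seed) * 1000L
    if ("seed" %in% formalNames && is.null(args$seed))
      args$seed <- as.integer(config$seed)
  }
  t0 <- Sys.time()
  result <- do.call(driver, args)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  csv <- file.path(outdir, paste0(name, ".csv"))
  utils::write.csv(result, csv, row.names = FALSE)
  log <- list(experiment = name, config = config,
              rows = nrow(result), csv = csv,
              elapsedSeconds = as.numeric(difftime(Sys.time(), t0,
                                                   units = "secs")))
  cat(jsonlite::toJSON(log, auto_unbox = TRUE),
      file = file.path(outdir, "run-log.jsonl"), append = TRUE, sep = "\n")
  invisible(result)
}
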