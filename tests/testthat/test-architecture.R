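test_that("architecture validation rejects malformed layouts", {
  # cycle
  expect_error(architectureSpec(
    data.frame(layer = 1:3, n = c(4, 4, 4), ap = c(NA, 50, 50)),
    data.frame(from = c(1, 2, 3), to = c(2, 3, 2), polarity = 1, ratio = 1)),
    "acyclic")
  # orphan non-input layer
  expect_error(architectureSpec(
    data.frame(layer = 1:3, n = 4, ap = c(NA, 50, 50)),
    data.frame(from = 1, to = 2, polarity = 1, ratio = 1)),
    "incoming")
  # AP out of range
  expect_error(architectureSpec(
    data.frame(layer = 1:2, n = 4, ap = c(NA, 120)),
    data.frame(from = 1, to = 2, polarity = 1, ratio = 1)),
    "AP")
  # bad polarity / ratio
  expect_error(architectureSpec(
    data.frame(layer = 1:2, n = 4, ap = c(NA, 50)),
    data.frame(from = 1, to = 2, polarity = 0, ratio = 1)),
    "polarity")
  expect_error(architectureSpec(
    data.frame(layer = 1:2, n = 4, ap = c(NA, 50)),
    data.frame(from = 1, to = 2, polarity = 1, ratio = -1)),
    "positive")
})

test_that("chain and preset architectures are valid and sized as declared", {
  arch <- chainArchitecture(10, 144, 1000, 50)
  expect_equal(unname(nNeurons(arch)), c(144, rep(1000, 9)))
  expect_equal(architectureLayers(arch)$ap[-1], rep(50, 9))
  cb <- cerebellarArchitecture()
  expect_equal(architectureLayers(cb)$ap[3:6], c(25, 25, 25, 25))
  expect_equal(sum(architectureEdges(cb)$polarity == -1), 1)
  bg <- basalGangliaArchitecture()
  expect_equal(architectureLayers(bg)$ap[-1], c(50, 25, 10, 25, 25))
  expect_equal(architectureEdges(bg)$ratio[5], 2)  # side branch 1:2
})

test_that("architectures round-trip through YAML and load from presets", {
  arch <- cerebellarArchitecture(inputSize = 16, layerSize = 40)
  path <- withr::local_tempfile(fileext = ".yaml")
  writeArchitecture(arch, path)
  back <- readArchitecture(path)
  expect_equal(architectureLayers(back), architectureLayers(arch))
  expect_equal(architectureEdges(back), architectureEdges(arch))

  shipped <- system.file("extdata", "arch-basal-ganglia.yaml",
                         package = "gmnet")
  bg <- readArchitecture(shipped)
  expect_equal(architectureLayers(bg)$ap[-1], c(50, 25, 10, 25, 25))
})

test_that("layered networks draw independent per-layer tables reproducibly", {
  arch <- chainArchitecture(3, 12, 30, 50)
  net1 <- buildLayeredGMN(arch, gr = 10, ge = 3, seed = 4)
  net2 <- buildLayeredGMN(arch, gr = 10, ge = 3, seed = 4)
  expect_identical(lapply(net1@expressions, geneSets),
                   lapply(net2@expressions, geneSets))
  expect_false(identical(geneSets(layerExpression(net1, 2)),
                         geneSets(layerExpression(net1, 3))))
  expect_equal(unname(nNeurons(net1)), c(12, 30, 30))
})

test_that("propagation follows drives, AP and polarity layer by layer", {
  # two layers, GE = 3, GR = 10, AP = 50: hand-checkable toy
  arch <- architectureSpec(
    data.frame(layer = 1:2, n = c(6, 8), ap = c(NA, 50)),
    data.frame(from = 1, to = 2, polarity = 1, ratio = 1))
  net <- buildLayeredGMN(arch, gr = 10, ge = 3, seed = 12)
  input <- c(1, 0, 1, 0, 0, 1)
  res <- propagate(net, input)
  w <- net@weights[[1]]
  drive <- as.numeric(w %*% input)
  expect_equal(summedInputs(res$states[["2"]]), drive)
  k <- 4                                 # round(50% of 8)
  wantActive <- logical(8)
  wantActive[order(-drive, 1:8)[1:k]] <- TRUE
  expect_equal(activeNeurons(res$states[["2"]]), wantActive)
  expect_equal(res$geneArrays[["2"]],
               activeGeneArray(wantActive, layerExpression(net, 2)))
  expect_equal(sum(res$geneArrays[["2"]]), k * 3)
  # determinism
  res2 <- propagate(net, input)
  expect_identical(res, res2)
})

test_that("an AP of 100 reduces each layer to the full-population histogram", {
  arch <- chainArchitecture(4, 10, 25, ap = 100)
  net <- buildLayeredGMN(arch, gr = 8, ge = 2, seed = 3)
  res <- propagate(net, runif(10))
  for (l in 2:4)
    expect_equal(res$geneArrays[[as.character(l)]],
                 as.integer(Matrix::colSums(
                   membershipMatrix(layerExpression(net, l)))))
})

test_that("negative polarity activates the lowest-drive neurons", {
  arch <- architectureSpec(
    data.frame(layer = 1:2, n = c(5, 20), ap = c(NA, 25)),
    data.frame(from = 1, to = 2, polarity = -1, ratio = 1))
  net <- buildLayeredGMN(arch, gr = 10, ge = 3, seed = 8)
  input <- runif(5)
  res <- propagate(net, input)
  drive <- as.numeric(net@weights[[1]] %*% input)
  expect_equal(which(activeNeurons(res$states[["2"]])),
               sort(utils::head(order(drive, 1:20), 5)))
})

test_that("combination ratios weight converging branches", {
  arch <- architectureSpec(
    data.frame(layer = 1:4, n = c(6, 10, 10, 12), ap = c(NA, 50, 50, 50)),
    data.frame(from = c(1, 1, 2, 3), to = c(2, 3, 4, 4),
               polarity = c(1, 1, 1, -1), ratio = c(1, 1, 1, 2)))
  net <- buildLayeredGMN(arch, gr = 12, ge = 3, seed = 9)
  input <- runif(6)
  res <- propagate(net, input)
  t2 <- as.numeric(activeNeurons(res$states[["2"]]))
  t3 <- as.numeric(activeNeurons(res$states[["3"]]))
  want <- (1 / 3) * as.numeric(net@weights[[3]] %*% t2) +
          (2 / 3) * as.numeric(net@weights[[4]] %*% (-t3))
  expect_equal(summedInputs(res$states[["4"]]), want)
})

test_that("batched propagation agrees with the single-input path", {
  net <- buildLayeredGMN(chainArchitecture(5, 12, 40), gr = 15, ge = 4,
                         seed = 10)
  inputs <- matrix(runif(8 * 12), 8, 12)
  batch <- gmnet:::propagateBatch(net, inputs)
  for (i in 1:8) {
    one <- propagate(net, inputs[i, ])
    for (l in c("2", "5"))
      expect_equal(batch[[l]][i, ], activeNeurons(one$states[[l]]))
  }
})
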