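weightsFixture <- function(seed = 5) {
  pre <- sampleExpression(30, 12, 3, seed = seed)
  post <- sampleExpression(30, 12, 3, seed = seed + 1)
  weightMatrix(interlayerWeights(pre, post))
}

test_that("a zero fraction is the identity for all three perturbations", {
  w <- weightsFixture()
  expect_identical(replaceConnections(w, 0, seed = 1), w)
  expect_identical(removeConnections(w, 0, seed = 1), w)
  net <- buildLayeredGMN(chainArchitecture(3, 8, 20), 10, 3, seed = 2)
  same <- removeNeurons(net, 0, seed = 3)
  expect_identical(same@weights, net@weights)
})

test_that("replacement conserves the total connection count exactly", {
  w <- weightsFixture()
  for (f in c(0.1, 0.5, 1)) {
    out <- replaceConnections(w, f, seed = 7)
    expect_equal(sum(out), sum(w))
    expect_true(all(out >= 0))
  }
})

test_that("removal deletes exactly the rounded number of connection units", {
  w <- weightsFixture()
  for (f in c(0.1, 0.5, 0.9)) {
    out <- removeConnections(w, f, seed = 8)
    expect_equal(sum(out), sum(w) - floor(f * sum(w) + 0.5))
    expect_true(all(out >= 0))
    expect_true(all(out <= w))    # removal never adds
  }
  expect_error(removeConnections(w, 1, seed = 1), "fraction")
})

test_that("perturbing a layered network rewires every edge independently", {
  net <- buildLayeredGMN(chainArchitecture(4, 10, 30), 10, 3, seed = 4)
  totals <- vapply(net@weights, sum, numeric(1))
  rep1 <- replaceConnections(net, 0.5, seed = 11)
  expect_equal(vapply(rep1@weights, sum, numeric(1)), totals)
  expect_false(identical(rep1@weights, net@weights))
  thin <- removeConnections(net, 0.5, seed = 12)
  expect_equal(vapply(thin@weights, sum, numeric(1)),
               totals - floor(0.5 * totals + 0.5))
})

test_that("neuron removal shrinks non-spared layers and rebuilds weights", {
  net <- buildLayeredGMN(chainArchitecture(4, 12, 40), 10, 3, seed = 6)
  cut <- removeNeurons(net, 0.5, seed = 13)
  expect_equal(unname(nNeurons(cut)), c(12, 20, 20, 20))
  spared <- removeNeurons(net, 0.5, seed = 13, spare = c(1, 2))
  expect_equal(unname(nNeurons(spared)), c(12, 40, 20, 20))
  expect_identical(geneSets(layerExpression(spared, 2)),
                   geneSets(layerExpression(net, 2)))
  # weights are recomputed from the surviving gene sets
  w <- interlayerWeights(layerExpression(cut, 2), layerExpression(cut, 3))
  expect_identical(cut@weights[[2]], weightMatrix(w))
  expect_error(removeNeurons(net, 1, seed = 1), "fraction")
})

test_that("neuron removal is nested in the fraction at a fixed seed", {
  net <- buildLayeredGMN(chainArchitecture(3, 10, 40), 10, 3, seed = 7)
  light <- removeNeurons(net, 0.2, seed = 21)
  heavy <- removeNeurons(net, 0.6, seed = 21)
  # heavy survivors must be a subsequence of light survivors, layer by layer
  for (l in 2:3) {
    a <- geneSets(layerExpression(light, l))
    b <- geneSets(layerExpression(heavy, l))
    idx <- 1
    for (set in b) {
      while (idx <= length(a) && !identical(a[[idx]], set)) idx <- idx + 1
      expect_lte(idx, length(a))
      idx <- idx + 1
    }
  }
})
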