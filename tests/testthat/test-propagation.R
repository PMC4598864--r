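test_that("summed input is the weighted sum over connections", {
  preSets <- randomSets(30, 10, 3, seed = 1)
  postSets <- randomSets(30, 10, 3, seed = 2)
  w <- interlayerWeights(expressionTable(preSets, 10),
                         expressionTable(postSets, 10))
  expect_equal(summedInput(numeric(30), w), numeric(30))
  src <- numeric(30); src[7] <- 1
  expect_equal(summedInput(src, w), as.numeric(weightMatrix(w)[, 7]))
  set.seed(3); x <- runif(30)
  naive <- vapply(1:30, function(j)
    sum(vapply(1:30, function(i)
      length(intersect(postSets[[j]], preSets[[i]])) * x[i], numeric(1))),
    numeric(1))
  expect_equal(summedInput(x, w), naive)
  expect_error(summedInput(numeric(5), w), "pre-layer")
})

test_that("AP thresholding activates the top k with half-up rounding", {
  expect_equal(apThreshold(c(3, 1, 4, 1), 100), rep(TRUE, 4))
  expect_equal(which(apThreshold(c(3, 1, 4, 1), 50)), c(1L, 3L))
  expect_equal(which(apThreshold(c(2, 2, 2, 2), 50)), c(1L, 2L))  # index ties
  expect_equal(sum(apThreshold(rnorm(10), 25)), 3)  # 2.5 rounds up
  expect_error(apThreshold(1:4, 0), "ap")
  expect_error(apThreshold(1:4, 101), "ap")
})

test_that("polarity is an involution and flips the activation ranking", {
  set.seed(9); x <- runif(50)
  expect_equal(applyPolarity(x, 1), x)
  expect_equal(applyPolarity(applyPolarity(x, -1), -1), x)
  topHalf <- apThreshold(x, 40)
  bottomHalf <- apThreshold(applyPolarity(x, -1), 40)
  expect_equal(which(bottomHalf), sort(utils::head(order(x), 20)))
  expect_error(applyPolarity(x, 2), "polarity")
})

test_that("combination ratios mix normalized convex combinations", {
  v <- c(2, 5, 1)
  expect_equal(combineInputs(list(v), 7), v)
  expect_equal(combineInputs(list(v, v), c(1, 2)), v)
  expect_equal(combineInputs(list(c(1, 0), c(0, 1)), c(1, 2)),
               c(1 / 3, 2 / 3))
  expect_error(combineInputs(list(1:2, 1:3), c(1, 1)), "length")
  expect_error(combineInputs(list(1:2), c(1, 1)), "ratios")
})

test_that("active-gene arrays count gene expression among active neurons", {
  sets <- randomSets(40, 12, 4, seed = 4)
  tab <- expressionTable(sets, 12)
  expect_equal(activeGeneArray(rep(FALSE, 40), tab), integer(12))
  all40 <- activeGeneArray(rep(TRUE, 40), tab)
  expect_equal(sum(all40), 40 * 4)               # conservation
  set.seed(5); active <- runif(40) > 0.5
  want <- integer(12)
  for (i in which(active)) for (g in sets[[i]]) want[g] <- want[g] + 1L
  expect_equal(activeGeneArray(active, tab), want)
})

test_that("gene-array drive is the gene-space dual of summed input", {
  tab <- expressionTable(randomSets(25, 8, 3, seed = 6), 8)
  expect_equal(geneArrayDrive(rep(2, 8), tab), rep(3 * 2, 25))
  oneHot <- numeric(8); oneHot[5] <- 1
  expect_equal(geneArrayDrive(oneHot, tab),
               as.numeric(membershipMatrix(tab)[, 5]))
  # equals propagation through a virtual one-neuron-per-gene pre-layer
  virtual <- expressionTable(as.list(1:8), 8)
  w <- interlayerWeights(virtual, tab)
  set.seed(7); arr <- runif(8)
  expect_equal(geneArrayDrive(arr, tab), summedInput(arr, w))
  expect_error(geneArrayDrive(numeric(3), tab), "repertoire")
})
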