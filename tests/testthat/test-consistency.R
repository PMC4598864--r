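test_that("L1 distance reduces to the expected special cases", {
  expect_equal(l1Distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(l1Distance(c(1, 0, 1, 1), c(0, 0, 1, 0)), 2)  # Hamming
  expect_equal(l1Distance(c(1, 2, 3), c(3, 2, 1)), 4)
  expect_error(l1Distance(1:3, 1:4), "length")
})

test_that("the consistency slope is the OLS slope of target on reference", {
  ref <- c(1, 2, 4, 7, 9)
  expect_equal(consistencySlope(ref, ref), 1)
  expect_equal(consistencySlope(ref, rep(3, 5)), 0)
  set.seed(2); tar <- 2 * ref + rnorm(5)
  expect_equal(consistencySlope(ref, tar),
               unname(coef(lm(tar ~ ref))[2]))
  expect_error(consistencySlope(rep(1, 4), 1:4), "variance")
  expect_error(consistencySlope(1:3, 1:4), "length")
})

test_that("slope scales linearly with a common target rescaling", {
  set.seed(3)
  ref <- runif(50); tar <- runif(50)
  base <- consistencySlope(ref, tar)
  for (c in c(0.25, 2, 10))
    expect_equal(consistencySlope(ref, c * tar), c * base)
})

test_that("pair sampling yields distinct valid pairs deterministically", {
  pairs <- gmnet:::samplePairs(20, 50, seed = 4)
  expect_equal(nrow(pairs), 50)
  expect_true(all(pairs[, "i"] < pairs[, "j"]))
  expect_true(all(pairs <= 20 & pairs >= 1))
  expect_equal(anyDuplicated(pairs), 0L)
  expect_identical(gmnet:::samplePairs(20, 50, seed = 4), pairs)
  expect_error(gmnet:::samplePairs(4, 100, seed = 1), "enough")
})

test_that("cross-layer consistency behaves at its boundaries", {
  net <- buildLayeredGMN(chainArchitecture(4, 16, 50), gr = 12, ge = 3,
                         seed = 6)
  inputs <- matrix(runif(30 * 16), 30, 16)
  expect_equal(as.numeric(crossLayerConsistency(
    net, inputs, "gene", referenceLayer = 2, targetLayer = 2,
    nPairs = 100, seed = 1)), 1)
  s1 <- crossLayerConsistency(net, inputs, "neuron", 2, 4, 200, seed = 2)
  s2 <- crossLayerConsistency(net, inputs, "neuron", 2, 4, 200, seed = 2)
  expect_identical(s1, s2)
  expect_error(crossLayerConsistency(net, inputs, "gene", 4, 2, 100, 1),
               "referenceLayer")
  expect_error(crossLayerConsistency(net, inputs, "gene", 2, 9, 100, 1),
               "unknown")
})

test_that("slopes computed from responses equal a direct reconstruction", {
  net <- buildLayeredGMN(chainArchitecture(3, 10, 30), gr = 10, ge = 3,
                         seed = 7)
  inputs <- matrix(runif(15 * 10), 15, 10)
  got <- as.numeric(crossLayerConsistency(net, inputs, "gene", 2, 3,
                                          nPairs = 40, seed = 9))
  # direct oracle: run every input individually, recompute the regression
  arrays2 <- t(vapply(seq_len(15), function(i)
    as.numeric(propagate(net, inputs[i, ])$geneArrays[["2"]]), numeric(10)))
  arrays3 <- t(vapply(seq_len(15), function(i)
    as.numeric(propagate(net, inputs[i, ])$geneArrays[["3"]]), numeric(10)))
  pairs <- gmnet:::samplePairs(15, 40, seed = 9)
  dr <- apply(pairs, 1, function(p) sum(abs(arrays2[p[1], ] - arrays2[p[2], ])))
  dt <- apply(pairs, 1, function(p) sum(abs(arrays3[p[1], ] - arrays3[p[2], ])))
  expect_equal(got, unname(coef(lm(dt ~ dr))[2]))
})
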