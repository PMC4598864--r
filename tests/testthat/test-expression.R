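test_that("sampled tables satisfy the expression invariants", {
  for (cfg in list(c(50, 10, 3), c(30, 50, 5), c(12, 6, 6))) {
    tab <- sampleExpression(cfg[1], cfg[2], cfg[3], seed = 42)
    expect_equal(nNeurons(tab), cfg[1])
    expect_equal(geneRepertoire(tab), cfg[2])
    sets <- geneSets(tab)
    expect_true(all(lengths(sets) == cfg[3]))
    expect_true(all(vapply(sets, anyDuplicated, integer(1)) == 0))
    expect_true(all(unlist(sets) >= 1 & unlist(sets) <= cfg[2]))
  }
})

test_that("GE = GR forces the full repertoire", {
  tab <- sampleExpression(4, gr = 3, ge = 3, seed = 1)
  expect_true(all(vapply(geneSets(tab), identical, logical(1), y = 1:3)))
})

test_that("sampling is deterministic given the seed and rejects ge > gr", {
  a <- sampleExpression(8, 6, 2, seed = 7)
  b <- sampleExpression(8, 6, 2, seed = 7)
  expect_identical(geneSets(a), geneSets(b))
  expect_error(sampleExpression(5, 3, 4), "ge")
})

test_that("per-gene expression frequency matches the binomial expectation", {
  tab <- sampleExpression(10000, 50, 5, seed = 11)
  freq <- Matrix::colSums(membershipMatrix(tab)) / 10000
  se <- sqrt(0.1 * 0.9 / 10000)
  expect_equal(mean(freq), 0.1)          # exact identity, no sampling error
  expect_true(all(abs(freq - 0.1) < 4 * se))
})

test_that("mean subnetwork size is the exact identity n * GE / GR", {
  for (s in 1:5) {
    tab <- sampleExpression(200, 40, 4, seed = s)
    expect_equal(meanSubnetworkSize(tab), 200 * 4 / 40)
  }
})

test_that("subnetworkMembers returns expressing neurons and checks range", {
  tab <- expressionTable(list(c(1, 2), c(2, 3), 4L), gr = 5)
  expect_equal(subnetworkMembers(tab, 2), c(1L, 2L))
  expect_equal(length(subnetworkMembers(tab, 5)), 0L)
  expect_error(subnetworkMembers(tab, 6), "repertoire")
})

test_that("rotational assignment hits the connection budget exactly once", {
  tab <- sampleExpressionRotational(100, 50, 500, seed = 3)
  count <- connectionCount(buildCircularGMN(tab), "multi")
  expect_gte(count, 500)
  expect_lte(count, 500 + 99)   # last gene adds at most n - 1 connections
  again <- sampleExpressionRotational(100, 50, 500, seed = 3)
  expect_identical(membershipMatrix(tab), membershipMatrix(again))
})

test_that("a zero budget yields an empty table", {
  tab <- sampleExpressionRotational(10, 5, 0, seed = 1)
  expect_equal(sum(membershipMatrix(tab)), 0)
})

test_that("unique-pair budget counting is available and coherent", {
  tab <- sampleExpressionRotational(100, 20, 500, seed = 5,
                                    countMode = "unique")
  expect_gte(connectionCount(buildCircularGMN(tab), "unique"), 500)
})

test_that("rotation spreads genes over neurons more evenly than iid draws", {
  varRatio <- vapply(1:10, function(s) {
    rot <- sampleExpressionRotational(100, 20, 500, seed = s)
    perNeuron <- Matrix::rowSums(membershipMatrix(rot))
    nGenes <- sum(perNeuron)
    set.seed(s + 1000)  # iid control: the same genes thrown at random neurons
    iid <- tabulate(sample.int(100, nGenes, replace = TRUE), nbins = 100)
    var(perNeuron) / var(iid)
  }, numeric(1))
  expect_lt(median(varRatio), 1)
})

test_that("an unreachable budget raises the termination guard", {
  expect_error(sampleExpressionRotational(2, 2, 10, seed = 1),
               "unreachable")
})

test_that("expression tables round-trip through TSV and JSON", {
  tab <- sampleExpression(15, 12, 4, seed = 9)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeExpressionTable(tab, tsv)
  back <- readExpressionTable(tsv, nNeurons = 15, gr = 12)
  expect_identical(geneSets(back), lapply(geneSets(tab), sort))

  js <- withr::local_tempfile(fileext = ".json")
  expressionToJSON(tab, js)
  back2 <- expressionFromJSON(js)
  expect_identical(membershipMatrix(back2), membershipMatrix(tab))
})

test_that("expressionTable validates its inputs", {
  expect_error(expressionTable(list(c(1, 1)), gr = 3), "duplicates")
  expect_error(expressionTable(list(c(0, 2)), gr = 3), "1..gr")
})
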