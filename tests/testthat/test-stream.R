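# Buffering of the feature stream and block bookkeeping.

test_that("bufferStream splits columns into H-wide blocks with a remainder", {
  vals <- matrix(rnorm(40), 4, 10)
  blocks <- bufferStream(vals, H = 4)
  expect_length(blocks, 3)
  expect_equal(vapply(blocks, blockWidth, integer(1)), c(4L, 4L, 2L))
  # order preservation: concatenated ids equal input order
  expect_equal(unlist(lapply(blocks, featureIds)),
               sprintf("f%04d", 1:10))

  wide <- bufferStream(matrix(rnorm(12), 4, 3), H = 8)
  expect_length(wide, 1)
  expect_equal(blockWidth(wide[[1]]), 3L)

  expect_length(bufferStream(matrix(nrow = 4, ncol = 0), H = 3), 0)
})

test_that("bufferStream preserves values and masks per block", {
  vals <- matrix(rnorm(30), 5, 6)
  vals[2, 3] <- NA
  blocks <- bufferStream(vals, H = 4, featureIds = letters[1:6])
  expect_equal(featureIds(blocks[[1]]), letters[1:4])
  expect_false(blockMask(blocks[[1]])[2, 3])
  expect_equal(blockValues(blocks[[2]]), vals[, 5:6],
               ignore_attr = TRUE)
})

test_that("missingRate uses all cells for a block, M for a column", {
  full <- SparseFeatureBlock(matrix(1:10, 2, 5))
  expect_equal(missingRate(full), 0)

  vals <- matrix(rnorm(10), 2, 5)
  vals[c(1, 4, 7)] <- NA
  expect_equal(missingRate(SparseFeatureBlock(vals)), 0.3)

  allNA <- SparseFeatureBlock(matrix(NA_real_, 2, 5))
  expect_equal(missingRate(allNA), 1)

  expect_equal(missingRate(c(1, NA, 2, NA)), 0.5)
  expect_error(missingRate(numeric(0)), "empty")
})

test_that("SparseFeatureBlock enforces its shape and mask invariants", {
  expect_error(SparseFeatureBlock(matrix(1, 2, 2), mask = matrix(TRUE, 2, 3)),
               "identical shape")
  expect_error(SparseFeatureBlock(matrix(1, 2, 2), featureIds = c("a", "a")),
               "unique")
  b <- SparseFeatureBlock(matrix(c(1, NA, 3, 4), 2, 2))
  expect_true(is.na(blockValues(b)[2, 1]))  # unobserved stored as NA
})

test_that("processStream rejects degenerate inputs", {
  sim <- generateStream(syntheticStreamSpec(M = 30, totalFeatures = 6,
    rank = 6, nInformative = 2, nRedundant = 0, missingRate = 0,
    bufferWidth = 3, seed = 5))
  cfg <- streamConfig(ga = gaParams(N = 6, Tmax = 3), masterSeed = 5)
  expect_error(processStream(list(), sim$labels, cfg), "empty stream")
  expect_error(processStream(sim$blocks, NULL, cfg), "labels")
  expect_error(processStream(sim$blocks, factor(rep("a", 30)), cfg),
               "2 distinct classes")
})

test_that("a fully observed stream is identical with imputation bypassed", {
  # completion preserves observed cells, so rho = 0 must leave every
  # block's matrix bit-identical to its input
  sim <- generateStream(syntheticStreamSpec(M = 30, totalFeatures = 6,
    rank = 6, nInformative = 2, nRedundant = 0, missingRate = 0,
    bufferWidth = 3, seed = 6))
  for (b in sim$blocks) {
    expect_true(all(blockMask(b)))
    expect_identical(imputeBlock(b), {
      out <- blockValues(b); colnames(out) <- featureIds(b); out
    })
  }
})

test_that("streaming selection finds a perfectly label-determining feature", {
  # one planted feature that determines the label among 9 noise
  # features; exhaustive-oracle reasoning: the planted feature is in
  # every error-0 subset, so the pipeline must select it
  M <- 60
  withr::with_seed(42, {
    planted <- rnorm(M)
    noise <- matrix(rnorm(M * 9), M, 9)
  })
  y <- factor(ifelse(planted > 0, "hi", "lo"))
  vals <- cbind(noise[, 1:4], planted, noise[, 5:9])
  colnames(vals) <- sprintf("f%02d", 1:10)
  blocks <- bufferStream(vals, H = 10)
  cfg <- streamConfig(ga = gaParams(N = 20, Tmax = 20), masterSeed = 9)
  st <- processStream(blocks, y, cfg)
  expect_true("f05" %in% selectedFeatures(st))
})

test_that("identical master seeds reproduce the selection state exactly", {
  sim <- generateStream(syntheticStreamSpec(M = 40, totalFeatures = 12,
    rank = 6, nInformative = 2, nRedundant = 1, missingRate = 0.15,
    bufferWidth = 6, seed = 7))
  cfg <- streamConfig(ga = gaParams(N = 8, Tmax = 6), masterSeed = 77)
  s1 <- processStream(sim$blocks, sim$labels, cfg)
  s2 <- processStream(sim$blocks, sim$labels, cfg)
  expect_identical(selectedFeatures(s1), selectedFeatures(s2))
  expect_identical(convergenceCurves(s1), convergenceCurves(s2))
})

test_that("selection state invariants hold along the stream", {
  sim <- generateStream(syntheticStreamSpec(M = 40, totalFeatures = 12,
    rank = 6, nInformative = 2, nRedundant = 1, missingRate = 0.1,
    bufferWidth = 5, seed = 8))
  cfg <- streamConfig(ga = gaParams(N = 8, Tmax = 6), masterSeed = 8)
  st <- processStream(sim$blocks, sim$labels, cfg)
  allIds <- unlist(lapply(sim$blocks, featureIds))
  # never selects an id that has not streamed
  expect_true(all(selectedFeatures(st) %in% allIds))
  prevSize <- 0
  for (h in selectionHistory(st)) {
    # candidate pool is bounded by |S_{t-1}| + H
    expect_lte(h$candidateCount, prevSize + 5)
    # per-block convergence curves are non-increasing
    expect_true(all(diff(h$convergence) <= 1e-12))
    prevSize <- h$postPruneSize
  }
  expect_equal(st@totalSeen, 12L)
})
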