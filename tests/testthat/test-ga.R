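# Genetic-algorithm operators and the elitist search loop.

test_that("initPopulation draws Bernoulli(p0) bits reproducibly", {
  expect_true(all(initPopulation(5, 8, p0 = 1, seed = 1) == 1))
  expect_true(all(initPopulation(5, 8, p0 = 0, seed = 1) == 0))

  pop <- initPopulation(200, 100, p0 = 0.5, seed = 2)
  expect_equal(dim(pop), c(200L, 100L))
  se <- sqrt(0.5 * 0.5 / (200 * 100))
  expect_lt(abs(mean(pop) - 0.5), 3 * se)

  expect_identical(initPopulation(6, 4, seed = 9),
                   initPopulation(6, 4, seed = 9))
  expect_error(initPopulation(1, 4, seed = 1), "N must be")
  expect_error(initPopulation(4, 0, seed = 1), "n must be")
})

test_that("chromosomeFitness combines error and sparsity as written", {
  toy <- separableToy(M = 40, p = 1)
  X <- cbind(toy$X, withr::with_seed(101, matrix(rnorm(40 * 9), 40, 9)))
  pr <- evalProtocol(seed = 3)
  # the separating feature alone: knn error 0, so fitness = beta * 1/10
  b <- c(1, rep(0, 9))
  f <- chromosomeFitness(b, X, toy$y, classifierSpec("knn3"), pr,
                         alpha = 1, beta = 0.1)
  expect_equal(f, 0.01)
  # beta = 0 removes the sparsity term entirely
  expect_equal(chromosomeFitness(b, X, toy$y, classifierSpec("knn3"), pr,
                                 alpha = 1, beta = 0), 0)
  # all-ones separable: error 0, sparsity term = beta
  expect_equal(chromosomeFitness(rep(1, 10), X, toy$y,
                                 classifierSpec("knn3"), pr,
                                 alpha = 1, beta = 0.1), 0.1)
  # the empty subset scores the majority-class error, not zero
  f0 <- chromosomeFitness(rep(0, 10), X, toy$y, classifierSpec("knn3"), pr,
                          alpha = 1, beta = 0.1)
  expect_equal(f0, 0.5)
})

test_that("roulette selection follows the 1/(f + iota) weights", {
  expect_equal(rouletteSelect(0.3, iota = 1e-6, r = 0.99), 1)

  # fitnesses (0, 1), iota = 0.01: weights (100, 1/1.01), P1 ~ 0.99020
  w <- c(1 / 0.01, 1 / 1.01)
  p1 <- w[1] / sum(w)
  expect_equal(p1, 0.99020, tolerance = 1e-4)
  expect_equal(rouletteSelect(c(0, 1), iota = 0.01, r = p1 - 1e-6), 1)
  expect_equal(rouletteSelect(c(0, 1), iota = 0.01, r = p1 + 1e-6), 2)

  # empirical frequencies match the weight probabilities
  fits <- c(0.1, 0.3, 0.9)
  probs <- (1 / (fits + 0.01)) / sum(1 / (fits + 0.01))
  draws <- withr::with_seed(17,
    vapply(1:10000, function(i) rouletteSelect(fits, iota = 0.01),
           numeric(1)))
  freq <- tabulate(draws, 3) / 10000
  for (i in 1:3) {
    se <- sqrt(probs[i] * (1 - probs[i]) / 10000)
    expect_lt(abs(freq[i] - probs[i]), 3 * se)
  }
})

test_that("single-point crossover swaps tails after the cut", {
  out <- singlePointCrossover(c(1, 1, 1), c(0, 0, 0), cutPoint = 1)
  expect_equal(out$bp, c(1, 0, 0))
  expect_equal(out$bq, c(0, 1, 1))

  # identical parents are invariant for any cut
  for (cp in 1:3) {
    same <- singlePointCrossover(c(1, 0, 1, 1), c(1, 0, 1, 1), cutPoint = cp)
    expect_equal(same$bp, c(1, 0, 1, 1))
  }

  # pc = 0 always copies
  withr::with_seed(5, {
    out0 <- singlePointCrossover(c(1, 1, 0), c(0, 1, 1), pc = 0)
  })
  expect_equal(out0$bp, c(1, 1, 0))
  expect_equal(out0$bq, c(0, 1, 1))

  # length-1 chromosomes degenerate to copying
  out1 <- singlePointCrossover(1, 0, pc = 1)
  expect_equal(out1$bp, 1)
  expect_equal(out1$bq, 0)
})

test_that("bit-flip mutation has the right limits and mean flip count", {
  b <- c(1, 0, 1, 1, 0)
  withr::with_seed(6, expect_equal(bitFlipMutation(b, pm = 0), b))
  withr::with_seed(6, expect_equal(bitFlipMutation(b, pm = 1), 1 - b))

  flips <- withr::with_seed(7, vapply(1:1000, function(i)
    sum(bitFlipMutation(rep(0L, 1000), pm = 0.05)), numeric(1)))
  se <- sqrt(1000 * 0.05 * 0.95 / 1000)
  expect_lt(abs(mean(flips) - 50), 3 * se)
})

test_that("elitist replacement swaps out the worst offspring", {
  pop <- rbind(c(1, 1), c(0, 1), c(0, 0))
  fits <- c(0.5, 0.9, 0.2)
  el <- elitistReplacement(pop, fits, bBest = c(1, 0), fBest = 0.1)
  expect_equal(el$pop[2, ], c(1, 0))
  expect_equal(el$fits, c(0.5, 0.1, 0.2))
  expect_lte(min(el$fits), 0.1)

  # ties on the worst fitness: the lower index is replaced
  elt <- elitistReplacement(pop, c(0.9, 0.9, 0.2), c(1, 0), 0.1)
  expect_equal(elt$pop[1, ], c(1, 0))
  expect_equal(elt$pop[2, ], c(0, 1))
})

test_that("runGA returns the initial best when Tmax = 0", {
  toy <- separableToy()
  res <- runGA(toy$X, toy$y, gaParams(N = 6, Tmax = 0, seed = 4),
               classifierSpec("knn3"), evalProtocol(seed = 4))
  expect_length(res$convergence, 1)
  expect_equal(res$convergence[1], res$fitness)
})

test_that("convergence curves never increase and runs are reproducible", {
  sim <- generateStream(syntheticStreamSpec(M = 40, totalFeatures = 8,
    rank = 6, nInformative = 2, nRedundant = 0, missingRate = 0, seed = 12))
  p <- gaParams(N = 10, Tmax = 12, seed = 3)
  r1 <- runGA(sim$values, sim$labels, p, classifierSpec("knn3"),
              evalProtocol(seed = 3))
  r2 <- runGA(sim$values, sim$labels, p, classifierSpec("knn3"),
              evalProtocol(seed = 3))
  expect_true(all(diff(r1$convergence) <= 1e-12))
  expect_identical(r1$bestBits, r2$bestBits)
  expect_identical(r1$convergence, r2$convergence)
  # GAResult bookkeeping invariants
  expect_equal(r1$nSelected, sum(r1$bestBits))
  expect_equal(r1$selected, colnames(sim$values)[r1$bestBits == 1])
})

test_that("per-generation evaluation count is bounded by the population", {
  # cost model O(N (n + C_F)): distinct wrapper evaluations can never
  # exceed one per chromosome per generation (plus the initial pop)
  toy <- separableToy(M = 30, p = 3)
  p <- gaParams(N = 8, Tmax = 10, seed = 5)
  res <- runGA(toy$X, toy$y, p, classifierSpec("knn3"), evalProtocol(seed = 5))
  expect_lte(res$evaluations, 8 * 11)
})

test_that("GA finds the exhaustive-enumeration optimum on a small task", {
  # 8 features, 2 informative: enumerate all 256 subsets with the same
  # fitness, then check the GA attains the global minimum
  sim <- generateStream(syntheticStreamSpec(M = 60, totalFeatures = 8,
    rank = 6, nInformative = 2, nRedundant = 0, missingRate = 0, seed = 21))
  spec <- classifierSpec("knn3")
  pr <- evalProtocol(seed = 21)
  sp <- streamFS:::protocolSplits(sim$labels, pr)
  fitnessOf <- function(bits) chromosomeFitness(bits, sim$values, sim$labels,
    spec, pr, alpha = 1, beta = 0.05, splits = sp)
  allBits <- as.matrix(expand.grid(rep(list(0:1), 8)))
  exhaustive <- min(apply(allBits, 1, fitnessOf))
  res <- runGA(sim$values, sim$labels,
               gaParams(N = 30, Tmax = 25, beta = 0.05, seed = 22), spec, pr)
  expect_equal(res$fitness, exhaustive)
})
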