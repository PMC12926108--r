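# Latent-factor completion: initialization, loss, SGD updates, training.

test_that("initFactors draws uniformly on [0, 0.004) and is reproducible", {
  fp <- initFactors(30, 10, 3, seed = 1)
  ent <- c(fp@U, fp@V)
  expect_true(all(ent >= 0 & ent < 0.004))
  expect_identical(initFactors(30, 10, 3, seed = 1), fp)
  expect_false(identical(initFactors(30, 10, 3, seed = 2), fp))

  tiny <- initFactors(1, 1, 1, seed = 3)
  expect_equal(dim(tiny@U), c(1L, 1L))
  expect_true(tiny@U[1, 1] >= 0 && tiny@U[1, 1] < 0.004)

  expect_error(initFactors(5, 4, 5, seed = 1), "L must satisfy")
  expect_error(initFactors(5, 4, 0, seed = 1), "L must satisfy")
})

test_that("blockLoss matches hand-computed values", {
  # exact rank-1 reconstruction has zero loss at lambda = 0
  u <- matrix(c(1, 2), 2, 1); v <- matrix(c(3, 4, 5), 3, 1)
  blk <- SparseFeatureBlock(tcrossprod(u, v))
  expect_equal(blockLoss(FactorPair(u, v), blk, lambda = 0), 0)

  # single observed cell, u.v = 0.5, value 1: 1/2 * 0.5^2 = 0.125
  one <- SparseFeatureBlock(matrix(1), featureIds = "f1")
  fp <- FactorPair(matrix(0.5), matrix(1))
  expect_equal(blockLoss(fp, one, lambda = 0), 0.125)
  # plus per-cell regularization lambda/2 * (|u|^2 + |v|^2)
  expect_equal(blockLoss(fp, one, lambda = 0.1),
               0.125 + 0.05 * (0.25 + 1))
})

test_that("sgdUpdateCell reproduces the hand-computed step", {
  # L=1, u=v=0.5, value 1, eta=0.1, lambda=0: err=0.75, both rows 0.5375
  s <- sgdUpdateCell(0.5, 0.5, 1, eta = 0.1, lambda = 0)
  expect_equal(s$u, 0.5375)
  expect_equal(s$v, 0.5375)
  expect_equal(s$err, 0.75)

  # zero residual leaves rows unchanged without regularization
  s0 <- sgdUpdateCell(c(1, 2), c(2, -0.5), 1, eta = 0.1, lambda = 0)
  expect_equal(s0$u, c(1, 2))
  expect_equal(s0$v, c(2, -0.5))

  # zero residual with lambda > 0 is pure shrinkage by (1 - eta*lambda)
  s1 <- sgdUpdateCell(c(1, 2), c(2, -0.5), 1, eta = 0.1, lambda = 0.5)
  expect_equal(s1$u, c(1, 2) * 0.95)
  expect_equal(s1$v, c(2, -0.5) * 0.95)
})

test_that("sgdUpdateCell agrees with a finite-difference gradient", {
  # per-cell objective: 1/2 err^2 + lambda/2 (|u|^2 + |v|^2)
  cellLoss <- function(u, v, f, lambda)
    0.5 * (f - sum(u * v))^2 + lambda / 2 * (sum(u^2) + sum(v^2))
  withr::with_seed(31, {
    for (rep in 1:20) {
      L <- sample(1:4, 1)
      u <- rnorm(L); v <- rnorm(L); f <- rnorm(1)
      lambda <- runif(1, 0, 0.5); eta <- 1e-3
      s <- sgdUpdateCell(u, v, f, eta, lambda)
      h <- 1e-6
      gu <- vapply(seq_len(L), function(k) {
        up <- u; up[k] <- up[k] + h
        um <- u; um[k] <- um[k] - h
        (cellLoss(up, v, f, lambda) - cellLoss(um, v, f, lambda)) / (2 * h)
      }, numeric(1))
      gv <- vapply(seq_len(L), function(k) {
        vp <- v; vp[k] <- vp[k] + h
        vm <- v; vm[k] <- vm[k] - h
        (cellLoss(u, vp, f, lambda) - cellLoss(u, vm, f, lambda)) / (2 * h)
      }, numeric(1))
      expect_equal(s$u, u - eta * gu, tolerance = 1e-5)
      expect_equal(s$v, v - eta * gv, tolerance = 1e-5)
    }
  })
})

test_that("training reduces loss and beats column-mean imputation", {
  fx <- rank1Block()
  fit <- trainFactors(fx$block, lfaParams(seed = 11))
  expect_lt(tail(fit$trajectory, 1), fit$trajectory[1])
  lfaErr <- heldOutRMSE(fx$block, fx$full, lfaParams(seed = 11))
  expect_lt(lfaErr, colMeanRMSE(fx$block, fx$full))
})

test_that("training is seed-reproducible and validates inputs", {
  fx <- rank1Block(M = 20, H = 8, rho = 0.4, seed = 33)
  f1 <- trainFactors(fx$block, lfaParams(L = 2, seed = 3))
  f2 <- trainFactors(fx$block, lfaParams(L = 2, seed = 3))
  expect_identical(f1$trajectory, f2$trajectory)
  expect_identical(f1$factors@U, f2$factors@U)

  empty <- SparseFeatureBlock(matrix(NA_real_, 4, 3))
  expect_error(trainFactors(empty, lfaParams(L = 2)), "no observed cells")
})

test_that("a divergent learning rate raises an error naming eta", {
  fx <- rank1Block(M = 20, H = 8, rho = 0.2, seed = 44)
  expect_error(trainFactors(fx$block, lfaParams(L = 2, eta = 5, seed = 1)),
               "eta = 5")
})

test_that("repeated epochs with zero residuals shrink the factor norms", {
  # all observed values equal current reconstructions: the only force
  # left is the lambda shrinkage, so |U|, |V| decrease monotonically
  withr::with_seed(55, {
    U <- matrix(runif(12, 0.5, 1), 4, 3)
    V <- matrix(runif(6, 0.5, 1), 2, 3)
  })
  blk <- SparseFeatureBlock(tcrossprod(U, V))
  norms <- numeric(6)
  for (i in 1:6) {
    norms[i] <- sqrt(sum(U^2) + sum(V^2))
    for (m in 1:4) for (j in 1:2) {
      s <- sgdUpdateCell(U[m, ], V[j, ], sum(U[m, ] * V[j, ]),
                         eta = 0.1, lambda = 0.3)
      U[m, ] <- s$u; V[j, ] <- s$v
    }
  }
  expect_true(all(diff(norms) < 0))
})

test_that("completeBlock copies observed cells and fills the rest", {
  fx <- rank1Block(M = 10, H = 6, rho = 0.3, seed = 66)
  fp <- trainFactors(fx$block, lfaParams(L = 2, seed = 1))$factors
  comp <- completeBlock(fx$block, fp)
  mask <- blockMask(fx$block)
  expect_identical(comp[mask], blockValues(fx$block)[mask])
  expect_false(anyNA(comp))

  # exact factors reproduce a hidden cell exactly
  u <- matrix(c(1, 2), 2, 1); v <- matrix(c(3, 4), 2, 1)
  vals <- tcrossprod(u, v)
  hidden <- vals; hidden[2, 2] <- NA
  out <- completeBlock(SparseFeatureBlock(hidden), FactorPair(u, v))
  expect_equal(unname(out[2, 2]), 8)

  full <- SparseFeatureBlock(vals)
  expect_equal(completeBlock(full, FactorPair(u, v)), vals,
               ignore_attr = TRUE)
})

test_that("held-out error decreases as more cells are observed", {
  params <- lfaParams(L = 3, seed = 21)
  rmse <- vapply(c(0.5, 0.3, 0.1), function(rho) {
    fx <- rank1Block(M = 50, H = 20, rho = rho, seed = 77)
    heldOutRMSE(fx$block, fx$full, params)
  }, numeric(1))
  expect_true(all(diff(rmse) < 0))
})
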