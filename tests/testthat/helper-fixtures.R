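# Shared in-code fixtures for the test suite.

# Two well-separated Gaussian clouds: any sane classifier scores ~0 error.
separableToy <- function(M = 40, p = 2, gap = 6, seed = 100) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(M / 2 * p), M / 2, p),
               matrix(rnorm(M / 2 * p, mean = gap), M / 2, p))
  })
  list(X = X, y = factor(rep(c("a", "b"), each = M / 2)))
}

# A noiseless rank-1 matrix with a seeded MCAR mask.
rank1Block <- function(M = 50, H = 20, rho = 0.3, seed = 200) {
  withr::with_seed(seed, {
    a <- rnorm(M); b <- rnorm(H)
  })
  full <- outer(a, b)
  list(full = full, block = injectMCAR(full, rho, seed = seed + 1))
}

# Column-mean imputation RMSE on the hidden cells of a masked block:
# the baseline oracle the factor model must beat.
colMeanRMSE <- function(block, full) {
  vals <- blockValues(block)
  mask <- blockMask(block)
  cm <- colMeans(vals, na.rm = TRUE)
  cm[is.nan(cm)] <- 0
  est <- matrix(cm, nrow(vals), ncol(vals), byrow = TRUE)
  sqrt(mean((est[!mask] - full[!mask])^2))
}

heldOutRMSE <- function(block, full, params) {
  comp <- completeBlock(block, trainFactors(block, params)$factors)
  mask <- blockMask(block)
  sqrt(mean((comp[!mask] - full[!mask])^2))
}

# The bundled five-method / six-dataset accuracy table.
accTable <- function() exampleAccuracyTable()
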