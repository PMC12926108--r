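# Elitist genetic algorithm over binary feature-inclusion chromosomes.

#' Initialize a GA population
#'
#' N chromosomes of length n; each bit is an independent Bernoulli(p0)
#' draw. \code{p0 = 0.5} gives unbiased initial exploration.
#'
#' @param N population size (>= 2).
#' @param n chromosome length (>= 1).
#' @param p0 per-bit inclusion probability.
#' @param seed integer seed.
#' @return integer matrix N x n of 0/1 bits.
#' @export
initPopulation <- function(N, n, p0 = 0.5, seed = 1L) {
  if (N < 2) stop("population size N must be >= 2")
  if (n < 1) stop("chromosome length n must be >= 1")
  withr::with_seed(deriveSeed(seed, "ga-init"),
    matrix(rbinom(N * n, 1L, p0), nrow = N, ncol = n))
}

#' Fitness of a chromosome
#'
#' \code{alpha * error + beta * ||b||_0 / n}, where the error is the
#' wrapped classifier's validation error on the selected columns. The
#' all-zero chromosome uses the majority-class error, so the empty
#' subset is never scored as a perfect classifier.
#'
#' @param bits 0/1 vector of length n.
#' @param X numeric M x n candidate matrix.
#' @param y class labels.
#' @param spec a [classifierSpec()].
#' @param protocol an [evalProtocol()].
#' @param alpha,beta objective weights (error term, sparsity term).
#' @param cache optional environment used to memoize fitness values by
#'   bit pattern; wrapper evaluations dominate cost and the GA revisits
#'   patterns.
#' @param splits optional precomputed validation splits (see
#'   [classificationError()]).
#' @return non-negative fitness (lower is better).
#' @export
chromosomeFitness <- function(bits, X, y, spec = classifierSpec("knn3"),
                              protocol = evalProtocol(), alpha = 1,
                              beta = 0.01, cache = NULL, splits = NULL) {
  n <- length(bits)
  stopifnot(all(bits %in% c(0, 1)), ncol(X) == n)
  key <- paste(bits, collapse = "")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  eps <- if (sum(bits) == 0) majorityClassError(y)
         else classificationError(X[, bits == 1, drop = FALSE], y, spec,
                                  protocol, splits)
  f <- alpha * eps + beta * sum(bits) / n
  if (!is.null(cache)) cache[[key]] <- f
  f
}

#' Roulette-wheel selection index
#'
#' Weights are \code{1 / (f + iota)} so lower error means higher
#' selection probability; \code{iota > 0} prevents division by zero.
#' Returns \code{min(i : P_i >= r)} for the cumulative probabilities
#' \code{P_i} and a uniform draw \code{r} (taken from the current RNG
#' stream unless supplied).
#'
#' @param fitnesses non-negative fitness vector.
#' @param iota small positive constant.
#' @param r optional uniform(0, 1) draw (for reproducing a specific
#'   selection); defaults to a fresh draw.
#' @return 1-based index of the selected chromosome.
#' @export
rouletteSelect <- function(fitnesses, iota = 1e-6, r = NULL) {
  stopifnot(length(fitnesses) >= 1, iota > 0, all(is.finite(fitnesses)))
  w <- 1 / (fitnesses + iota)
  P <- cumsum(w / sum(w))
  if (is.null(r)) r <- runif(1)
  which(P >= r)[1]
}

#' Single-point crossover
#'
#' With probability \code{pc}, a cut point c is drawn uniformly on
#' \code{1..(n-1)} and the tails after c are swapped; otherwise the
#' offspring are exact copies. Length-1 chromosomes degenerate to
#' copying.
#'
#' @param bp,bq parent bit vectors of equal length.
#' @param pc crossover probability.
#' @param cutPoint optional forced cut point (crossover then always
#'   applied), used for deterministic construction.
#' @return list with offspring \code{bp} and \code{bq}.
#' @export
singlePointCrossover <- function(bp, bq, pc = 0.8, cutPoint = NULL) {
  n <- length(bp)
  stopifnot(length(bq) == n)
  if (n < 2) return(list(bp = bp, bq = bq))
  doCross <- if (is.null(cutPoint)) runif(1) < pc else TRUE
  if (doCross) {
    cp <- if (is.null(cutPoint)) sample.int(n - 1L, 1L) else cutPoint
    stopifnot(cp >= 1, cp <= n - 1)
    tail <- (cp + 1L):n
    t1 <- bp[tail]
    bp[tail] <- bq[tail]
    bq[tail] <- t1
  }
  list(bp = bp, bq = bq)
}

#' Bit-flip mutation
#'
#' Each bit is independently flipped with probability \code{pm}.
#'
#' @param bits 0/1 vector.
#' @param pm per-bit flip probability.
#' @return mutated bit vector.
#' @export
bitFlipMutation <- function(bits, pm = 0.05) {
  flip <- runif(length(bits)) < pm
  bits[flip] <- 1L - bits[flip]
  bits
}

#' Elitist replacement
#'
#' The offspring with maximal (worst) fitness — ties broken toward the
#' lowest index — is replaced by the best chromosome found so far, which
#' guarantees the population's minimum fitness never exceeds the running
#' best and hence a non-increasing convergence curve.
#'
#' @param pop offspring population matrix (N x n).
#' @param fits offspring fitness vector.
#' @param bBest best chromosome so far.
#' @param fBest its fitness.
#' @return list with updated \code{pop} and \code{fits}.
#' @export
elitistReplacement <- function(pop, fits, bBest, fBest) {
  worst <- which.max(fits)  # which.max returns the first maximum
  pop[worst, ] <- bBest
  fits[worst] <- fBest
  list(pop = pop, fits = fits)
}

#' Run the elitist GA over a candidate feature matrix
#'
#' Initialization (Bernoulli(p0) bits), then \code{Tmax} generations of
#' roulette selection into a mating pool of size N, single-point
#' crossover of consecutive pairs (odd N: the final individual passes
#' through uncrossed), per-bit mutation, offspring evaluation, best
#' update, and elitist replacement of the worst offspring. Fitness
#' evaluations are pure functions of the bit pattern (splits depend only
#' on the protocol seed) and are memoized, so their scheduling order
#' cannot change the result.
#'
#' @param X numeric M x n candidate matrix (column names are the feature
#'   ids).
#' @param y class labels.
#' @param params a [gaParams()].
#' @param spec a [classifierSpec()].
#' @param protocol an [evalProtocol()].
#' @param warmStart optional 0/1 vector of length n injected as the
#'   first chromosome of the initial population (the remaining N - 1
#'   are Bernoulli(p0) draws). Streaming runs pass the incumbent
#'   selected set here: combined with elitism it guarantees the winner
#'   never scores worse than the incumbent, so carried-over features
#'   are only dropped when the objective measurably prefers it.
#' @return list of class \code{"GAResult"}: \code{bestBits},
#'   \code{selected} (ids), \code{nSelected}, \code{fitness},
#'   \code{convergence} (length Tmax + 1, non-increasing) and
#'   \code{evaluations} (number of distinct wrapper evaluations).
#' @examples
#' sim <- generateStream(syntheticStreamSpec(M = 40, totalFeatures = 6,
#'   rank = 2, nInformative = 2, nRedundant = 0, missingRate = 0, seed = 3))
#' res <- runGA(sim$values, sim$labels, gaParams(N = 10, Tmax = 5, seed = 3))
#' res$selected
#' @export
runGA <- function(X, y, params = gaParams(), spec = classifierSpec("knn3"),
                  protocol = evalProtocol(), warmStart = NULL) {
  stopifnot(inherits(params, "GAParams"))
  X <- as.matrix(X)
  n <- ncol(X)
  if (n < 1) stop("candidate matrix must have at least one feature")
  if (params$N < 2) stop("population size N must be >= 2")
  if (params$Tmax < 0) stop("Tmax must be >= 0")
  ids <- colnames(X)
  if (is.null(ids)) ids <- sprintf("f%04d", seq_len(n))

  cache <- new.env(parent = emptyenv())
  splits <- protocolSplits(as.factor(y), protocol)
  evalPop <- function(pop) {
    vapply(seq_len(nrow(pop)), function(i)
      chromosomeFitness(pop[i, ], X, y, spec, protocol,
                        params$alpha, params$beta, cache, splits),
      numeric(1))
  }

  pop <- initPopulation(params$N, n, params$p0, params$seed)
  if (!is.null(warmStart)) {
    stopifnot(length(warmStart) == n, all(warmStart %in% c(0, 1)))
    pop[1, ] <- as.integer(warmStart)
  }
  fits <- evalPop(pop)
  bi <- which.min(fits)
  bBest <- pop[bi, ]; fBest <- fits[bi]
  curve <- numeric(params$Tmax + 1)
  curve[1] <- fBest

  withr::with_seed(deriveSeed(params$seed, "ga-ops"), {
    t <- 0L
    while (t < params$Tmax) {
      mates <- t(vapply(seq_len(params$N), function(i)
        pop[rouletteSelect(fits, params$iota), ], numeric(n)))
      if (n == 1) mates <- matrix(mates, ncol = 1)
      off <- mates
      i <- 1L
      while (i + 1L <= params$N) {
        cr <- singlePointCrossover(mates[i, ], mates[i + 1L, ], params$pc)
        off[i, ] <- cr$bp
        off[i + 1L, ] <- cr$bq
        i <- i + 2L
      }
      for (i in seq_len(params$N)) off[i, ] <- bitFlipMutation(off[i, ], params$pm)
      fits <- evalPop(off)
      if (min(fits) < fBest) {
        bi <- which.min(fits)
        bBest <- off[bi, ]; fBest <- fits[bi]
      }
      el <- elitistReplacement(off, fits, bBest, fBest)
      pop <- el$pop; fits <- el$fits
      t <- t + 1L
      curve[t + 1L] <- fBest
    }
  })

  structure(list(bestBits = bBest, selected = ids[bBest == 1],
                 nSelected = sum(bBest), fitness = fBest,
                 convergence = curve,
                 evaluations = length(ls(cache))),
            class = "GAResult")
}

#' @export
print.GAResult <- function(x, ...) {
  cat(sprintf("GAResult: %d features selected, fitness %.4f after %d generations\n",
              x$nSelected, x$fitness, length(x$convergence) - 1L))
  invisible(x)
}
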