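# Buffering of the feature stream and the per-block
# impute -> select -> prune orchestration.

#' Buffer a feature stream into fixed-width sparse blocks
#'
#' Columns arrive in order and are collected into blocks of width H;
#' every block except possibly the last has width H and the last block
#' holds the remainder (no data are discarded). The concatenation of
#' block feature ids equals the input order.
#'
#' @param values numeric matrix, samples x features, with \code{NA}
#'   marking missing entries; columns in arrival order.
#' @param H buffer width (>= 1).
#' @param featureIds optional character ids (default: column names or
#'   \code{"f0001"}-style).
#' @return list of [SparseFeatureBlock-class] objects (empty list for a
#'   zero-column input).
#' @examples
#' blocks <- bufferStream(matrix(rnorm(40), 4, 10), H = 4)
#' vapply(blocks, blockWidth, integer(1))  # 4 4 2
#' @export
bufferStream <- function(values, H, featureIds = NULL) {
  stopifnot(H >= 1)
  values <- as.matrix(values)
  Tn <- ncol(values)
  if (is.null(featureIds)) {
    featureIds <- colnames(values)
    if (is.null(featureIds)) featureIds <- sprintf("f%04d", seq_len(Tn))
  }
  if (length(featureIds) != Tn)
    stop("featureIds length must equal the number of columns")
  if (Tn == 0L) return(list())
  starts <- seq(1L, Tn, by = H)
  lapply(starts, function(s) {
    cols <- s:min(s + H - 1L, Tn)
    SparseFeatureBlock(values[, cols, drop = FALSE],
                       featureIds = featureIds[cols])
  })
}

#' Process a sparse feature stream: impute, select, prune
#'
#' For each block in order: (1) complete the block with the latent-
#' factor model (skipped identically when nothing is missing); (2) form
#' the candidate pool as the previously selected features plus the
#' current block's features (features discarded in earlier blocks are
#' not recalled); (3) run the elitist GA over the pool; (4) screen the
#' GA winner's features for irrelevance and apply redundancy pruning;
#' (5) update the selected set. The master seed is split into
#' independent substreams per block and component, so re-running with
#' the same seed reproduces the state exactly.
#'
#' @param blocks non-empty list of [SparseFeatureBlock-class] objects,
#'   e.g. from [bufferStream()] or [generateStream()].
#' @param labels class labels, length M, at least 2 classes.
#' @param config a [streamConfig()].
#' @return a [SelectionState-class].
#' @examples
#' sim <- generateStream(syntheticStreamSpec(M = 40, totalFeatures = 10,
#'   rank = 3, nInformative = 2, nRedundant = 1, missingRate = 0,
#'   bufferWidth = 5, seed = 2))
#' cfg <- streamConfig(ga = gaParams(N = 8, Tmax = 5), masterSeed = 2)
#' st <- processStream(sim$blocks, sim$labels, cfg)
#' selectedFeatures(st)
#' @export
processStream <- function(blocks, labels, config = streamConfig()) {
  stopifnot(inherits(config, "StreamConfig"))
  if (length(blocks) == 0L) stop("empty stream: no blocks to process")
  if (!all(vapply(blocks, is, logical(1), "SparseFeatureBlock")))
    stop("blocks must be SparseFeatureBlock objects")
  if (missing(labels) || is.null(labels)) stop("labels are required")
  labels <- as.factor(labels)
  M <- sampleCount(blocks[[1]])
  if (length(labels) != M) stop("labels length must equal the sample count")
  if (nlevels(droplevels(labels)) < 2)
    stop("labels must contain at least 2 distinct classes")

  selIds <- character(0)
  selVals <- matrix(nrow = M, ncol = 0)
  history <- list()
  seen <- 0L

  for (t in seq_along(blocks)) {
    blk <- blocks[[t]]
    if (sampleCount(blk) != M) stop("all blocks must share the sample count M")
    rho <- missingRate(blk)

    lp <- config$lfa
    lp$seed <- deriveSeed(config$masterSeed, "lfa", t)
    # narrow final blocks cap the latent dimension at min(M, width)
    lp$L <- min(lp$L, sampleCount(blk), blockWidth(blk))
    completed <- imputeBlock(blk, lp)

    pool <- cbind(selVals, completed)
    colnames(pool) <- c(selIds, featureIds(blk))

    gp <- config$ga
    gp$seed <- deriveSeed(config$masterSeed, "ga", t)
    pr <- config$protocol
    pr$seed <- deriveSeed(config$masterSeed, "eval", t)
    # the incumbent selected set seeds the initial population: with
    # elitism the winner can never score worse than S_{t-1}
    warm <- c(rep(1L, length(selIds)), rep(0L, blockWidth(blk)))
    ga <- runGA(pool, labels, gp, config$classifier, pr, warmStart = warm)

    winner <- pool[, ga$bestBits == 1, drop = FALSE]

    # individual-feature relevance screen: drop features independent of
    # the label under every conditioning subset of the other winners
    irrelevant <- logical(ncol(winner))
    for (j in seq_len(ncol(winner))) {
      irrelevant[j] <- isIrrelevant(
        winner[, j], labels, winner[, -j, drop = FALSE],
        config$redundancyAlpha, config$maxCond)
    }
    screened <- winner[, !irrelevant, drop = FALSE]

    pruned <- redundancyPrune(screened, labels, config$redundancyAlpha,
                              config$maxCond)

    selIds <- pruned$keptIds
    selVals <- pruned$kept
    seen <- seen + blockWidth(blk)
    history[[t]] <- list(
      block = t, missingRate = rho,
      candidateCount = ncol(pool),
      convergence = ga$convergence,
      gaSelected = ga$selected,
      screenedOut = colnames(winner)[irrelevant],
      prunedOut = pruned$removedIds,
      postPruneSize = length(selIds))
  }

  new("SelectionState", selectedIds = selIds, selectedValues = selVals,
      history = history, totalSeen = seen,
      masterSeed = as.numeric(config$masterSeed))
}
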