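#' Latent-factor model parameters
#'
#' Settings for block completion by regularized matrix factorization
#' trained with SGD on the observed cells.
#'
#' @param L latent dimension (default 5); must satisfy
#'   \code{1 <= L <= min(M, H)} at training time.
#' @param eta learning rate (> 0, default 0.01).
#' @param lambda regularization coefficient (>= 0, default 0.05), applied
#'   per observed cell to both factor rows.
#' @param maxEpochs maximum SGD epochs (default 500).
#' @param relTol relative-change stopping tolerance on the training loss
#'   (default 1e-5).
#' @param seed integer seed for factor initialization and cell ordering.
#' @return validated list of class \code{"LfaParams"}.
#' @export
lfaParams <- function(L = 5L, eta = 0.01, lambda = 0.05, maxEpochs = 500L,
                      relTol = 1e-5, seed = 1L) {
  stopifnot(L >= 1, eta > 0, lambda >= 0, maxEpochs >= 1, relTol >= 0)
  structure(list(L = as.integer(L), eta = eta, lambda = lambda,
                 maxEpochs = as.integer(maxEpochs), relTol = relTol,
                 initScale = 0.004, seed = as.integer(seed)),
            class = "LfaParams")
}

#' Genetic-algorithm parameters
#'
#' @param N population size (>= 2, default 30).
#' @param Tmax maximum generations (default 100).
#' @param pc single-point crossover probability (default 0.8).
#' @param pm per-bit mutation probability (default 0.05).
#' @param p0 initial per-bit inclusion probability (default 0.5, unbiased
#'   exploration).
#' @param iota small positive constant in the roulette weight
#'   \code{1 / (f + iota)} preventing division by zero (default 1e-6).
#' @param alpha weight of the classification-error term (default 1).
#' @param beta weight of the sparsity term \code{||b||_0 / n}
#'   (default 0.01): small enough that error dominates, but ties break
#'   toward sparser subsets.
#' @param mu mutation strength; accepted and recorded but unused by the
#'   binary bit-flip operator (default 0.01).
#' @param seed integer seed controlling initialization and operators.
#' @return validated list of class \code{"GAParams"}.
#' @export
gaParams <- function(N = 30L, Tmax = 100L, pc = 0.8, pm = 0.05, p0 = 0.5,
                     iota = 1e-6, alpha = 1, beta = 0.01, mu = 0.01,
                     seed = 1L) {
  stopifnot(N >= 2, Tmax >= 0, pc >= 0, pc <= 1, pm >= 0, pm <= 1,
            p0 >= 0, p0 <= 1, iota > 0, alpha >= 0, beta >= 0,
            alpha + beta > 0)
  structure(list(N = as.integer(N), Tmax = as.integer(Tmax), pc = pc,
                 pm = pm, p0 = p0, iota = iota, alpha = alpha, beta = beta,
                 mu = mu, seed = as.integer(seed)),
            class = "GAParams")
}

#' Wrapped-classifier specification
#'
#' @param kind one of \code{"knn3"} (3-nearest-neighbours), \code{"rf6"}
#'   (random forest, 6 trees), \code{"cart"} (CART with default split
#'   rules) or \code{"svm_linear"} (linear-kernel SVM). The SVM is fit
#'   without internal rescaling, the usual libsvm practice when inputs
#'   are already on comparable scales; pre-standardize features that are
#'   not.
#' @return validated list of class \code{"ClassifierSpec"}.
#' @export
classifierSpec <- function(kind = c("knn3", "rf6", "cart", "svm_linear")) {
  kind <- match.arg(kind)
  settings <- switch(kind,
    knn3 = list(neighbors = 3L),
    rf6 = list(trees = 6L),
    cart = list(),
    svm_linear = list(kernel = "linear", scale = FALSE))
  structure(list(kind = kind, settings = settings), class = "ClassifierSpec")
}

#' Fitness evaluation protocol
#'
#' @param k hold-out folds: \code{k = 0} (default) means a single
#'   stratified 70/30 hold-out; \code{k >= 2} means stratified k-fold.
#' @param repeats number of repeats with re-randomized splits (default 1).
#' @param seed integer seed; splits are a function of the seed only, so a
#'   fitness evaluation is a pure function of the chromosome.
#' @return validated list of class \code{"EvalProtocol"}.
#' @export
evalProtocol <- function(k = 0L, repeats = 1L, seed = 1L) {
  stopifnot(k == 0 || k >= 2, repeats >= 1)
  structure(list(k = as.integer(k), repeats = as.integer(repeats),
                 seed = as.integer(seed)),
            class = "EvalProtocol")
}

#' Streaming-run configuration
#'
#' @param bufferWidth block width H (>= 1).
#' @param lfa an [lfaParams()] object.
#' @param ga a [gaParams()] object (default uses a per-block budget of
#'   50 generations: block pools are small — at most the carried-over
#'   set plus H new arrivals — and convergence plateaus well before the
#'   standalone-search default of 100).
#' @param classifier a [classifierSpec()] used inside the GA fitness
#'   (default linear SVM, the canonical wrapper example; its validation
#'   error degrades sharply when an informative feature is dropped,
#'   which keeps the subset objective well-separated).
#' @param protocol an [evalProtocol()] for fitness evaluation (default
#'   stratified two-fold cross-validation: every sample is validated
#'   once, which keeps the error resolution fine enough to rank a
#'   parent feature above its noisy duplicate, at two classifier fits
#'   per evaluation).
#' @param redundancyAlpha significance level of the conditional-
#'   independence tests (default 0.05).
#' @param maxCond maximum conditioning-subset size d (default 3).
#' @param masterSeed integer master seed; split into independent
#'   substreams for factor initialization, GA operators and splits, so no
#'   component's randomness perturbs another's.
#' @return validated list of class \code{"StreamConfig"}.
#' @export
streamConfig <- function(bufferWidth = 20L, lfa = lfaParams(),
                         ga = gaParams(Tmax = 50L),
                         classifier = classifierSpec("svm_linear"),
                         protocol = evalProtocol(k = 2L),
                         redundancyAlpha = 0.05, maxCond = 3L,
                         masterSeed = 1L) {
  stopifnot(bufferWidth >= 1, inherits(lfa, "LfaParams"),
            inherits(ga, "GAParams"), inherits(classifier, "ClassifierSpec"),
            inherits(protocol, "EvalProtocol"),
            redundancyAlpha > 0, redundancyAlpha < 1, maxCond >= 0)
  structure(list(bufferWidth = as.integer(bufferWidth), lfa = lfa, ga = ga,
                 classifier = classifier, protocol = protocol,
                 redundancyAlpha = redundancyAlpha,
                 maxCond = as.integer(maxCond),
                 masterSeed = as.integer(masterSeed)),
            class = "StreamConfig")
}

#' Synthetic sparse-stream specification
#'
#' Parameters of the generator emulating the structural assumptions the
#' selection pipeline relies on: an approximately low-rank feature matrix,
#' a planted label-informative subset, redundant features that are linear
#' combinations of informative ones, pure-noise features whose latent
#' weights are orthogonal to the label direction, and an MCAR mask.
#'
#' @param M samples (>= 20).
#' @param totalFeatures total streamed features T.
#' @param rank true latent rank of the generated matrix (default 10).
#'   Must exceed \code{nInformative} for noise features to exist as
#'   genuinely label-independent low-rank structure: noise features load
#'   only on the latents beyond the first \code{nInformative}, so they
#'   carry no label information individually or jointly.
#' @param nInformative planted informative features (<= rank).
#' @param nRedundant redundant features (noisy scaled duplicates of
#'   informative columns, assigned round-robin).
#' @param labelModel \code{"linear-threshold"} (sign of a weighted sum of
#'   the informative columns) or \code{"xor-pair"} (exclusive-or of two
#'   thresholded informative columns).
#' @param noiseSd additive noise standard deviation (default 0.5,
#'   i.e. a 4:1 signal-to-noise variance ratio, typical of biomedical
#'   assays). The noise also degrades redundant duplicates relative to
#'   their parents, which is what makes planted roles identifiable: at
#'   very small \code{noiseSd} a duplicate is statistically
#'   interchangeable with its parent and no method can be expected to
#'   prefer the original.
#' @param missingRate MCAR cell-hiding probability in \eqn{[0, 1)}.
#' @param bufferWidth block width H used when streaming the features.
#' @param seed integer seed; generation is fully reproducible.
#' @return validated list of class \code{"SyntheticStreamSpec"}.
#' @export
syntheticStreamSpec <- function(M = 200L, totalFeatures = 100L, rank = 10L,
                                nInformative = 5L, nRedundant = 5L,
                                labelModel = c("linear-threshold", "xor-pair"),
                                noiseSd = 0.5, missingRate = 0.1,
                                bufferWidth = 20L, seed = 1L) {
  labelModel <- match.arg(labelModel)
  stopifnot(M >= 20, totalFeatures >= 1, rank >= 1, nInformative >= 1,
            nRedundant >= 0, nInformative + nRedundant <= totalFeatures,
            nInformative <= rank, noiseSd >= 0,
            missingRate >= 0, missingRate < 1, bufferWidth >= 1)
  if (labelModel == "xor-pair" && nInformative < 2)
    stop("xor-pair label model needs at least 2 informative features")
  structure(list(M = as.integer(M), totalFeatures = as.integer(totalFeatures),
                 rank = as.integer(rank), nInformative = as.integer(nInformative),
                 nRedundant = as.integer(nRedundant),
                 nNoise = as.integer(totalFeatures - nInformative - nRedundant),
                 labelModel = labelModel, noiseSd = noiseSd,
                 missingRate = missingRate,
                 bufferWidth = as.integer(bufferWidth),
                 seed = as.integer(seed)),
            class = "SyntheticStreamSpec")
}
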