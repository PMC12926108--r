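# Wrapper-classifier error evaluation: the fitness core of the GA.

fitAndPredictError <- function(spec, Xtr, ytr, Xte, yte, seed) {
  lv <- levels(ytr)
  pred <- switch(spec$kind,
    knn3 = {
      fit <- caret::knn3(Xtr, ytr, k = spec$settings$neighbors)
      pr <- predict(fit, Xte, type = "prob")
      # ties.method = "first" breaks probability ties toward the smallest
      # class label (columns are in level order)
      factor(lv[max.col(pr, ties.method = "first")], levels = lv)
    },
    rf6 = {
      fit <- withr::with_seed(seed,
        randomForest::randomForest(Xtr, ytr, ntree = spec$settings$trees))
      predict(fit, Xte)
    },
    cart = {
      dtr <- data.frame(Xtr); dtr$.y <- ytr
      dte <- data.frame(Xte)
      colnames(dte) <- colnames(data.frame(Xtr))
      fit <- rpart::rpart(.y ~ ., data = dtr, method = "class")
      predict(fit, dte, type = "class")
    },
    svm_linear = {
      fit <- e1071::svm(Xtr, ytr, kernel = "linear",
                        scale = spec$settings$scale)
      predict(fit, Xte)
    },
    stop("unrecognized classifier kind: ", spec$kind))
  mean(as.character(pred) != as.character(yte))
}

checkStratifiable <- function(y, need) {
  tab <- table(y)
  bad <- names(tab)[tab < need]
  if (length(bad) > 0)
    stop(sprintf("class '%s' has %d sample(s), fewer than the %d required for stratified splitting",
                 bad[1], tab[bad[1]], need))
}

# Stratified validation splits for a protocol: a list of repeats, each a
# list of test-index vectors. Splits depend only on (y, protocol), never
# on the feature subset, so every chromosome in a GA run is scored
# against identical folds and the splits can be computed once per run.
protocolSplits <- function(y, protocol) {
  lapply(seq_len(protocol$repeats), function(r) {
    splitSeed <- deriveSeed(protocol$seed, "split", r)
    withr::with_seed(splitSeed, {
      if (protocol$k == 0L) {
        tr <- caret::createDataPartition(y, p = 0.7, list = FALSE)[, 1]
        list(setdiff(seq_along(y), tr))
      } else {
        caret::createFolds(y, k = protocol$k)
      }
    })
  })
}

#' Classification error of a feature subset
#'
#' Mean misclassification rate of the wrapped classifier over the
#' protocol's validation splits. With \code{k = 0} a single stratified
#' 70/30 hold-out is used per repeat; with \code{k >= 2}, stratified
#' k-fold cross-validation. With zero columns the majority-class error
#' is returned, so the empty subset never scores as a perfect
#' classifier. Splits depend only on the protocol seed, making the
#' error a pure, order-independent function of the subset.
#'
#' @param X numeric M x p matrix (p may be 0).
#' @param y class labels (factor or coercible), length M.
#' @param spec a [classifierSpec()].
#' @param protocol an [evalProtocol()].
#' @param splits optional precomputed [protocolSplits()] result (an
#'   internal memoization used by [runGA()]); when supplied it must
#'   have been built from the same \code{y} and \code{protocol}.
#' @return error rate in \eqn{[0, 1]}.
#' @examples
#' X <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 4), 20))
#' y <- rep(c("a", "b"), each = 20)
#' classificationError(X, y, classifierSpec("knn3"), evalProtocol(seed = 1))
#' @export
classificationError <- function(X, y, spec = classifierSpec("knn3"),
                                protocol = evalProtocol(), splits = NULL) {
  stopifnot(inherits(spec, "ClassifierSpec"), inherits(protocol, "EvalProtocol"))
  y <- as.factor(y)
  if (nlevels(droplevels(y)) < 2) stop("labels must contain at least 2 classes")
  X <- as.matrix(X)
  if (ncol(X) == 0) return(majorityClassError(y))
  if (nrow(X) != length(y)) stop("X and y disagree on the number of samples")
  if (nrow(X) < 10) stop("at least 10 samples are required for stratified splitting")
  checkStratifiable(y, max(2L, protocol$k))
  colnames(X) <- sprintf("V%d", seq_len(ncol(X)))
  if (is.null(splits)) splits <- protocolSplits(y, protocol)

  idx <- seq_along(y)
  errs <- unlist(lapply(seq_along(splits), function(r) {
    clfSeed <- deriveSeed(protocol$seed, "clf", r)
    vapply(splits[[r]], function(te) {
      tr <- idx[-te]
      fitAndPredictError(
        spec, X[tr, , drop = FALSE], droplevels(y[tr]),
        X[te, , drop = FALSE], y[te], seed = clfSeed)
    }, numeric(1))
  }))
  mean(errs)
}
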