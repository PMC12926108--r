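# Evaluation protocol: repeated cross-validated accuracy, Friedman test
# across methods x datasets, exact Wilcoxon signed-rank comparison.

#' Repeated stratified cross-validated accuracy (percent)
#'
#' Mean and standard deviation of classification accuracy over
#' \code{repeats} repeats of stratified \code{folds}-fold
#' cross-validation, with splits re-randomized per repeat. The standard
#' deviation is taken across the per-repeat mean accuracies.
#'
#' @param X numeric M x p feature matrix (the selected subset).
#' @param y class labels.
#' @param spec a [classifierSpec()].
#' @param folds fold count (>= 2, default 5: 80/20 splits).
#' @param repeats number of repeats (default 10).
#' @param seed integer seed; results are seed-deterministic.
#' @return list with \code{mean} and \code{sd}, both on the percent
#'   scale.
#' @export
crossValidatedAccuracy <- function(X, y, spec = classifierSpec("knn3"),
                                   folds = 5L, repeats = 10L, seed = 1L) {
  stopifnot(folds >= 2, repeats >= 1)
  y <- as.factor(y)
  X <- as.matrix(X)
  colnames(X) <- sprintf("V%d", seq_len(ncol(X)))
  checkStratifiable(y, folds)
  repMeans <- vapply(seq_len(repeats), function(r) {
    fs <- withr::with_seed(deriveSeed(seed, "cvrep", r),
                           caret::createFolds(y, k = folds))
    accs <- vapply(fs, function(te) {
      tr <- setdiff(seq_along(y), te)
      1 - fitAndPredictError(spec, X[tr, , drop = FALSE], droplevels(y[tr]),
                             X[te, , drop = FALSE], y[te],
                             seed = deriveSeed(seed, "cvclf", r))
    }, numeric(1))
    mean(accs)
  }, numeric(1))
  list(mean = 100 * mean(repMeans),
       sd = 100 * (if (repeats > 1) sd(repMeans) else 0))
}

#' Friedman rank test over a methods-by-datasets accuracy table
#'
#' Ranks the methods within each dataset (rank 1 = highest accuracy,
#' ties get average ranks) and computes the chi-square statistic
#' \code{12 / (n k (k+1)) * sum(Rj^2) - 3 n (k+1)} with \code{k - 1}
#' degrees of freedom, where k is the number of methods and n the
#' number of datasets.
#'
#' @param acc numeric matrix, methods in rows, datasets in columns,
#'   accuracies in percent.
#' @return list with \code{statistic}, \code{p.value}, \code{rankSums}
#'   and the rank matrix \code{ranks}.
#' @export
friedmanRankTest <- function(acc) {
  acc <- as.matrix(acc)
  k <- nrow(acc); n <- ncol(acc)
  if (k < 2 || n < 2)
    stop("Friedman test needs at least 2 methods and 2 datasets")
  if (any(!is.finite(acc))) stop("accuracy table contains non-finite values")
  ranks <- apply(acc, 2, function(col) rank(-col, ties.method = "average"))
  Rj <- rowSums(ranks)
  stat <- 12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
  list(statistic = stat,
       p.value = pchisq(stat, df = k - 1, lower.tail = FALSE),
       rankSums = Rj, ranks = ranks)
}

# Exact null distribution of R+ by convolution over the (doubled, hence
# integer even with average ranks) rank values: counts[s + 1] holds the
# number of sign assignments with doubled rank sum s.
exactRplusTail <- function(ranks2, threshold2, lower = FALSE) {
  total <- sum(ranks2)
  counts <- c(1, rep(0, total))
  for (r in ranks2) {
    shifted <- c(rep(0, r), counts[seq_len(total + 1 - r)])
    counts <- counts + shifted
  }
  s <- 0:total
  sel <- if (lower) s <= threshold2 else s >= threshold2
  sum(counts[sel]) / 2^length(ranks2)
}

#' Exact Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are discarded; the absolute differences are ranked
#' with average ranks on ties; R+ and R- are the rank sums of the
#' positive and negative differences. The p-value is exact, from the
#' full null distribution over all 2^n sign assignments.
#'
#' @param a,b paired numeric vectors of equal length.
#' @param alternative \code{"greater"} (one-sided: a tends to exceed b,
#'   the orientation of a proposed-vs-baseline report) or
#'   \code{"two.sided"}.
#' @return list with \code{rPlus}, \code{rMinus}, \code{p.value}
#'   (exact) and \code{n} (non-zero differences used).
#' @examples
#' wilcoxonSignedRankExact(c(5, 6, 7, 8, 9, 10), c(1, 2, 3, 4, 5, 6))
#' @export
wilcoxonSignedRankExact <- function(a, b,
                                    alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all paired differences are zero: test undefined")
  if (n > 30) stop("exact enumeration supported for n <= 30")
  rk <- rank(abs(d))
  rPlus <- sum(rk[d > 0])
  rMinus <- sum(rk[d < 0])
  ranks2 <- as.integer(round(2 * rk))
  pGreater <- exactRplusTail(ranks2, round(2 * rPlus))
  p <- if (alternative == "greater") pGreater
       else min(1, 2 * min(pGreater,
                           exactRplusTail(ranks2, round(2 * rPlus),
                                          lower = TRUE)))
  list(rPlus = rPlus, rMinus = rMinus, p.value = p, n = n)
}

#' Bundled example accuracy table
#'
#' A small methods-by-datasets table of mean classification accuracies
#' (percent) for five streaming feature selectors on six datasets,
#' shipped with the package to demonstrate the Friedman and exact
#' Wilcoxon comparison protocol on realistic numbers.
#'
#' @return numeric matrix, 5 methods (rows M1..M5) x 6 datasets
#'   (columns D1..D6).
#' @export
exampleAccuracyTable <- function() {
  path <- system.file("extdata", "benchmark_accuracy.tsv",
                      package = "streamFS")
  tab <- read.delim(path, row.names = 1, check.names = FALSE)
  as.matrix(tab)
}
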