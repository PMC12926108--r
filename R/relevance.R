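# Conditional-independence relevance classification and Markov-blanket
# style redundancy pruning of a selected feature set.

encodeLabel <- function(y) {
  y <- as.factor(y)
  if (nlevels(y) == 2) as.numeric(y == levels(y)[2]) else as.numeric(y)
}

# Fisher-z partial-correlation test via QR regression residuals: robust
# to (near-)duplicated conditioning columns, where matrix inversion of
# the correlation matrix breaks down. A residual with essentially zero
# variance means the variable is fully explained by the conditioning
# set, hence conditionally independent of anything else.
fisherZTest <- function(x, y, Z = NULL, alpha = 0.05) {
  M <- length(x)
  q <- if (is.null(Z)) 0L else ncol(Z)
  if (M <= q + 3) stop("Fisher-z test needs M > |conditioning| + 3 samples")
  if (sd(x) < 1e-12 || sd(y) < 1e-12)
    stop("degenerate (constant) input column in conditional-independence test")
  if (q == 0L) {
    r <- cor(x, y)
  } else {
    dec <- qr(cbind(1, Z))
    rx <- qr.resid(dec, x)
    ry <- qr.resid(dec, y)
    if (sd(rx) < 1e-8 * sd(x) || sd(ry) < 1e-8 * sd(y)) {
      return(list(statistic = 0, p.value = 1))
    }
    r <- cor(rx, ry)
  }
  r <- max(min(r, 1 - 1e-12), -1 + 1e-12)
  z <- 0.5 * log((1 + r) / (1 - r)) * sqrt(M - q - 3)
  list(statistic = z, p.value = 2 * pnorm(-abs(z)))
}

# G^2 likelihood-ratio test on discretized values, used when the label
# has 3+ classes. Continuous variables are cut at their tertiles;
# conditioning columns define strata.
gSquaredTest <- function(x, y, Z = NULL, bins = 3L) {
  disc <- function(v) {
    if (is.factor(v) || length(unique(v)) <= bins) return(as.factor(v))
    br <- unique(quantile(v, probs = seq(0, 1, length.out = bins + 1)))
    if (length(br) < 2) stop("degenerate (constant) input column in conditional-independence test")
    cut(v, breaks = br, include.lowest = TRUE)
  }
  xf <- disc(x); yf <- as.factor(y)
  strata <- if (is.null(Z)) factor(rep(1, length(x)))
            else interaction(as.data.frame(lapply(as.data.frame(Z), disc)), drop = TRUE)
  g2 <- 0; df <- 0
  for (s in levels(strata)) {
    sel <- strata == s
    tab <- table(xf[sel], yf[sel])
    if (sum(tab) == 0) next
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    nz <- tab > 0
    g2 <- g2 + 2 * sum(tab[nz] * log(tab[nz] / e[nz]))
    df <- df + max(1L, (sum(rowSums(tab) > 0) - 1L) * (sum(colSums(tab) > 0) - 1L))
  }
  list(statistic = g2, p.value = pchisq(g2, df, lower.tail = FALSE))
}

#' Conditional-independence test
#'
#' Tests whether \code{x} and \code{y} are independent given the
#' conditioning columns, at level \code{alpha}. Continuous pairs (and
#' binary labels, numerically encoded) use Fisher's z transform of the
#' partial correlation; a label with three or more classes falls back to
#' a G-squared contingency test on tertile-discretized values.
#'
#' @param x numeric vector of length M.
#' @param y numeric vector or class labels of length M.
#' @param conditioning optional numeric matrix of conditioning columns
#'   (M rows), or \code{NULL}.
#' @param alpha significance level (default 0.05).
#' @return list of class \code{"ciTestResult"} with \code{statistic},
#'   \code{p.value}, \code{independent} (\code{p.value > alpha}) and
#'   \code{conditioningIds}.
#' @examples
#' x <- rnorm(200); ciTest(x, x + rnorm(200, sd = 0.1))$independent
#' @export
ciTest <- function(x, y, conditioning = NULL, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  Z <- if (!is.null(conditioning)) {
    Z <- as.matrix(conditioning)
    if (ncol(Z) == 0) NULL else Z
  }
  multiclass <- (is.factor(y) || is.character(y)) &&
    nlevels(as.factor(y)) > 2
  res <- if (multiclass) gSquaredTest(x, y, Z)
         else fisherZTest(x, if (is.factor(y) || is.character(y))
                               encodeLabel(y) else y, Z)
  structure(list(statistic = res$statistic, p.value = res$p.value,
                 independent = res$p.value > alpha,
                 conditioningIds = colnames(conditioning)),
            class = "ciTestResult")
}

subsetsUpTo <- function(items, d) {
  out <- list(integer(0))
  for (size in seq_len(min(d, length(items)))) {
    # combn(x, m) with scalar x would enumerate subsets of 1:x
    cmb <- if (length(items) == 1L) list(items)
           else combn(items, size, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

#' Classify the relevance of a candidate feature
#'
#' Tests the dependence of the candidate with the labels conditioned on
#' every subset of the selected columns up to size \code{maxCond}:
#' dependent under all tested subsets is strong relevance, under some
#' but not all is weak relevance, under none is irrelevance.
#'
#' @param candidate numeric column of length M.
#' @param labels class labels.
#' @param selected numeric matrix of currently selected columns (may
#'   have 0 columns).
#' @param alpha test level.
#' @param maxCond maximum conditioning-subset size d.
#' @return one of \code{"strong"}, \code{"weak"}, \code{"irrelevant"}.
#' @export
classifyRelevance <- function(candidate, labels, selected = NULL,
                              alpha = 0.05, maxCond = 3L) {
  selected <- if (is.null(selected)) matrix(nrow = length(candidate), ncol = 0)
              else as.matrix(selected)
  subs <- subsetsUpTo(seq_len(ncol(selected)), maxCond)
  dep <- vapply(subs, function(s) {
    Z <- if (length(s)) selected[, s, drop = FALSE] else NULL
    !ciTest(candidate, labels, Z, alpha)$independent
  }, logical(1))
  if (all(dep)) "strong" else if (any(dep)) "weak" else "irrelevant"
}

# TRUE when no conditioning subset (up to maxCond) of `others` shows
# dependence between candidate and labels; early exit at the first
# dependence keeps the common (relevant) case cheap.
isIrrelevant <- function(candidate, labels, others, alpha, maxCond) {
  for (s in subsetsUpTo(seq_len(ncol(others)), maxCond)) {
    Z <- if (length(s)) others[, s, drop = FALSE] else NULL
    if (!ciTest(candidate, labels, Z, alpha)$independent) return(FALSE)
  }
  TRUE
}

labelAssociation <- function(x, labels) {
  if (nlevels(as.factor(labels)) > 2) {
    gSquaredTest(x, labels)$statistic
  } else {
    abs(cor(x, encodeLabel(labels)))
  }
}

#' Redundancy pruning of a selected feature set
#'
#' Iterates the features in ascending order of unconditional association
#' with the label (weakest first) and removes a feature whenever some
#' subset of the remaining set, of size at most \code{maxCond}, renders
#' it conditionally independent of the label — the Markov-blanket
#' redundancy criterion. The operation is idempotent: a second pass over
#' its own output removes nothing (survivors were dependent under every
#' subset of a larger pool).
#'
#' For a feature and a near-duplicate of it, each renders the other
#' conditionally independent of the label, and the marginal-association
#' ordering that decides which is examined first is a near coin flip.
#' Such *mutually removable* pairs are therefore resolved by conditional
#' retention: when feature A is removable through the single feature B
#' and B is also removable through A, the one whose conditional
#' dependence on the label given the other is weaker (the larger
#' p-value) is the one removed.
#'
#' @param selected numeric matrix of selected columns, with column names
#'   as feature ids.
#' @param labels class labels.
#' @param alpha test level.
#' @param maxCond maximum conditioning-subset size d.
#' @return list with \code{kept} (pruned matrix), \code{keptIds} and
#'   \code{removedIds}.
#' @examples
#' x <- rnorm(100); y <- factor(x > 0)
#' S <- cbind(a = x, b = x)  # exact duplicate: one copy survives
#' redundancyPrune(S, y)$keptIds
#' @export
redundancyPrune <- function(selected, labels, alpha = 0.05, maxCond = 3L) {
  selected <- as.matrix(selected)
  if (ncol(selected) == 0)
    return(list(kept = selected, keptIds = character(0),
                removedIds = character(0)))
  ids <- colnames(selected)
  if (is.null(ids)) ids <- sprintf("f%04d", seq_len(ncol(selected)))
  assoc <- vapply(seq_len(ncol(selected)),
                  function(j) labelAssociation(selected[, j], labels),
                  numeric(1))
  order_ <- order(assoc)  # weakest association first
  keep <- rep(TRUE, ncol(selected))
  for (j in order_) {
    rest <- which(keep)
    rest <- rest[rest != j]
    if (length(rest) == 0) {
      # no candidate blanket: remove only if unconditionally independent
      if (ciTest(selected[, j], labels, NULL, alpha)$independent)
        keep[j] <- FALSE
      next
    }
    for (s in subsetsUpTo(rest, maxCond)) {
      Z <- if (length(s)) selected[, s, drop = FALSE] else NULL
      tj <- ciTest(selected[, j], labels, Z, alpha)
      if (tj$independent) {
        # mutual-removability check: if a member of the removing
        # blanket is itself removable with j swapped into its place,
        # and retains less label information (larger p), spare j — the
        # weaker member is removed when its own turn comes
        mutualWeaker <- FALSE
        for (z in s) {
          Zalt <- selected[, c(setdiff(s, z), j), drop = FALSE]
          tz <- ciTest(selected[, z], labels, Zalt, alpha)
          if (tz$independent && tz$p.value > tj$p.value) {
            mutualWeaker <- TRUE
            break
          }
        }
        if (mutualWeaker) next
        keep[j] <- FALSE
        break
      }
    }
  }
  list(kept = selected[, keep, drop = FALSE], keptIds = ids[keep],
       removedIds = ids[!keep])
}
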