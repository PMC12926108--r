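#' Initialize latent factors
#'
#' Every entry of U (M x L) and V (H x L) is drawn independently and
#' uniformly on \eqn{[0, 0.004)}: a small non-zero starting vicinity so
#' the multiplicative SGD updates can move in both directions.
#'
#' @param M number of samples (rows of U).
#' @param H number of features (rows of V).
#' @param L latent dimension, \code{1 <= L <= min(M, H)}.
#' @param seed integer seed; the same seed reproduces the same factors.
#' @return a [FactorPair-class].
#' @export
initFactors <- function(M, H, L, seed = 1L) {
  if (L < 1 || L > min(M, H))
    stop("latent dimension L must satisfy 1 <= L <= min(M, H)")
  withr::with_seed(deriveSeed(seed, "lfa-init"), {
    U <- matrix(runif(M * L, 0, 0.004), M, L)
    V <- matrix(runif(H * L, 0, 0.004), H, L)
  })
  FactorPair(U, V)
}

#' Training loss of a factor pair on a sparse block
#'
#' Sum over observed cells of half the squared residual plus, per
#' observed cell, \code{lambda/2 * (||u_m||^2 + ||v_j||^2)}. The
#' regularizer is charged once per observed cell, exactly as the
#' objective is written, not once per factor row; frequently observed
#' rows are therefore shrunk harder.
#'
#' @param fp a [FactorPair-class].
#' @param block a [SparseFeatureBlock-class] of matching shape.
#' @param lambda regularization coefficient (>= 0).
#' @return non-negative scalar loss.
#' @export
blockLoss <- function(fp, block, lambda = 0) {
  stopifnot(is(fp, "FactorPair"), is(block, "SparseFeatureBlock"))
  U <- fp@U; V <- fp@V
  if (nrow(U) != sampleCount(block) || nrow(V) != blockWidth(block))
    stop("factor and block shapes disagree")
  mask <- blockMask(block)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(0)
  recon <- tcrossprod(U, V)
  resid <- blockValues(block)[mask] - recon[mask]
  reg <- lambda / 2 *
    sum(rowSums(U^2)[idx[, 1]] + rowSums(V^2)[idx[, 2]])
  sum(0.5 * resid^2) + reg
}

#' One SGD update for a single observed cell
#'
#' Computes the residual \code{err = value - sum(u * v)} once from the
#' pre-update rows and updates both rows simultaneously:
#' \code{u + eta * (v * err - lambda * u)} and symmetrically for
#' \code{v}. With \code{err = 0} and \code{lambda > 0} this reduces to
#' pure shrinkage by \code{(1 - eta * lambda)}.
#'
#' @param u,v length-L factor rows.
#' @param value the observed cell value.
#' @param eta learning rate.
#' @param lambda regularization coefficient.
#' @return list with updated rows \code{u} and \code{v} and the residual
#'   \code{err}.
#' @export
sgdUpdateCell <- function(u, v, value, eta, lambda = 0) {
  stopifnot(length(u) == length(v), is.finite(value))
  err <- value - sum(u * v)
  list(u = u + eta * (v * err - lambda * u),
       v = v + eta * (u * err - lambda * v),
       err = err)
}

#' Train latent factors on a sparse block by SGD
#'
#' Each epoch visits every observed cell once, in a seed-controlled
#' shuffled order, applying [sgdUpdateCell()]. Training stops at
#' \code{maxEpochs} or when the relative change of the full training
#' loss (see [blockLoss()]) drops below \code{relTol}.
#'
#' @param block a [SparseFeatureBlock-class] with at least one observed
#'   cell.
#' @param params an [lfaParams()] object.
#' @return list with elements \code{factors} (a [FactorPair-class]) and
#'   \code{trajectory} (the per-epoch loss sequence).
#' @examples
#' blk <- injectMCAR(tcrossprod(rnorm(30), rnorm(10)), 0.3, seed = 7)
#' fit <- trainFactors(blk, lfaParams(L = 1, seed = 7))
#' tail(fit$trajectory, 1) < fit$trajectory[1]
#' @export
trainFactors <- function(block, params = lfaParams()) {
  stopifnot(is(block, "SparseFeatureBlock"), inherits(params, "LfaParams"))
  mask <- blockMask(block)
  obs <- which(mask, arr.ind = TRUE)
  if (nrow(obs) == 0L) stop("cannot train factors: block has no observed cells")
  M <- sampleCount(block); H <- blockWidth(block)
  fp0 <- initFactors(M, H, params$L, params$seed)
  fit <- sgd_train_cpp(blockValues(block),
                       obs[, 1] - 1L, obs[, 2] - 1L,
                       fp0@U, fp0@V,
                       params$eta, params$lambda,
                       params$maxEpochs, params$relTol,
                       deriveSeed(params$seed, "lfa-shuffle"))
  if (fit$diverged)
    stop(sprintf(
      "SGD diverged (non-finite loss); reduce the learning rate eta = %g",
      params$eta))
  list(factors = FactorPair(fit$U, fit$V), trajectory = as.numeric(fit$loss))
}

#' Complete a sparse block from trained factors
#'
#' Observed cells are copied through unchanged; unobserved cells are set
#' to the inner product \code{sum_k U[m, k] * V[j, k]}. The result has
#' no missing values.
#'
#' @param block a [SparseFeatureBlock-class].
#' @param fp a [FactorPair-class] of matching shape.
#' @return dense numeric M x H matrix with the block's feature ids as
#'   column names.
#' @export
completeBlock <- function(block, fp) {
  stopifnot(is(block, "SparseFeatureBlock"), is(fp, "FactorPair"))
  if (nrow(fp@U) != sampleCount(block) || nrow(fp@V) != blockWidth(block))
    stop("factor and block shapes disagree")
  out <- tcrossprod(fp@U, fp@V)
  mask <- blockMask(block)
  out[mask] <- blockValues(block)[mask]
  colnames(out) <- featureIds(block)
  out
}

#' Impute a sparse block (train + complete)
#'
#' Convenience wrapper: trains factors on the observed cells and returns
#' the completed matrix. Fully observed blocks are returned as-is
#' (completion preserves observed cells, so training is skipped).
#'
#' @inheritParams trainFactors
#' @return dense numeric M x H matrix.
#' @export
imputeBlock <- function(block, params = lfaParams()) {
  if (all(blockMask(block))) {
    out <- blockValues(block)
    colnames(out) <- featureIds(block)
    return(out)
  }
  completeBlock(block, trainFactors(block, params)$factors)
}
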