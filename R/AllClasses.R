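#' SparseFeatureBlock: a buffered block of streamed feature columns
#'
#' An M x H block of feature values together with an observation mask.
#' Cells where the mask is \code{FALSE} are unobserved and stored as
#' \code{NA}, so no consumer can accidentally read them; the observed-cell
#' index set is the block's \eqn{\Lambda}.
#'
#' @slot values numeric matrix, M samples x H features; \code{NA} where
#'   unobserved.
#' @slot mask logical matrix of the same shape; \code{TRUE} = observed.
#' @slot featureIds character vector of H global feature identifiers in
#'   arrival order.
#'
#' @seealso [bufferStream()], [missingRate()], [completeBlock()]
#' @export
setClass("SparseFeatureBlock",
  representation(values = "matrix", mask = "matrix", featureIds = "character"))

setValidity("SparseFeatureBlock", function(object) {
  v <- object@values; m <- object@mask
  if (!is.numeric(v)) return("values must be numeric")
  if (!is.logical(m)) return("mask must be logical")
  if (!identical(dim(v), dim(m))) return("values and mask must have identical shape")
  if (length(object@featureIds) != ncol(v))
    return("featureIds length must equal block width")
  if (anyDuplicated(object@featureIds)) return("featureIds must be unique")
  if (any(is.na(m))) return("mask must not contain NA")
  if (any(is.na(v[m]))) return("observed cells must not be NA")
  if (any(!is.finite(v[m]))) return("observed cells must be finite")
  if (any(!is.na(v[!m]))) return("unobserved cells must be stored as NA")
  TRUE
})

#' Construct a SparseFeatureBlock
#'
#' @param values numeric matrix (samples x features); \code{NA} marks
#'   missing entries when \code{mask} is not given.
#' @param mask logical matrix, \code{TRUE} = observed. Defaults to
#'   \code{!is.na(values)}.
#' @param featureIds character ids, one per column; defaults to column
#'   names or \code{"f0001"}-style ids.
#' @return a [SparseFeatureBlock-class] object.
#' @examples
#' b <- SparseFeatureBlock(matrix(c(1, NA, 3, 4), 2, 2))
#' missingRate(b)
#' @export
SparseFeatureBlock <- function(values, mask = NULL, featureIds = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(mask)) mask <- !is.na(values)
  mask <- as.matrix(mask)
  if (!identical(dim(values), dim(mask)))
    stop("values and mask must have identical shape")
  if (is.null(featureIds)) {
    featureIds <- colnames(values)
    if (is.null(featureIds))
      featureIds <- sprintf("f%04d", seq_len(ncol(values)))
  }
  values[!mask] <- NA_real_
  dimnames(values) <- NULL
  dimnames(mask) <- NULL
  new("SparseFeatureBlock", values = values, mask = mask,
      featureIds = as.character(featureIds))
}

#' FactorPair: latent factor matrices approximating a block
#'
#' Sample factors U (M x L) and feature factors V (H x L) give the rank-L
#' reconstruction \eqn{UV^T} of a sparse block.
#'
#' @slot U numeric matrix of sample factors, M x L.
#' @slot V numeric matrix of feature factors, H x L.
#' @seealso [initFactors()], [trainFactors()], [completeBlock()]
#' @export
setClass("FactorPair", representation(U = "matrix", V = "matrix"))

setValidity("FactorPair", function(object) {
  if (ncol(object@U) != ncol(object@V))
    return("U and V must share the latent dimension L")
  L <- ncol(object@U)
  if (L < 1) return("latent dimension L must be >= 1")
  if (L > min(nrow(object@U), nrow(object@V)))
    return("latent dimension L must be <= min(M, H)")
  if (any(!is.finite(object@U)) || any(!is.finite(object@V)))
    return("factor entries must be finite")
  TRUE
})

#' Construct a FactorPair
#' @param U numeric M x L matrix of sample factors.
#' @param V numeric H x L matrix of feature factors.
#' @return a [FactorPair-class] object.
#' @export
FactorPair <- function(U, V) {
  new("FactorPair", U = as.matrix(U), V = as.matrix(V))
}

#' SelectionState: the evolving selected-feature set of a streaming run
#'
#' Holds the selected feature ids after the last processed block, their
#' completed column values (so later blocks can pool them with new
#' arrivals), the per-block processing history including each block's GA
#' convergence curve, and the total number of features seen.
#'
#' @slot selectedIds character vector of selected global feature ids.
#' @slot selectedValues numeric matrix (M x length(selectedIds)) of the
#'   completed values of the selected features.
#' @slot history list of per-block records (block index, candidate count,
#'   convergence curve, pruned ids, post-prune size, missing rate).
#' @slot totalSeen integer, cumulative number of streamed features.
#' @slot masterSeed numeric, seed the run was executed under.
#' @seealso [processStream()], [selectedFeatures()], [selectionHistory()]
#' @export
setClass("SelectionState",
  representation(selectedIds = "character", selectedValues = "matrix",
                 history = "list", totalSeen = "integer",
                 masterSeed = "numeric"))

setValidity("SelectionState", function(object) {
  if (ncol(object@selectedValues) != length(object@selectedIds))
    return("selectedValues must have one column per selected id")
  for (rec in object@history) {
    cc <- rec$convergence
    if (!is.null(cc) && length(cc) > 1 && any(diff(cc) > 1e-12))
      return("per-block convergence curves must be non-increasing")
  }
  TRUE
})

#' @describeIn SparseFeatureBlock-class number of samples M.
#' @param object a SparseFeatureBlock.
#' @export
setGeneric("sampleCount", function(object) standardGeneric("sampleCount"))
#' @rdname SparseFeatureBlock-class
#' @export
setMethod("sampleCount", "SparseFeatureBlock", function(object) nrow(object@values))

#' @describeIn SparseFeatureBlock-class block width H.
#' @export
setGeneric("blockWidth", function(object) standardGeneric("blockWidth"))
#' @rdname SparseFeatureBlock-class
#' @export
setMethod("blockWidth", "SparseFeatureBlock", function(object) ncol(object@values))

#' @describeIn SparseFeatureBlock-class value matrix (NA where unobserved).
#' @export
setGeneric("blockValues", function(object) standardGeneric("blockValues"))
#' @rdname SparseFeatureBlock-class
#' @export
setMethod("blockValues", "SparseFeatureBlock", function(object) object@values)

#' @describeIn SparseFeatureBlock-class logical observation mask.
#' @export
setGeneric("blockMask", function(object) standardGeneric("blockMask"))
#' @rdname SparseFeatureBlock-class
#' @export
setMethod("blockMask", "SparseFeatureBlock", function(object) object@mask)

#' @describeIn SparseFeatureBlock-class feature identifiers in arrival order.
#' @export
setGeneric("featureIds", function(object) standardGeneric("featureIds"))
#' @rdname SparseFeatureBlock-class
#' @export
setMethod("featureIds", "SparseFeatureBlock", function(object) object@featureIds)

#' Missing rate of a sparse block or a single column
#'
#' For a block, the fraction of unobserved cells among all M x H cells,
#' \eqn{\rho = 1 - |\Lambda| / (M H)}; for a single numeric column
#' (\code{NA} = missing), the per-column rate \eqn{1 - |\Lambda| / M}.
#'
#' @param object a [SparseFeatureBlock-class] or a numeric vector.
#' @return missing rate in \eqn{[0, 1]}.
#' @examples
#' missingRate(SparseFeatureBlock(matrix(c(1, NA, 3, 4), 2, 2)))
#' missingRate(c(1, NA, 2, NA))
#' @export
setGeneric("missingRate", function(object) standardGeneric("missingRate"))

#' @rdname missingRate
#' @export
setMethod("missingRate", "SparseFeatureBlock", function(object) {
  n <- length(object@mask)
  if (n == 0L) stop("missing rate of a zero-cell block is undefined")
  1 - sum(object@mask) / n
})

#' @rdname missingRate
#' @export
setMethod("missingRate", "numeric", function(object) {
  if (length(object) == 0L) stop("missing rate of an empty column is undefined")
  mean(is.na(object))
})

#' @describeIn FactorPair-class latent dimension L.
#' @param object a FactorPair.
#' @export
setGeneric("latentDim", function(object) standardGeneric("latentDim"))
#' @rdname FactorPair-class
#' @export
setMethod("latentDim", "FactorPair", function(object) ncol(object@U))

#' @describeIn SelectionState-class ids of the currently selected features.
#' @param object a SelectionState.
#' @export
setGeneric("selectedFeatures", function(object) standardGeneric("selectedFeatures"))
#' @rdname SelectionState-class
#' @export
setMethod("selectedFeatures", "SelectionState", function(object) object@selectedIds)

#' @describeIn SelectionState-class per-block processing records.
#' @export
setGeneric("selectionHistory", function(object) standardGeneric("selectionHistory"))
#' @rdname SelectionState-class
#' @export
setMethod("selectionHistory", "SelectionState", function(object) object@history)

#' @describeIn SelectionState-class list of per-block GA convergence curves.
#' @export
setGeneric("convergenceCurves", function(object) standardGeneric("convergenceCurves"))
#' @rdname SelectionState-class
#' @export
setMethod("convergenceCurves", "SelectionState",
          function(object) lapply(object@history, `[[`, "convergence"))

setMethod("show", "SparseFeatureBlock", function(object) {
  cat(sprintf("SparseFeatureBlock: %d samples x %d features, %.1f%% missing\n",
              sampleCount(object), blockWidth(object),
              100 * missingRate(object)))
  cat("  ids:", paste(head(object@featureIds, 6), collapse = ", "),
      if (blockWidth(object) > 6) "..." else "", "\n")
})

setMethod("show", "FactorPair", function(object) {
  cat(sprintf("FactorPair: U %d x %d, V %d x %d\n",
              nrow(object@U), ncol(object@U), nrow(object@V), ncol(object@V)))
})

setMethod("show", "SelectionState", function(object) {
  cat(sprintf(
    "SelectionState: %d features selected of %d seen over %d blocks\n",
    length(object@selectedIds), object@totalSeen, length(object@history)))
  cat("  selected:", paste(head(object@selectedIds, 8), collapse = ", "),
      if (length(object@selectedIds) > 8) "..." else "", "\n")
})
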