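# Synthetic sparse feature streams with planted ground truth.

#' Hide cells completely at random
#'
#' Each cell of the matrix is hidden independently with probability
#' \code{rho}, independent of its value (MCAR). Observed cells keep
#' their input values exactly.
#'
#' @param values numeric matrix.
#' @param rho hiding probability in \eqn{[0, 1)}.
#' @param seed integer seed; the same seed reproduces the same mask.
#' @return a [SparseFeatureBlock-class].
#' @export
injectMCAR <- function(values, rho, seed = 1L) {
  stopifnot(rho >= 0, rho < 1)
  values <- as.matrix(values)
  mask <- withr::with_seed(deriveSeed(seed, "mcar"),
    matrix(runif(length(values)) >= rho, nrow(values), ncol(values)))
  SparseFeatureBlock(values, mask, featureIds = colnames(values))
}

#' Generate a synthetic sparse feature stream with known ground truth
#'
#' Draws an M x rank latent sample matrix A (standard normal). Every
#' feature column is \code{A \%*\% w + noiseSd * noise}, so the full
#' matrix is approximately rank \code{rank} — the structural premise the
#' latent-factor completion step relies on. Informative features load on
#' distinct latent directions and the labels are the sign of their
#' weighted sum (or the exclusive-or of two thresholded informative
#' columns); redundant features are noisy scaled duplicates of single
#' informative columns (linearly dependent on them up to noise); noise
#' features load only on the latent directions beyond the informative
#' subspace, hence orthogonal to the label direction and jointly
#' uninformative about the labels. An MCAR mask
#' hides each cell with probability \code{missingRate}, and the columns
#' are streamed in a shuffled arrival order and buffered into blocks of
#' width \code{bufferWidth}.
#'
#' @param spec a [syntheticStreamSpec()].
#' @return list with \code{blocks} (list of [SparseFeatureBlock-class]),
#'   \code{labels} (factor), \code{values} (the complete M x T matrix
#'   before masking, columns in arrival order), and \code{truth} (data
#'   frame: feature \code{id}, \code{role} in
#'   \{informative, redundant, noise\}, arrival \code{position}).
#' @examples
#' sim <- generateStream(syntheticStreamSpec(M = 30, totalFeatures = 10,
#'   rank = 3, nInformative = 2, nRedundant = 2, missingRate = 0.2, seed = 1))
#' table(sim$truth$role)
#' @export
generateStream <- function(spec) {
  stopifnot(inherits(spec, "SyntheticStreamSpec"))
  M <- spec$M; Tn <- spec$totalFeatures
  nI <- spec$nInformative; nR <- spec$nRedundant; nN <- spec$nNoise

  gen <- withr::with_seed(deriveSeed(spec$seed, "synth"), {
    A <- matrix(rnorm(M * spec$rank), M, spec$rank)
    noise <- function(n = M) spec$noiseSd * rnorm(n)

    inf <- matrix(sapply(seq_len(nI), function(j) A[, j] + noise()),
                  nrow = M)
    labWeights <- runif(nI, 0.8, 1.2)
    labels <- if (spec$labelModel == "linear-threshold") {
      factor(ifelse(c(inf %*% labWeights) > 0, "pos", "neg"))
    } else {
      a <- inf[, 1] > median(inf[, 1]); b <- inf[, 2] > median(inf[, 2])
      factor(ifelse(xor(a, b), "pos", "neg"))
    }

    # noisy scaled duplicates: each redundant feature copies one
    # informative column, so its label association is slightly weaker
    # than its parent's and Markov-blanket pruning has a well-defined
    # feature to remove
    red <- if (nR > 0) matrix(sapply(seq_len(nR), function(j) {
      src <- if (nI == 1) 1L else 1L + (j - 1L) %% nI
      runif(1, 0.5, 1.5) * inf[, src] + noise()
    }), nrow = M) else matrix(nrow = M, ncol = 0)

    # noise features load only on the latents beyond the informative
    # subspace (latents nI+1..rank), so they are label-independent both
    # individually and jointly; when no extra latents exist they are
    # pure iid noise columns
    nExtra <- spec$rank - nI
    noi <- if (nN > 0) matrix(sapply(seq_len(nN), function(j) {
      if (nExtra == 0) return(rnorm(M))
      w <- rnorm(nExtra)
      w <- w / sqrt(sum(w^2))
      c(A[, nI + seq_len(nExtra), drop = FALSE] %*% w) + noise()
    }), nrow = M) else matrix(nrow = M, ncol = 0)

    roles <- c(rep("informative", nI), rep("redundant", nR), rep("noise", nN))
    values <- cbind(inf, red, noi)
    arrival <- sample.int(Tn)
    list(values = values[, arrival, drop = FALSE],
         roles = roles[arrival], labels = labels)
  })

  ids <- sprintf("f%03d", seq_len(Tn))
  colnames(gen$values) <- ids
  masked <- injectMCAR(gen$values, spec$missingRate,
                       seed = deriveSeed(spec$seed, "mask"))
  blocks <- bufferStream(blockValues(masked), spec$bufferWidth,
                         featureIds = ids)
  list(blocks = blocks, labels = gen$labels, values = gen$values,
       truth = data.frame(id = ids, role = gen$roles,
                          position = seq_len(Tn)))
}
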