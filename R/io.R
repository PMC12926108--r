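# Delimited-matrix readers and JSON run reports.

#' Read a delimited feature matrix with missing-value markers
#'
#' Reads a rectangular delimited numeric matrix, maps missing-value
#' markers (empty cell, \code{NA}, \code{NaN} by default) to unobserved
#' mask cells, and normalizes the orientation to samples x features.
#'
#' @param path file path.
#' @param sep field delimiter (default comma).
#' @param header whether the first row holds feature ids; when absent,
#'   ids are synthesized as \code{"f0001"}, ...
#' @param orientation \code{"samples"} when rows are samples (default)
#'   or \code{"features"} when rows are features (the matrix is then
#'   transposed).
#' @param naStrings missing-value markers.
#' @return list with \code{values} (numeric matrix, \code{NA} where
#'   missing), \code{mask} (logical) and \code{featureIds}.
#' @export
readMatrix <- function(path, sep = ",", header = TRUE,
                       orientation = c("samples", "features"),
                       naStrings = c("", "NA", "NaN")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- count.fields(path, sep = sep)
  if (length(unique(nf)) > 1)
    stop(sprintf("ragged rows in %s: line %d has %d fields, expected %d",
                 path, which(nf != nf[1])[1], nf[nf != nf[1]][1], nf[1]))
  df <- read.csv(path, sep = sep, header = header,
                 na.strings = naStrings, check.names = FALSE)
  values <- as.matrix(df)
  if (!is.numeric(values)) stop("matrix contains non-numeric entries")
  storage.mode(values) <- "double"
  if (orientation == "features") values <- t(values)
  ids <- colnames(values)
  if (is.null(ids) || !header)
    ids <- sprintf("f%04d", seq_len(ncol(values)))
  dimnames(values) <- NULL
  list(values = values, mask = !is.na(values), featureIds = ids)
}

#' Write a JSON run report for a streaming selection run
#'
#' Persists the selected ids, the per-block history (candidate counts,
#' convergence curves, pruned ids), all configuration parameters, the
#' master seed and the package version; reading the report back with
#' [readRunReport()] reproduces the selected set exactly.
#'
#' @param state a [SelectionState-class] from [processStream()].
#' @param config the [streamConfig()] the run used.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeRunReport <- function(state, config, path) {
  stopifnot(is(state, "SelectionState"), inherits(config, "StreamConfig"))
  report <- list(
    software = list(package = "streamFS",
                    version = as.character(packageVersion("streamFS"))),
    masterSeed = state@masterSeed,
    selected = selectedFeatures(state),
    totalSeen = state@totalSeen,
    history = selectionHistory(state),
    config = lapply(unclass(config),
                    function(x) if (is.list(x)) unclass(x) else x))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read back a JSON run report
#'
#' @param path path written by [writeRunReport()].
#' @return the parsed report list; \code{$selected} holds the selected
#'   feature ids.
#' @export
readRunReport <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE,
                      simplifyDataFrame = FALSE)
}
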