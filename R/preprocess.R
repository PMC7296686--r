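#' Remove features with any missing value
#'
#' Heterogeneous cohorts often miss a feature in a handful of subjects; no
#' imputation is attempted — a feature column is kept only if it is observed
#' in every sample.  The sample set is never changed and column order is
#' preserved.
#'
#' @param X a \linkS4class{FeatureMatrix}.
#' @return a \linkS4class{FeatureMatrix} with complete columns only.
#' @export
dropIncompleteFeatures <- function(X) {
  stopifnot(is(X, "FeatureMatrix"))
  keep <- colSums(is.na(X@values)) == 0L
  if (!any(keep))
    stop("empty matrix: every feature has at least one missing value")
  new("FeatureMatrix", values = X@values[, keep, drop = FALSE])
}

#' Fit per-feature min-max scaling statistics
#'
#' Learns the per-column minimum and maximum on the (training) matrix so the
#' same affine map can later be applied to held-out samples without leaking
#' their statistics.  A constant (degenerate) column is mapped to the range
#' midpoint.
#'
#' @param X complete \linkS4class{FeatureMatrix}.
#' @param lo,hi target range, default [-1, 1].
#' @return an object of class \code{minmaxScaler} for
#'   \code{\link{applyScaler}}.
#' @export
fitScaler <- function(X, lo = -1, hi = 1) {
  stopifnot(is(X, "FeatureMatrix"), !anyNA(X@values), lo < hi)
  structure(list(min = apply(X@values, 2, min),
                 max = apply(X@values, 2, max),
                 lo = lo, hi = hi,
                 featureIds = colnames(X@values)),
            class = "minmaxScaler")
}

#' Apply fitted min-max scaling
#'
#' Maps each column by \eqn{x \mapsto lo + (hi-lo)(x - min)/(max - min)}
#' using the statistics learned by \code{\link{fitScaler}}.  Values of new
#' samples falling outside the training range are clipped into [lo, hi];
#' degenerate training columns map to the range midpoint.
#'
#' @param scaler a \code{minmaxScaler}.
#' @param X \linkS4class{FeatureMatrix} with the scaler's feature columns.
#' @return rescaled \linkS4class{FeatureMatrix}.
#' @export
applyScaler <- function(scaler, X) {
  stopifnot(inherits(scaler, "minmaxScaler"), is(X, "FeatureMatrix"))
  if (!identical(colnames(X@values), scaler$featureIds))
    stop("feature columns do not match the fitted scaler")
  rng <- scaler$max - scaler$min
  mid <- (scaler$lo + scaler$hi) / 2
  v <- X@values
  out <- v
  const <- rng == 0
  span <- scaler$hi - scaler$lo
  if (any(!const)) {
    j <- which(!const)
    out[, j] <- sweep(sweep(v[, j, drop = FALSE], 2, scaler$min[j]),
                      2, rng[j], "/") * span + scaler$lo
  }
  if (any(const)) out[, const] <- mid
  out[out < scaler$lo] <- scaler$lo
  out[out > scaler$hi] <- scaler$hi
  new("FeatureMatrix", values = out)
}

#' Min-max rescale a feature matrix
#'
#' Convenience wrapper: fit the scaler on \code{X} itself and apply it, so
#' each column's minimum maps to \code{lo} and maximum to \code{hi}.  Use
#' \code{\link{fitScaler}}/\code{\link{applyScaler}} in holdout protocols.
#'
#' @inheritParams fitScaler
#' @return rescaled \linkS4class{FeatureMatrix}.
#' @examples
#' X <- FeatureMatrix(matrix(c(0, 5, 10), 3, 1))
#' values(minmaxRescale(X))   # -1, 0, 1
#' @export
minmaxRescale <- function(X, lo = -1, hi = 1) {
  applyScaler(fitScaler(X, lo, hi), X)
}

#' Read / write delimited feature matrices
#'
#' Plain delimited text: first row holds feature ids, first column sample
#' ids; an empty cell or \code{NA} denotes a missing value.  The separator
#' is inferred from the file extension (.csv comma, otherwise tab) unless
#' given.
#'
#' @param path file path.
#' @param sep field separator; inferred when NULL.
#' @return \code{readFeatureMatrix}: a \linkS4class{FeatureMatrix}.
#' @export
readFeatureMatrix <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, na.strings = c("NA", ""),
                          comment.char = "")
  FeatureMatrix(as.matrix(df))
}

#' @rdname readFeatureMatrix
#' @param X a \linkS4class{FeatureMatrix} to write.
#' @export
writeFeatureMatrix <- function(X, path, sep = NULL) {
  stopifnot(is(X, "FeatureMatrix"))
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- data.frame(sample_id = rownames(X@values), X@values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a label table
#'
#' Two-column delimited table: sample id, class label (header optional but
#' recommended: \code{sample_id, label}).
#'
#' @param path file path.
#' @param sep separator, inferred from extension when NULL.
#' @return named character vector of labels, names = sample ids.
#' @export
readLabels <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop("label table must have two columns: sample id, label")
  stats::setNames(df[[2]], df[[1]])
}
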