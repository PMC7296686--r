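#' Construct a FeatureMatrix
#'
#' @param values numeric matrix (samples x features).
#' @param sampleIds,featureIds optional ids; taken from dimnames when absent,
#'   generated (\code{s1..}, \code{f1..}) when neither is available.
#' @return a \linkS4class{FeatureMatrix}.
#' @export
FeatureMatrix <- function(values, sampleIds = NULL, featureIds = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.null(sampleIds)) rownames(values) <- sampleIds
  if (!is.null(featureIds)) colnames(values) <- featureIds
  if (is.null(rownames(values)))
    rownames(values) <- paste0("s", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("f", seq_len(ncol(values)))
  new("FeatureMatrix", values = values)
}

#' @rdname FeatureMatrix
#' @param x a FeatureMatrix (or other object with a values slot).
#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' @rdname FeatureMatrix
#' @export
setMethod("values", "FeatureMatrix", function(x) x@values)

#' @rdname FeatureMatrix
#' @export
setMethod("values", "RegionMeasureTable", function(x) x@values)

#' @rdname FeatureMatrix
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname FeatureMatrix
#' @export
setMethod("sampleIds", "FeatureMatrix", function(x) rownames(x@values))

#' @rdname FeatureMatrix
#' @export
setMethod("sampleIds", "KernelStack", function(x) x@sampleIds)

#' @rdname FeatureMatrix
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @rdname FeatureMatrix
#' @export
setMethod("featureIds", "FeatureMatrix", function(x) colnames(x@values))

#' Missing-cell mask of a FeatureMatrix
#'
#' @param x a \linkS4class{FeatureMatrix}.
#' @return logical matrix, TRUE where the cell is missing.
#' @export
missingMask <- function(x) is.na(x@values)

setMethod("show", "FeatureMatrix", function(object) {
  v <- object@values
  cat(sprintf("FeatureMatrix: %d samples x %d features (%d missing cells)\n",
              nrow(v), ncol(v), sum(is.na(v))))
  if (length(v))
    cat(sprintf("  range: [%.4g, %.4g]\n", min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
})

#' Construct a RegionMeasureTable
#'
#' @param values subjects x regions numeric matrix, complete.
#' @param measureName measure label, e.g. "CGMV" or "CT".
#' @param subjectIds,regionIds optional ids; generated when absent.
#' @return a \linkS4class{RegionMeasureTable}.
#' @export
RegionMeasureTable <- function(values, measureName = "measure",
                               subjectIds = NULL, regionIds = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.null(subjectIds)) rownames(values) <- subjectIds
  if (!is.null(regionIds)) colnames(values) <- regionIds
  if (is.null(rownames(values)))
    rownames(values) <- paste0("s", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("r", seq_len(ncol(values)))
  new("RegionMeasureTable", values = values, measureName = measureName)
}

setMethod("show", "RegionMeasureTable", function(object) {
  cat(sprintf("RegionMeasureTable '%s': %d subjects x %d regions\n",
              object@measureName, nrow(object@values), ncol(object@values)))
})

#' Construct a KernelSpec
#'
#' @param family kernel family: gaussian, polynomial, linear or sigmoid.
#' @param ... family parameters (gaussian: sigma; polynomial: degree, offset;
#'   linear: offset; sigmoid: alpha, offset).  Conventional defaults are
#'   filled in for omitted offsets (polynomial offset 1, linear/sigmoid
#'   offset 0).
#' @return a \linkS4class{KernelSpec}.
#' @export
KernelSpec <- function(family = c("gaussian", "polynomial", "linear", "sigmoid"),
                       ...) {
  family <- match.arg(family)
  params <- list(...)
  defaults <- switch(family,
    gaussian   = list(),
    polynomial = list(degree = 2, offset = 1),
    linear     = list(offset = 0),
    sigmoid    = list(offset = 0))
  for (nm in names(defaults))
    if (is.null(params[[nm]])) params[[nm]] <- defaults[[nm]]
  new("KernelSpec", family = family, params = params)
}

setMethod("show", "KernelSpec", function(object) {
  p <- paste(names(object@params),
             vapply(object@params, format, ""), sep = "=", collapse = ", ")
  cat(sprintf("KernelSpec: %s(%s)\n", object@family, p))
})

#' KernelStack accessors
#'
#' @param x a \linkS4class{KernelStack}.
#' @return \code{kernelMatrices}: the list of kernel matrices;
#'   \code{nKernels}: their number M; \code{viewIds}: the originating views.
#' @export
kernelMatrices <- function(x) x@kernels

#' @rdname kernelMatrices
#' @export
nKernels <- function(x) length(x@kernels)

#' @rdname kernelMatrices
#' @export
setGeneric("viewIds", function(x) standardGeneric("viewIds"))

#' @rdname kernelMatrices
#' @export
setMethod("viewIds", "KernelStack", function(x) x@viewIds)

#' @rdname kernelMatrices
#' @export
setMethod("viewIds", "MKLDRModel", function(x) x@viewIds)

setMethod("show", "KernelStack", function(object) {
  cat(sprintf("KernelStack: M = %d kernels over N = %d samples\n",
              length(object@kernels), length(object@sampleIds)))
  fams <- vapply(object@specs, function(s) s@family, "")
  for (f in unique(fams))
    cat(sprintf("  %s: %d\n", f, sum(fams == f)))
})

#' ChainOrder accessors
#'
#' @param x a \linkS4class{ChainOrder}.
#' @return \code{totalCost}: the minimal scalar-multiplication count
#'   \eqn{F(1, n)}; \code{splitTable}: the argmin split points.
#' @export
totalCost <- function(x) x@totalCost

#' @rdname totalCost
#' @export
splitTable <- function(x) x@splitTable

setMethod("show", "ChainOrder", function(object) {
  cat(sprintf("ChainOrder over %d matrices (dims %s): minimal cost %s\n",
              length(object@dims) - 1L, paste(object@dims, collapse = "x"),
              format(object@totalCost, big.mark = ",")))
})

#' MKLDRModel accessors
#'
#' @param x a trained \linkS4class{MKLDRModel}.
#' @return \code{sampleCoefs}: the N x P sample-coefficient matrix A;
#'   \code{kernelWeights}: the length-M kernel weight vector beta;
#'   \code{viewWeights}: beta aggregated per originating view (sum of
#'   squared weights, so the per-view shares sum to 1);
#'   \code{reducedDim}: the embedding dimension P.
#' @export
sampleCoefs <- function(x) x@A

#' @rdname sampleCoefs
#' @export
kernelWeights <- function(x) x@beta

#' @rdname sampleCoefs
#' @export
viewWeights <- function(x) {
  w <- tapply(x@beta^2, factor(x@viewIds, levels = unique(x@viewIds)), sum)
  w <- as.vector(w)
  names(w) <- unique(x@viewIds)
  w
}

#' @rdname sampleCoefs
#' @export
reducedDim <- function(x) x@P

setMethod("show", "MKLDRModel", function(object) {
  cat(sprintf("MKLDRModel: N = %d training samples, M = %d kernels, P = %d\n",
              nrow(object@A), length(object@beta), object@P))
  vw <- viewWeights(object)
  cat("  view weights:",
      paste(sprintf("%s=%.3f", names(vw), vw), collapse = " "), "\n")
  if (nrow(object@history))
    cat(sprintf("  final objective: %.6g after %d iterations\n",
                utils::tail(object@history$objective, 1), nrow(object@history)))
})

#' Construct a SplitScheme
#'
#' @param trainFraction fraction of samples used for training (default 2/3).
#' @param nReps number of random repetitions (default 20).
#' @param seed integer seed.
#' @return a \linkS4class{SplitScheme}.
#' @export
SplitScheme <- function(trainFraction = 2 / 3, nReps = 20L, seed = 1L) {
  new("SplitScheme", trainFraction = trainFraction,
      nReps = as.integer(nReps), seed = as.integer(seed))
}

#' EvalReport accessors
#'
#' @param x an \linkS4class{EvalReport}.
#' @return \code{perRepetition}: data.frame of per-repetition accuracy/AUC;
#'   \code{bestAccuracy}, \code{meanAccuracy}, \code{ciLower}: summary
#'   numbers; \code{rocPoints}: (fpr, tpr) of the best repetition.
#' @export
perRepetition <- function(x) x@perRep

#' @rdname perRepetition
#' @export
bestAccuracy <- function(x) x@bestAccuracy

#' @rdname perRepetition
#' @export
meanAccuracy <- function(x) x@meanAccuracy

#' @rdname perRepetition
#' @export
ciLower <- function(x) x@ciLower

#' @rdname perRepetition
#' @export
rocPoints <- function(x) x@rocPoints

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: %d repetitions\n", object@nReps))
  cat(sprintf("  mean accuracy: %.4f   best: %.4f\n",
              object@meanAccuracy, object@bestAccuracy))
  cat(sprintf("  lower %.0f%% confidence bound of mean: %.4f\n",
              100 * object@level, object@ciLower))
  if (nrow(object@perRep) && !all(is.na(object@perRep$auc)))
    cat(sprintf("  mean AUC: %.4f\n", mean(object@perRep$auc, na.rm = TRUE)))
})
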