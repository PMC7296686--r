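#' @import methods
NULL

#' FeatureMatrix: a samples-by-features view
#'
#' A real-valued matrix of one data view (e.g. one omic assay, or the vertex
#' or edge features of an ROI network), with unique sample identifiers as row
#' names and unique feature identifiers as column names.  Missing cells are
#' stored as \code{NA}; \code{\link{missingMask}} exposes them as a logical
#' matrix.  After preprocessing (\code{\link{dropIncompleteFeatures}} then
#' \code{\link{minmaxRescale}}) the matrix is complete and every column lies
#' in the target range.
#'
#' @slot values real matrix, samples in rows, features in columns; \code{NA}
#'   marks a missing cell.
#' @export
setClass("FeatureMatrix", representation(values = "matrix"))

setValidity("FeatureMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v)) msg <- c(msg, "values must be a numeric matrix")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "values must carry sample ids (rownames) and feature ids (colnames)")
  else {
    if (anyDuplicated(rownames(v))) msg <- c(msg, "sample ids must be unique")
    if (anyDuplicated(colnames(v))) msg <- c(msg, "feature ids must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' RegionMeasureTable: one anatomical measure over brain regions
#'
#' Subjects-by-regions table of a single anatomical measure (cortical grey
#' matter volume, cortical thickness, surface area, curvature, folding index,
#' or sub-cortical volume).  The vertex set of each subject's individual
#' network.
#'
#' @slot values real matrix, subjects in rows, regions in columns (complete).
#' @slot measureName length-one character naming the measure.
#' @export
setClass("RegionMeasureTable",
         representation(values = "matrix", measureName = "character"))

setValidity("RegionMeasureTable", function(object) {
  v <- object@values
  msg <- character()
  if (ncol(v) < 2) msg <- c(msg, "at least 2 regions are required")
  if (anyNA(v)) msg <- c(msg, "measure table must be complete (no NA)")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "values must carry subject ids (rownames) and region ids (colnames)")
  if (length(object@measureName) != 1L) msg <- c(msg, "measureName must be length 1")
  if (length(msg)) msg else TRUE
})

#' ROIGraphFeatures: per-subject individual-network features
#'
#' The two feature views derived from one \linkS4class{RegionMeasureTable}:
#' \code{V} holds the vertex features (the region measures themselves) and
#' \code{E} the edge weights \eqn{1/(|m_i - m_j| + 1)} over all unordered
#' region pairs of the complete graph, in the fixed order of
#' \code{pairIndex}.
#'
#' @slot V \linkS4class{FeatureMatrix} of vertex features (subjects x regions).
#' @slot E \linkS4class{FeatureMatrix} of edge weights (subjects x C(n,2) pairs).
#' @slot pairIndex two-column data.frame of region ids, pairs (i, j) with
#'   i before j in region order, lexicographic.
#' @export
setClass("ROIGraphFeatures",
         representation(V = "FeatureMatrix", E = "FeatureMatrix",
                        pairIndex = "data.frame"))

setValidity("ROIGraphFeatures", function(object) {
  nr <- ncol(object@V@values)
  np <- ncol(object@E@values)
  msg <- character()
  if (np != nr * (nr - 1L) / 2L)
    msg <- c(msg, "E must have one column per unordered region pair (complete graph)")
  if (nrow(object@pairIndex) != np)
    msg <- c(msg, "pairIndex must have one row per E column")
  ev <- object@E@values
  if (length(ev) && (any(ev <= 0) || any(ev > 1)))
    msg <- c(msg, "edge weights must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' KernelSpec: one base-kernel definition
#'
#' @slot family one of \code{"gaussian"}, \code{"polynomial"},
#'   \code{"linear"}, \code{"sigmoid"}.
#' @slot params named list of family parameters (gaussian: \code{sigma};
#'   polynomial: \code{degree}, \code{offset}; linear: \code{offset};
#'   sigmoid: \code{alpha}, \code{offset}).
#' @export
setClass("KernelSpec", representation(family = "character", params = "list"))

# Parameters that must be present per family.  gaussian sigma and sigmoid
# alpha may be absent: they then default at evaluation time to the data-
# dependent values (sigma = number of samples, alpha = 1 / feature count).
.kernel_param_names <- list(
  gaussian   = character(),
  polynomial = c("degree", "offset"),
  linear     = "offset",
  sigmoid    = "offset"
)

setValidity("KernelSpec", function(object) {
  fam <- object@family
  if (length(fam) != 1L || !fam %in% names(.kernel_param_names))
    return(sprintf("unknown kernel family '%s'", paste(fam, collapse = ",")))
  need <- .kernel_param_names[[fam]]
  miss <- setdiff(need, names(object@params))
  if (length(miss))
    return(sprintf("%s kernel requires parameter(s): %s",
                   fam, paste(miss, collapse = ", ")))
  TRUE
})

#' KernelStack: M base kernels over a shared sample ordering
#'
#' Houses the kernel matrices \eqn{K_1, \ldots, K_M} that multiple kernel
#' learning combines with the weight vector \eqn{\beta}.  All matrices are
#' N x N over the same ordered sample set; each is symmetric and (for
#' gaussian/linear/polynomial families) positive semidefinite.  Sigmoid
#' kernels may be indefinite and are only checked for symmetry.
#'
#' @slot kernels list of M numeric N x N matrices.
#' @slot specs list of \linkS4class{KernelSpec}, one per kernel.
#' @slot viewIds character vector, the originating view of each kernel.
#' @slot sampleIds character vector, the shared sample ordering.
#' @export
setClass("KernelStack",
         representation(kernels = "list", specs = "list",
                        viewIds = "character", sampleIds = "character"))

setValidity("KernelStack", function(object) {
  M <- length(object@kernels)
  N <- length(object@sampleIds)
  msg <- character()
  if (length(object@specs) != M || length(object@viewIds) != M)
    msg <- c(msg, "kernels, specs and viewIds must have equal length")
  for (m in seq_len(M)) {
    K <- object@kernels[[m]]
    if (!is.matrix(K) || nrow(K) != N || ncol(K) != N) {
      msg <- c(msg, sprintf("kernel %d is not %d x %d", m, N, N)); next
    }
    if (max(abs(K - t(K))) > 1e-10)
      msg <- c(msg, sprintf("kernel %d is not symmetric within 1e-10", m))
    fam <- if (length(object@specs) >= m) object@specs[[m]]@family else "gaussian"
    if (fam != "sigmoid" && N > 0) {
      ev <- eigen((K + t(K)) / 2, symmetric = TRUE, only.values = TRUE)$values
      tol <- 1e-8 * max(sum(diag(K)), 1)
      if (min(ev) < -tol)
        msg <- c(msg, sprintf("kernel %d is not PSD (min eigenvalue %.3g)", m, min(ev)))
    }
  }
  if (length(msg)) msg else TRUE
})

#' ChainOrder: optimal parenthesization of a matrix chain
#'
#' Output of the dynamic program over scalar-multiplication counts
#' \eqn{F(i,j)} for a chain of matrices with dimension vector \code{dims}
#' (matrix i is dims[i] x dims[i+1]).  \code{splitTable[i, j]} is the
#' argmin split point t (smallest on ties); \code{totalCost} is
#' \eqn{F(1, n)}, the minimum number of scalar multiplications.
#'
#' @slot dims numeric vector of length n+1.
#' @slot costTable n x n numeric matrix F (upper triangle used).
#' @slot splitTable n x n numeric matrix of split points.
#' @slot totalCost numeric scalar.
#' @export
setClass("ChainOrder",
         representation(dims = "numeric", costTable = "matrix",
                        splitTable = "matrix", totalCost = "numeric"))

setValidity("ChainOrder", function(object) {
  n <- length(object@dims) - 1L
  msg <- character()
  if (n < 1L) msg <- c(msg, "dims must have length >= 2")
  if (any(object@dims < 1)) msg <- c(msg, "all dims must be >= 1")
  if (n >= 1L && any(diag(object@costTable) != 0))
    msg <- c(msg, "F(i,i) must be 0")
  if (length(msg)) msg else TRUE
})

#' AffinityPair: intrinsic and constraint graph affinities
#'
#' The two graphs of the embedded linear-discriminant analysis: the intrinsic
#' graph \code{W} with \eqn{w_{ij} = 1/n_c} for same-class pairs (class size
#' \eqn{n_c}, zero otherwise) and the constraint graph \code{Wprime} with
#' \eqn{w'_{ij} = 1/N} everywhere.
#'
#' @slot W N x N symmetric intrinsic affinity matrix; for the LDA graph
#'   every row sums to 1.
#' @slot Wprime N x N symmetric constraint affinity matrix.
#' @export
setClass("AffinityPair", representation(W = "matrix", Wprime = "matrix"))

setValidity("AffinityPair", function(object) {
  msg <- character()
  if (max(abs(object@W - t(object@W))) > 1e-12) msg <- c(msg, "W must be symmetric")
  if (max(abs(object@Wprime - t(object@Wprime))) > 1e-12)
    msg <- c(msg, "Wprime must be symmetric")
  if (length(msg)) msg else TRUE
})

#' MKLDRModel: a trained kernel-fusion embedding
#'
#' Result of the alternating optimization: the sample-coefficient matrix
#' \code{A} (N x P) and the kernel weight vector \code{beta} (length M,
#' unit Euclidean norm).  A sample with kernel-slice matrix
#' \eqn{\mathbb{K}^{(i)}} (N x M, column m = kernel m evaluated against all
#' training samples) is embedded as \eqn{(A^\top \mathbb{K}^{(i)} \beta)^\top}.
#'
#' @slot A numeric N x P sample-coefficient matrix.
#' @slot beta numeric length-M kernel weight vector, unit norm.
#' @slot P integer, reduced dimension.
#' @slot history per-iteration diagnostics (iteration, objective).
#' @slot trainSampleIds character, ordering A refers to.
#' @slot viewIds character, originating view of each kernel weight.
#' @slot specs list of \linkS4class{KernelSpec} of the training stack.
#' @export
setClass("MKLDRModel",
         representation(A = "matrix", beta = "numeric", P = "integer",
                        history = "data.frame", trainSampleIds = "character",
                        viewIds = "character", specs = "list"))

setValidity("MKLDRModel", function(object) {
  msg <- character()
  if (ncol(object@A) != object@P) msg <- c(msg, "A must have P columns")
  if (object@P > nrow(object@A)) msg <- c(msg, "P must not exceed N")
  nb <- sqrt(sum(object@beta^2))
  if (nb > 0 && abs(nb - 1) > 1e-6) msg <- c(msg, "beta must have unit norm")
  if (length(msg)) msg else TRUE
})

#' SplitScheme: repeated random holdout design
#'
#' @slot trainFraction fraction of samples drawn (without stratification)
#'   for training in each repetition; default 2/3.
#' @slot nReps number of repetitions; default 20.
#' @slot seed integer seed for the split stream.
#' @export
setClass("SplitScheme",
         representation(trainFraction = "numeric", nReps = "integer",
                        seed = "integer"))

setValidity("SplitScheme", function(object) {
  msg <- character()
  if (object@trainFraction <= 0 || object@trainFraction >= 1)
    msg <- c(msg, "trainFraction must be in (0, 1)")
  if (object@nReps < 1L) msg <- c(msg, "nReps must be >= 1")
  if (length(msg)) msg else TRUE
})

#' EvalReport: repeated-holdout evaluation summary
#'
#' @slot perRep data.frame with columns rep, accuracy, auc.
#' @slot bestAccuracy best single-repetition accuracy.
#' @slot meanAccuracy mean accuracy over repetitions.
#' @slot ciLower one-sided lower confidence bound of the mean accuracy from
#'   the one-sample t interval at \code{level}.
#' @slot level confidence level used.
#' @slot rocPoints data.frame (fpr, tpr) of the best repetition.
#' @slot nReps number of repetitions.
#' @export
setClass("EvalReport",
         representation(perRep = "data.frame", bestAccuracy = "numeric",
                        meanAccuracy = "numeric", ciLower = "numeric",
                        level = "numeric", rocPoints = "data.frame",
                        nReps = "integer"))

setValidity("EvalReport", function(object) {
  msg <- character()
  pr <- object@perRep
  if (nrow(pr) != object@nReps) msg <- c(msg, "nReps must equal nrow(perRep)")
  if (nrow(pr)) {
    if (any(pr$accuracy < 0 | pr$accuracy > 1)) msg <- c(msg, "accuracies must be in [0,1]")
    ok_auc <- pr$auc[!is.na(pr$auc)]
    if (length(ok_auc) && any(ok_auc < 0 | ok_auc > 1)) msg <- c(msg, "AUCs must be in [0,1]")
    if (object@bestAccuracy < object@meanAccuracy - 1e-12)
      msg <- c(msg, "best accuracy must be >= mean accuracy")
  }
  if (length(msg)) msg else TRUE
})
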