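#' Gaussian (RBF) kernel matrix
#'
#' \eqn{K[a,b] = \exp(-\|x_a - x_b\|^2 / 2\sigma^2)}.  With \code{Y} given,
#' returns the cross-kernel between the rows of \code{X} and the rows of
#' \code{Y} (used to embed held-out samples against the training set);
#' otherwise the symmetric N x N training kernel with unit diagonal.
#'
#' @param X \linkS4class{FeatureMatrix} (or numeric matrix), samples in rows.
#' @param sigma bandwidth, must be positive.
#' @param Y optional second matrix with the same feature columns.
#' @return numeric kernel matrix, \code{nrow(X)} x \code{nrow(Y)} (or N x N).
#' @examples
#' X <- FeatureMatrix(matrix(c(0, 2), 2, 1))
#' gaussianKernel(X, sigma = 1)[1, 2]   # exp(-2)
#' @export
gaussianKernel <- function(X, sigma, Y = NULL) {
  if (sigma <= 0) stop("sigma must be positive")
  Xv <- if (is(X, "FeatureMatrix")) X@values else as.matrix(X)
  Yv <- if (is.null(Y)) Xv else if (is(Y, "FeatureMatrix")) Y@values else as.matrix(Y)
  d2 <- outer(rowSums(Xv^2), rowSums(Yv^2), "+") - 2 * tcrossprod(Xv, Yv)
  d2[d2 < 0] <- 0                       # guard against round-off
  K <- exp(-d2 / (2 * sigma^2))
  if (is.null(Y)) {
    K <- (K + t(K)) / 2
    diag(K) <- 1
  }
  K
}

#' Kernel matrix under a KernelSpec
#'
#' Dispatches on the spec's family.  Data-dependent defaults mirror common
#' dimensionality-reduction toolbox settings and are filled in when the
#' parameter is absent from the spec: gaussian \code{sigma} = number of
#' samples; sigmoid \code{alpha} = 1 / number of features.  Polynomial is
#' the inhomogeneous \eqn{(x \cdot y + \mathrm{offset})^d} with degree 2 and
#' offset 1 by default; linear is \eqn{x \cdot y + c} with c = 0; sigmoid is
#' \eqn{\tanh(\alpha\, x \cdot y + c)} with c = 0.
#'
#' @param X \linkS4class{FeatureMatrix} (or matrix), samples in rows.
#' @param spec a \linkS4class{KernelSpec}.
#' @param Y optional second matrix for a cross-kernel.
#' @return numeric kernel matrix.
#' @export
namedKernel <- function(X, spec, Y = NULL) {
  stopifnot(is(spec, "KernelSpec"))
  Xv <- if (is(X, "FeatureMatrix")) X@values else as.matrix(X)
  Yv <- if (is.null(Y)) Xv else if (is(Y, "FeatureMatrix")) Y@values else as.matrix(Y)
  p <- spec@params
  switch(spec@family,
    gaussian = {
      sigma <- if (!is.null(p$sigma)) p$sigma else nrow(Xv)
      gaussianKernel(Xv, sigma, if (is.null(Y)) NULL else Yv)
    },
    polynomial = {
      K <- (tcrossprod(Xv, Yv) + p$offset)^p$degree
      if (is.null(Y)) K <- (K + t(K)) / 2
      K
    },
    linear = {
      K <- tcrossprod(Xv, Yv) + p$offset
      if (is.null(Y)) K <- (K + t(K)) / 2
      K
    },
    sigmoid = {
      alpha <- if (!is.null(p$alpha)) p$alpha else 1 / ncol(Xv)
      K <- tanh(alpha * tcrossprod(Xv, Yv) + p$offset)
      if (is.null(Y)) K <- (K + t(K)) / 2
      K
    },
    stop(sprintf("unknown kernel family '%s'", spec@family)))
}

.check_shared_samples <- function(views) {
  if (is.null(names(views)))
    names(views) <- paste0("view", seq_along(views))
  ids <- rownames(views[[1]]@values)
  for (nm in names(views)) {
    if (!identical(rownames(views[[nm]]@values), ids))
      stop(sprintf("view '%s' does not share the common sample ordering", nm))
  }
  views
}

#' Build a Gaussian kernel stack over a sigma grid
#'
#' One Gaussian kernel per (view, sigma) combination, so M = #views x
#' #sigmas.  The default grid spans twelve orders of magnitude
#' \{1e-6, 1e-3, 1, 1e3, 1e6\}; with 12 views it yields 60 kernels.  All
#' views must share the same sample ordering.
#'
#' @param views named list of \linkS4class{FeatureMatrix} views.
#' @param sigmas numeric vector of Gaussian bandwidths.
#' @return a \linkS4class{KernelStack}.
#' @export
kernelGrid <- function(views, sigmas = c(1e-6, 1e-3, 1, 1e3, 1e6)) {
  views <- .check_shared_samples(views)
  kernels <- list(); specs <- list(); vids <- character()
  for (nm in names(views)) {
    for (s in sigmas) {
      kernels[[length(kernels) + 1L]] <- gaussianKernel(views[[nm]], s)
      specs[[length(specs) + 1L]] <- KernelSpec("gaussian", sigma = s)
      vids <- c(vids, nm)
    }
  }
  new("KernelStack", kernels = kernels, specs = specs, viewIds = vids,
      sampleIds = rownames(views[[1]]@values))
}

#' Build a kernel stack from explicit specs
#'
#' One kernel per (view, spec) combination, for mixing kernel families over
#' the same data (e.g. gaussian + polynomial + linear + sigmoid on a single
#' expression view).
#'
#' @param views named list of \linkS4class{FeatureMatrix} views.
#' @param specs list of \linkS4class{KernelSpec}.
#' @return a \linkS4class{KernelStack} with M = #views x #specs kernels.
#' @export
kernelStack <- function(views, specs) {
  views <- .check_shared_samples(views)
  kernels <- list(); allspecs <- list(); vids <- character()
  for (nm in names(views)) {
    for (sp in specs) {
      kernels[[length(kernels) + 1L]] <- namedKernel(views[[nm]], sp)
      allspecs[[length(allspecs) + 1L]] <- sp
      vids <- c(vids, nm)
    }
  }
  new("KernelStack", kernels = kernels, specs = allspecs, viewIds = vids,
      sampleIds = rownames(views[[1]]@values))
}

#' Median-heuristic Gaussian bandwidth
#'
#' The median of the nonzero pairwise Euclidean distances between samples —
#' the standard data-driven bandwidth that places the Gaussian kernel at
#' the scale of the data, so the kernel is neither an identity matrix
#' (bandwidth far too small) nor an all-ones matrix (far too large).
#'
#' @param X \linkS4class{FeatureMatrix} or numeric matrix, samples in rows.
#' @return positive numeric bandwidth.
#' @export
medianSigma <- function(X) {
  Xv <- if (is(X, "FeatureMatrix")) X@values else as.matrix(X)
  d <- stats::dist(Xv)
  d <- d[d > 0]
  if (!length(d)) return(1)
  stats::median(d)
}

#' One median-bandwidth Gaussian kernel per view
#'
#' The recommended stack for rescaled data: each view contributes a single
#' Gaussian kernel at its own median-heuristic bandwidth (M = number of
#' views), so the kernel weights read directly as view weights and every
#' kernel operates at the scale of its view.
#'
#' @param views named list of \linkS4class{FeatureMatrix} views sharing a
#'   sample ordering.
#' @return a \linkS4class{KernelStack} with one kernel per view.
#' @export
medianKernelStack <- function(views) {
  views <- .check_shared_samples(views)
  kernels <- list(); specs <- list()
  for (nm in names(views)) {
    s <- medianSigma(views[[nm]])
    kernels[[length(kernels) + 1L]] <- gaussianKernel(views[[nm]], s)
    specs[[length(specs) + 1L]] <- KernelSpec("gaussian", sigma = s)
  }
  new("KernelStack", kernels = kernels, specs = specs,
      viewIds = names(views), sampleIds = rownames(views[[1]]@values))
}

#' Per-sample kernel slice
#'
#' The N x M matrix \eqn{\mathbb{K}^{(i)}} whose m-th column is the i-th
#' column of the m-th kernel: entry (n, m) is kernel m evaluated between
#' training sample n and sample i.  This is the per-sample building block
#' of the scatter matrices and of the projection
#' \eqn{(A^\top \mathbb{K}^{(i)} \beta)^\top}.
#'
#' @param stack a \linkS4class{KernelStack}.
#' @param i sample index in the stack's ordering.
#' @return numeric N x M matrix.
#' @export
kernelSlice <- function(stack, i) {
  N <- length(stack@sampleIds)
  if (i < 1L || i > N) stop(sprintf("sample index %d out of range 1..%d", i, N))
  vapply(stack@kernels, function(K) K[, i], numeric(N))
}

#' Cross-kernel matrices for held-out samples
#'
#' For each kernel in a training stack, evaluates the same kernel spec
#' between the training samples of its view and the corresponding held-out
#' view, giving the N_train x n_new matrices from which test-sample slices
#' \eqn{\mathbb{K}^{(i)}} are read column-wise.
#'
#' @param stack the training \linkS4class{KernelStack}.
#' @param trainViews,newViews named lists of \linkS4class{FeatureMatrix};
#'   names must cover the stack's \code{viewIds}, and each pair must share
#'   feature columns.
#' @return list of M numeric N_train x n_new matrices.
#' @export
crossKernelMatrices <- function(stack, trainViews, newViews) {
  lapply(seq_along(stack@kernels), function(m) {
    nm <- stack@viewIds[m]
    if (is.null(trainViews[[nm]]) || is.null(newViews[[nm]]))
      stop(sprintf("view '%s' absent from the supplied view lists", nm))
    namedKernel(trainViews[[nm]], stack@specs[[m]], Y = newViews[[nm]])
  })
}

#' Slices for a set of new samples from cross-kernel matrices
#'
#' @param crossMats list returned by \code{\link{crossKernelMatrices}}.
#' @return list of n_new matrices, each N_train x M.
#' @export
crossKernelSlices <- function(crossMats) {
  nNew <- ncol(crossMats[[1]])
  N <- nrow(crossMats[[1]])
  lapply(seq_len(nNew), function(i)
    vapply(crossMats, function(K) K[, i], numeric(N)))
}
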