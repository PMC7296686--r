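#' Linear-discriminant graph affinities
#'
#' The graph-embedding form of LDA over N labelled samples: the intrinsic
#' graph connects same-class pairs with weight \eqn{1/n_c} (class size
#' \eqn{n_c}), so each row sums to 1 and minimizing the induced scatter
#' shrinks within-class spread; the constraint graph weights every pair
#' \eqn{1/N}, anchoring total spread.
#'
#' @param labels class vector of length N (factor or character); at least
#'   two classes, each with at least two members.
#' @return an \linkS4class{AffinityPair}.
#' @export
ldaAffinities <- function(labels) {
  labels <- as.factor(labels)
  N <- length(labels)
  tab <- table(labels)
  if (length(tab) < 2L) stop("at least two classes are required")
  if (any(tab < 2L))
    stop(sprintf("singleton class '%s': within-class graph is degenerate",
                 names(tab)[tab < 2L][1]))
  W <- matrix(0, N, N)
  for (cl in names(tab)) {
    idx <- which(labels == cl)
    W[idx, idx] <- 1 / length(idx)
  }
  new("AffinityPair", W = W, Wprime = matrix(1 / N, N, N))
}

# Graph Laplacian D - W of a symmetric affinity matrix.
.laplacian <- function(W) diag(rowSums(W)) - W

#' Scatter matrices in the kernel-weight space (M x M)
#'
#' Assembles
#' \deqn{S^A = \sum_{i,j} w_{ij}\,
#'   (\mathbb{K}^{(i)} - \mathbb{K}^{(j)})^\top A A^\top
#'   (\mathbb{K}^{(i)} - \mathbb{K}^{(j)})}
#' and its analogue under the constraint affinities.  Two equivalent
#' evaluation paths are provided:
#' \describe{
#'   \item{\code{"fast"}}{the graph-Laplacian identity
#'     \eqn{\sum_{ij} w_{ij} (u_i-u_j)(v_i-v_j)^\top = 2\,U L V^\top}
#'     applied blockwise, giving \eqn{O(M N^2 P + M^2 N P)} work — the
#'     cubic-time route used in training.}
#'   \item{\code{"chain"}}{the literal double sum with each term's 4-matrix
#'     chain \eqn{(\cdot)^\top A\, A^\top (\cdot)} multiplied under the
#'     minimum-cost MCMO parenthesization; quadratic in N, retained for
#'     audits and as a second route in equivalence tests.}
#' }
#' Both agree with the plain double-sum definition to round-off.
#'
#' @param stack a \linkS4class{KernelStack} (M kernels over N samples).
#' @param A numeric N x P sample-coefficient matrix.
#' @param aff an \linkS4class{AffinityPair}.
#' @param order optional \linkS4class{ChainOrder} for the
#'   \eqn{(M,N,P,N,M)} chain; computed on the fly for the chain path when
#'   absent.  Ignored by the fast path.
#' @param method \code{"fast"} (default) or \code{"chain"}.
#' @return list with symmetric M x M matrices \code{S} (intrinsic) and
#'   \code{Sprime} (constraint).
#' @export
scatterA <- function(stack, A, aff, order = NULL,
                     method = c("fast", "chain")) {
  method <- match.arg(method)
  M <- length(stack@kernels)
  N <- length(stack@sampleIds)
  P <- ncol(A)
  stopifnot(nrow(A) == N)
  if (method == "fast") {
    Ts <- lapply(stack@kernels, function(K) crossprod(A, K))   # P x N each
    one <- function(W) {
      L <- .laplacian(W)
      R <- lapply(Ts, function(Tm) Tm %*% L)
      S <- matrix(0, M, M)
      for (m in seq_len(M)) for (mp in m:M) {
        S[m, mp] <- 2 * sum(Ts[[m]] * R[[mp]])
        S[mp, m] <- S[m, mp]
      }
      S
    }
    return(list(S = unname(one(aff@W)), Sprime = unname(one(aff@Wprime))))
  }
  if (is.null(order)) order <- chainOrder(c(M, N, P, N, M))
  slices <- lapply(seq_len(N), function(i) kernelSlice(stack, i))
  one <- function(W) {
    S <- matrix(0, M, M)
    for (i in seq_len(N)) for (j in seq_len(N)) {
      if (W[i, j] == 0) next
      X <- slices[[i]] - slices[[j]]
      S <- S + W[i, j] * multiplyChain(list(t(X), A, t(A), X), order)
    }
    S
  }
  list(S = unname(one(aff@W)), Sprime = unname(one(aff@Wprime)))
}

#' Scatter matrices in the sample-coefficient space (N x N)
#'
#' Assembles
#' \deqn{S^\beta = \sum_{i,j} w_{ij}\,
#'   (\mathbb{K}^{(i)} - \mathbb{K}^{(j)})\, \beta\beta^\top
#'   (\mathbb{K}^{(i)} - \mathbb{K}^{(j)})^\top}
#' and its constraint analogue.  The fast path uses
#' \eqn{u_i = \mathbb{K}^{(i)}\beta} (column i of the combined kernel
#' \eqn{U = \sum_m \beta_m K_m}) and the Laplacian identity
#' \eqn{S^\beta = 2\, U L U^\top}; the chain path multiplies each term's
#' \eqn{(N,M,1,M,N)} chain under its MCMO order.
#'
#' @inheritParams scatterA
#' @param beta numeric length-M kernel weight vector.
#' @return list with symmetric N x N matrices \code{S} and \code{Sprime}.
#' @export
scatterBeta <- function(stack, beta, aff, order = NULL,
                        method = c("fast", "chain")) {
  method <- match.arg(method)
  M <- length(stack@kernels)
  N <- length(stack@sampleIds)
  stopifnot(length(beta) == M)
  if (method == "fast") {
    U <- matrix(0, N, N)
    for (m in seq_len(M)) U <- U + beta[m] * stack@kernels[[m]]
    one <- function(W) {
      S <- 2 * (U %*% .laplacian(W) %*% t(U))
      unname((S + t(S)) / 2)
    }
    return(list(S = one(aff@W), Sprime = one(aff@Wprime)))
  }
  if (is.null(order)) order <- chainOrder(c(N, M, 1, M, N))
  slices <- lapply(seq_len(N), function(i) kernelSlice(stack, i))
  b <- matrix(beta, ncol = 1)
  one <- function(W) {
    S <- matrix(0, N, N)
    for (i in seq_len(N)) for (j in seq_len(N)) {
      if (W[i, j] == 0) next
      X <- slices[[i]] - slices[[j]]
      S <- S + W[i, j] * multiplyChain(list(X, b, t(b), t(X)), order)
    }
    S
  }
  list(S = unname(one(aff@W)), Sprime = unname(one(aff@Wprime)))
}

# Solve the symmetric pencil S x = lambda S' x for the nSmall smallest
# eigenpairs.  The constraint matrix S' is singular by construction (the
# all-pairs graph centres the data, and degenerate base kernels contribute
# null directions to both scatters), so the pencil is solved on the range
# of S': S' is eigendecomposed, directions with spectrum below
# tol * max(eigenvalue) are discarded — they carry no constraint scatter
# and cannot discriminate — and the remainder is whitened
# (B = V Lambda^{-1/2}) to reduce to an ordinary symmetric eigenproblem.
# Columns come back normalized so t(X) %*% S' %*% X = I on that range.
.gen_eigen_smallest <- function(S, Sp, nSmall, tol = 1e-10) {
  Sp <- (Sp + t(Sp)) / 2
  eg <- eigen(Sp, symmetric = TRUE)
  top <- max(eg$values, 0)
  if (top <= 0)
    stop("constraint scatter matrix is numerically singular beyond repair")
  pos <- eg$values > tol * top
  r <- sum(pos)
  if (nSmall > r)
    stop(sprintf(
      "requested dimension %d exceeds the rank %d of the constraint pencil",
      nSmall, r))
  B <- eg$vectors[, pos, drop = FALSE] %*%
    diag(1 / sqrt(eg$values[pos]), r, r)
  Mst <- crossprod(B, S %*% B)
  Mst <- (Mst + t(Mst)) / 2
  eg2 <- eigen(Mst, symmetric = TRUE)
  idx <- seq(r, r - nSmall + 1L)                       # smallest eigenvalues
  list(vectors = B %*% eg2$vectors[, idx, drop = FALSE],
       values = eg2$values[idx])
}

#' Sample-coefficient update
#'
#' Columns of A are the generalized eigenvectors of
#' \eqn{S^\beta a = \lambda S'^\beta a} with the P smallest eigenvalues,
#' normalized so \eqn{A^\top S'^\beta A = I}.  The constraint matrix is
#' rank-deficient by construction (the all-pairs graph centres the data),
#' so the pencil is solved on its numerical range: null directions carry
#' no constraint scatter and are excluded rather than ridged into the
#' spectrum.
#'
#' @param Sbeta,SbetaPrime symmetric N x N scatter matrices from
#'   \code{\link{scatterBeta}}.
#' @param P number of embedding dimensions (columns of A).
#' @return list with \code{A} (N x P) and \code{values} (the P smallest
#'   generalized eigenvalues, increasing).
#' @export
optimizeA <- function(Sbeta, SbetaPrime, P) {
  stopifnot(P >= 1, P <= nrow(Sbeta))
  sol <- .gen_eigen_smallest(Sbeta, SbetaPrime, P)
  list(A = sol$vectors[, rev(seq_len(P)), drop = FALSE],
       values = rev(sol$values))
}

#' Kernel-weight update
#'
#' \eqn{\beta} is the generalized eigenvector of
#' \eqn{S^A b = \lambda S'^A b} with the smallest eigenvalue, scaled to unit
#' Euclidean norm with its sign chosen so the entry sum is nonnegative.
#' With \code{nonneg = TRUE} (default) negative entries are clipped to zero
#' and the vector renormalized, so the weights act as convex-combination
#' coefficients over the base kernels.
#'
#' @param SA,SAPrime symmetric M x M scatter matrices from
#'   \code{\link{scatterA}}.
#' @param nonneg clip negative weights to zero and renormalize.
#' @return unit-norm numeric vector of length M.
#' @export
optimizeBeta <- function(SA, SAPrime, nonneg = TRUE) {
  M <- nrow(SA)
  if (M == 1L) return(1)
  sol <- .gen_eigen_smallest(SA, SAPrime, 1L)
  b <- as.vector(sol$vectors)
  b <- b / sqrt(sum(b^2))
  if (sum(b) < 0) b <- -b
  if (nonneg) {
    b[b < 0] <- 0
    nb <- sqrt(sum(b^2))
    if (nb > 0) b <- b / nb else b <- rep(1 / sqrt(M), M)
  }
  b
}

#' Train the fast kernel-fusion embedding
#'
#' Alternating optimization of the sample-coefficient matrix A and the
#' kernel weight vector beta under the linear-discriminant graph embedding:
#' each iteration assembles the relevant scatter matrices and solves the
#' corresponding generalized eigenproblem for the other block.  The two
#' matrix-chain orderings (for the M x M and N x N scatter chains) are
#' computed by \code{\link{chainOrder}} exactly once each before the loop —
#' the chain shapes do not change across iterations, so the ordering DP
#' never needs to run again.
#'
#' Initialization (the two produce similar fits; A tends to converge
#' faster):
#' \itemize{
#'   \item \code{init = "A"}: P leading eigenvectors of the summed kernel
#'     \eqn{\sum_m K_m};
#'   \item \code{init = "beta"}: uniform \eqn{1/\sqrt{M}}.
#' }
#' Training runs a fixed number of iterations (no early stop); the history
#' records the trace-ratio objective
#' \eqn{\mathrm{tr}(A^\top S^\beta A) / \mathrm{tr}(A^\top S'^\beta A)}
#' after each iteration.
#'
#' @param stack training \linkS4class{KernelStack}.
#' @param labels class vector aligned with the stack's samples.
#' @param P embedding dimension (default 5).
#' @param nIter number of alternating iterations (default 10).
#' @param init \code{"A"} or \code{"beta"}.
#' @param nonneg passed to \code{\link{optimizeBeta}}.
#' @return a trained \linkS4class{MKLDRModel}.
#' @export
trainFMKLDR <- function(stack, labels, P = 5L, nIter = 10L,
                        init = c("A", "beta"), nonneg = TRUE) {
  init <- match.arg(init)
  M <- length(stack@kernels)
  N <- length(stack@sampleIds)
  if (length(labels) != N)
    stop("labels must align with the stack's samples")
  P <- as.integer(P)
  if (P > N) stop("P must not exceed the number of training samples")
  aff <- ldaAffinities(labels)

  # The two chain shapes of the scatter equations; ordered once, up front.
  orderA    <- chainOrder(c(M, N, P, N, M))
  orderBeta <- chainOrder(c(N, M, 1, M, N))

  if (init == "beta") {
    beta <- rep(1 / sqrt(M), M)
    A <- NULL
  } else {
    Ksum <- Reduce(`+`, stack@kernels)
    eg <- eigen((Ksum + t(Ksum)) / 2, symmetric = TRUE)
    A <- eg$vectors[, seq_len(P), drop = FALSE]
    beta <- NULL
  }

  history <- data.frame(iteration = integer(), objective = numeric())
  for (it in seq_len(nIter)) {
    if (init == "beta") {
      sb <- scatterBeta(stack, beta, aff, order = orderBeta)
      A <- optimizeA(sb$S, sb$Sprime, P)$A
      sa <- scatterA(stack, A, aff, order = orderA)
      beta <- optimizeBeta(sa$S, sa$Sprime, nonneg = nonneg)
    } else {
      sa <- scatterA(stack, A, aff, order = orderA)
      beta <- optimizeBeta(sa$S, sa$Sprime, nonneg = nonneg)
      sb <- scatterBeta(stack, beta, aff, order = orderBeta)
      A <- optimizeA(sb$S, sb$Sprime, P)$A
    }
    sb2 <- scatterBeta(stack, beta, aff, order = orderBeta)
    num <- sum(diag(crossprod(A, sb2$S %*% A)))
    den <- sum(diag(crossprod(A, sb2$Sprime %*% A)))
    history <- rbind(history,
                     data.frame(iteration = it,
                                objective = if (den > 0) num / den else NA_real_))
  }

  new("MKLDRModel", A = A, beta = beta, P = P, history = history,
      trainSampleIds = stack@sampleIds, viewIds = stack@viewIds,
      specs = stack@specs)
}

#' Project samples into the fused embedding
#'
#' Sample i with kernel-slice matrix \eqn{\mathbb{K}^{(i)}} (N_train x M,
#' column m = kernel m evaluated between sample i and every training
#' sample) embeds as row \eqn{(A^\top \mathbb{K}^{(i)} \beta)^\top}.  For
#' training samples the slices come from \code{\link{kernelSlice}}; for
#' held-out samples from \code{\link{crossKernelMatrices}} /
#' \code{\link{crossKernelSlices}} under the same kernel specs.
#'
#' @param model a trained \linkS4class{MKLDRModel}.
#' @param slices list of N_train x M slice matrices, one per sample to
#'   embed.
#' @return numeric n x P embedding matrix.
#' @export
project <- function(model, slices) {
  N <- nrow(model@A); M <- length(model@beta)
  Z <- vapply(slices, function(S) {
    if (!is.matrix(S) || nrow(S) != N || ncol(S) != M)
      stop(sprintf("slice must be %d x %d", N, M))
    as.vector(crossprod(model@A, S %*% model@beta))
  }, numeric(model@P))
  if (model@P == 1L) Z <- matrix(Z, ncol = 1L) else Z <- t(Z)
  Z
}

#' Project the training samples of a stack
#'
#' Equivalent to slicing every training sample and calling
#' \code{\link{project}}, computed in one pass as \eqn{U A} with
#' \eqn{U = \sum_m \beta_m K_m}.
#'
#' @param model a trained \linkS4class{MKLDRModel}.
#' @param stack the training \linkS4class{KernelStack}.
#' @return numeric N x P embedding matrix.
#' @export
projectTraining <- function(model, stack) {
  if (!identical(stack@sampleIds, model@trainSampleIds))
    stop("stack sample ordering differs from the model's training ordering")
  U <- matrix(0, nrow(model@A), nrow(model@A))
  for (m in seq_along(model@beta)) U <- U + model@beta[m] * stack@kernels[[m]]
  unname(U %*% model@A)
}
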