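# Independent reference implementations used as oracles.  These stay naive
# on purpose: plain double loops and pair counting, no shared code with the
# package's fast paths.

# Literal double-sum scatter matrices, left-to-right products only.
naiveScatterA <- function(stack, A, aff) {
  N <- length(stack@sampleIds)
  slices <- lapply(seq_len(N), kernelSlice, stack = stack)
  one <- function(W) {
    S <- matrix(0, ncol(slices[[1]]), ncol(slices[[1]]))
    for (i in seq_len(N)) for (j in seq_len(N)) {
      X <- slices[[i]] - slices[[j]]
      S <- S + W[i, j] * (t(X) %*% A %*% t(A) %*% X)
    }
    S
  }
  list(S = one(aff@W), Sprime = one(aff@Wprime))
}

naiveScatterBeta <- function(stack, beta, aff) {
  N <- length(stack@sampleIds)
  slices <- lapply(seq_len(N), kernelSlice, stack = stack)
  b <- matrix(beta, ncol = 1)
  one <- function(W) {
    S <- matrix(0, N, N)
    for (i in seq_len(N)) for (j in seq_len(N)) {
      X <- slices[[i]] - slices[[j]]
      S <- S + W[i, j] * (X %*% b %*% t(b) %*% t(X))
    }
    S
  }
  list(S = one(aff@W), Sprime = one(aff@Wprime))
}

relFrobenius <- function(A, B) {
  den <- sqrt(sum(B^2))
  if (den == 0) sqrt(sum(A^2)) else sqrt(sum((A - B)^2)) / den
}

# AUC by explicit concordant-pair counting, ties worth one half.
bruteForceAUC <- function(scores, truth, positive) {
  pos <- scores[truth == positive]
  neg <- scores[truth != positive]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Random small kernel stack over gaussian kernels (always valid/PSD).
randomStack <- function(N, M, d = 3, sigma = 2) {
  ids <- sprintf("s%d", seq_len(N))
  views <- lapply(seq_len(M), function(m) {
    FeatureMatrix(matrix(rnorm(N * d), N, d,
                         dimnames = list(ids, sprintf("f%d", seq_len(d)))))
  })
  names(views) <- sprintf("v%d", seq_len(M))
  kernelGrid(views, sigmas = sigma)
}

balancedLabels <- function(N) rep(c("a", "b"), c(ceiling(N / 2), floor(N / 2)))
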