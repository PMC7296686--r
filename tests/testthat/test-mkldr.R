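test_that("LDA graph affinities follow the class structure", {
  aff <- ldaAffinities(c("a", "a", "b", "b"))
  expect_equal(aff@W, rbind(c(.5, .5, 0, 0), c(.5, .5, 0, 0),
                            c(0, 0, .5, .5), c(0, 0, .5, .5)))
  expect_equal(aff@Wprime, matrix(0.25, 4, 4))
  expect_equal(rowSums(aff@W), rep(1, 4))

  aff9 <- ldaAffinities(rep(c("a", "b"), c(3, 6)))
  expect_equal(aff9@W[1:3, 1:3], matrix(1 / 3, 3, 3))
  expect_equal(aff9@W[4:9, 4:9], matrix(1 / 6, 6, 6))
  expect_equal(aff9@W[1:3, 4:9], matrix(0, 3, 6))
  expect_equal(aff9@Wprime, matrix(1 / 9, 9, 9))
  expect_equal(rowSums(aff9@W), rep(1, 9))

  expect_error(ldaAffinities(rep("a", 5)), "two classes")
  expect_error(ldaAffinities(c("a", "a", "b")), "singleton")
})

test_that("both scatter evaluation paths match the naive double sum", {
  set.seed(77)
  stack <- randomStack(N = 6, M = 2)
  labels <- balancedLabels(6)
  aff <- ldaAffinities(labels)
  A <- matrix(rnorm(6), 6, 1)
  beta <- c(0.6, 0.8)

  na <- naiveScatterA(stack, A, aff)
  for (method in c("fast", "chain")) {
    sa <- scatterA(stack, A, aff, method = method)
    expect_lt(relFrobenius(sa$S, na$S), 1e-10)
    expect_lt(relFrobenius(sa$Sprime, na$Sprime), 1e-10)
  }
  nb <- naiveScatterBeta(stack, beta, aff)
  for (method in c("fast", "chain")) {
    sb <- scatterBeta(stack, beta, aff, method = method)
    expect_lt(relFrobenius(sb$S, nb$S), 1e-10)
    expect_lt(relFrobenius(sb$Sprime, nb$Sprime), 1e-10)
  }
})

test_that("scatter forms are quadratic in A and vanish on zero graphs/weights", {
  set.seed(12)
  stack <- randomStack(N = 5, M = 2)
  aff <- ldaAffinities(balancedLabels(5))
  A <- matrix(rnorm(5), 5, 1)
  s1 <- scatterA(stack, A, aff)
  s2 <- scatterA(stack, 2 * A, aff)
  expect_equal(s2$S, 4 * s1$S, tolerance = 1e-10)

  zero <- new("AffinityPair", W = matrix(0, 5, 5), Wprime = aff@Wprime)
  expect_equal(scatterA(stack, A, zero)$S, matrix(0, 2, 2))
  expect_equal(scatterBeta(stack, c(0, 0), aff)$S, matrix(0, 5, 5))

  # single kernel: the beta scatter reduces to column-difference outer products
  one <- new("KernelStack", kernels = stack@kernels[1],
             specs = stack@specs[1], viewIds = stack@viewIds[1],
             sampleIds = stack@sampleIds)
  sb <- scatterBeta(one, 1, aff)
  expect_lt(relFrobenius(sb$S, naiveScatterBeta(one, 1, aff)$S), 1e-10)
})

test_that("the sample-coefficient update solves the generalized eigenproblem", {
  r <- optimizeA(diag(3), diag(3), P = 2)
  expect_equal(sum(r$values), 2)

  r <- optimizeA(diag(c(3, 2, 1)), diag(3), P = 1)
  expect_equal(abs(as.vector(r$A)), c(0, 0, 1), tolerance = 1e-12)
  expect_equal(r$values, 1)

  # independent oracle: nonsymmetric eigen of solve(Sp) %*% S
  set.seed(9)
  G <- matrix(rnorm(36), 6); S <- crossprod(G)
  H <- matrix(rnorm(36), 6); Sp <- crossprod(H) + diag(6)
  r <- optimizeA(S, Sp, P = 2)
  ref <- sort(Re(eigen(solve(Sp, S))$values))
  expect_equal(sort(r$values), ref[1:2], tolerance = 1e-8)
  expect_equal(crossprod(r$A, Sp %*% r$A), diag(2), tolerance = 1e-6)

  expect_error(optimizeA(diag(3), matrix(0, 3, 3), P = 1), "singular")
  expect_error(optimizeA(diag(3), diag(c(1, 0, 0)), P = 2), "rank")
})

test_that("the kernel-weight update returns the smallest generalized eigenvector", {
  expect_equal(optimizeBeta(matrix(4), matrix(2)), 1)
  expect_equal(optimizeBeta(diag(c(5, 1)), diag(2)), c(0, 1))

  set.seed(19)
  G <- matrix(rnorm(16), 4); S <- crossprod(G)
  H <- matrix(rnorm(16), 4); Sp <- crossprod(H) + diag(4)
  b <- optimizeBeta(S, Sp, nonneg = FALSE)
  lam <- as.numeric((b %*% S %*% b) / (b %*% Sp %*% b))
  expect_lt(sqrt(sum((S %*% b - lam * (Sp %*% b))^2)), 1e-8)
  expect_equal(sum(b^2), 1)
  expect_gte(sum(b), 0)

  bn <- optimizeBeta(S, Sp, nonneg = TRUE)
  expect_true(all(bn >= 0))
  expect_equal(sum(bn^2), 1)
})

test_that("training orders each scatter chain exactly once", {
  set.seed(41)
  stack <- randomStack(N = 30, M = 3)
  labels <- balancedLabels(30)
  resetChainOrderCallCount()
  model <- trainFMKLDR(stack, labels, P = 2, nIter = 5)
  expect_identical(chainOrderCallCount(), 2L)
  expect_identical(nrow(model@history), 5L)
  expect_s4_class(model, "MKLDRModel")
})

test_that("a single kernel leaves nothing to reweight", {
  set.seed(42)
  stack <- randomStack(N = 10, M = 1)
  model <- trainFMKLDR(stack, balancedLabels(10), P = 2, nIter = 3,
                       init = "beta")
  expect_identical(kernelWeights(model), 1)
})

test_that("kernel weights concentrate on the class-informative view", {
  hits <- 0
  for (s in 1:10) {
    coh <- makeMultiviewCohort(simSpec(nSamples = 60L,
                                       classSizes = c(30L, 30L),
                                       missingRate = 0, seed = s))
    views <- lapply(coh$views, minmaxRescale)
    stack <- medianKernelStack(views)
    model <- trainFMKLDR(stack, coh$labels, P = 2, nIter = 5)
    if (which.max(viewWeights(model)) == 1L) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("projection follows (A' K b)' and its special cases", {
  set.seed(23)
  stack <- randomStack(N = 8, M = 2)
  labels <- balancedLabels(8)
  model <- trainFMKLDR(stack, labels, P = 2, nIter = 3)
  Z1 <- projectTraining(model, stack)
  Z2 <- project(model, lapply(1:8, kernelSlice, stack = stack))
  expect_equal(Z1, Z2, tolerance = 1e-10)

  zero <- model; zero@beta <- rep(0, 2)
  expect_equal(project(zero, lapply(1:8, kernelSlice, stack = stack)),
               matrix(0, 8, 2))

  # M = 1, beta = 1, A = e1: embedding of sample i is K[1, i]
  one <- randomStack(N = 5, M = 1)
  sel <- new("MKLDRModel", A = matrix(c(1, 0, 0, 0, 0), 5, 1), beta = 1,
             P = 1L, history = data.frame(),
             trainSampleIds = one@sampleIds, viewIds = one@viewIds,
             specs = one@specs)
  Z <- project(sel, lapply(1:5, kernelSlice, stack = one))
  expect_equal(as.vector(Z), kernelMatrices(one)[[1]][1, ],
               ignore_attr = TRUE)

  expect_error(project(model, list(matrix(0, 3, 2))), "slice must be")
})

test_that("sample order does not change the embedding geometry", {
  set.seed(61)
  coh <- makeMultiviewCohort(simSpec(nSamples = 24L, classSizes = c(12L, 12L),
                                     missingRate = 0, seed = 61))
  views <- lapply(coh$views, minmaxRescale)
  perm <- sample(24)
  viewsP <- lapply(views, function(v) FeatureMatrix(values(v)[perm, ]))
  # P = 1: with two classes the pencil has exactly one well-separated
  # discriminative eigenvalue, so the embedding is unique up to sign;
  # higher dimensions live in a degenerate eigenspace and are not
  # comparable coordinate-wise
  m1 <- trainFMKLDR(medianKernelStack(views), coh$labels, P = 1, nIter = 4)
  m2 <- trainFMKLDR(medianKernelStack(viewsP), coh$labels[perm], P = 1,
                    nIter = 4)
  expect_equal(kernelWeights(m1), kernelWeights(m2), tolerance = 1e-8)
  Z1 <- projectTraining(m1, medianKernelStack(views))
  Z2 <- projectTraining(m2, medianKernelStack(viewsP))
  Z2[perm, ] <- Z2            # undo the permutation
  d1 <- as.matrix(dist(Z1)); d2 <- as.matrix(dist(Z2))
  expect_lt(max(abs(d1 - d2)), 1e-6 * max(1, max(d1)))
})

test_that("rescaling the whole stack leaves the weight ranking unchanged", {
  set.seed(71)
  coh <- makeMultiviewCohort(simSpec(nSamples = 30L, classSizes = c(15L, 15L),
                                     missingRate = 0, seed = 71))
  views <- lapply(coh$views, minmaxRescale)
  stack <- medianKernelStack(views)
  scaled <- stack
  scaled@kernels <- lapply(stack@kernels, function(K) 3.7 * K)
  b1 <- kernelWeights(trainFMKLDR(stack, coh$labels, P = 2, nIter = 4))
  b2 <- kernelWeights(trainFMKLDR(scaled, coh$labels, P = 2, nIter = 4))
  expect_identical(order(b1), order(b2))
})

test_that("well-separated classes give zero nearest-centroid error after fusion", {
  for (s in 1:10) {
    coh <- makeMultiviewCohort(simSpec(nSamples = 40L, classSizes = c(20L, 20L),
                                       missingRate = 0, seed = 100 + s))
    views <- lapply(coh$views, minmaxRescale)
    stack <- medianKernelStack(views)
    model <- trainFMKLDR(stack, coh$labels, P = 2, nIter = 5)
    Z <- projectTraining(model, stack)
    cen <- rowsum(Z, coh$labels) / as.vector(table(coh$labels))
    d <- as.matrix(dist(rbind(cen, Z)))[3:(40 + 2), 1:2]
    pred <- rownames(cen)[apply(d, 1, which.min)]
    expect_identical(mean(pred == coh$labels), 1)
  }
})
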