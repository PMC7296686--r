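test_that("gaussian kernel matches its closed form", {
  X <- FeatureMatrix(matrix(c(0, 2), 2, 1))
  K <- gaussianKernel(X, sigma = 1)
  expect_equal(diag(K), c(1, 1), ignore_attr = TRUE)
  expect_equal(K[1, 2], exp(-2))
  expect_error(gaussianKernel(X, sigma = 0), "positive")
  expect_error(gaussianKernel(X, sigma = -1), "positive")

  # bounded data, enormous bandwidth: kernel flattens to all ones
  set.seed(3)
  B <- FeatureMatrix(matrix(runif(40, -1, 1), 10, 4))
  expect_lt(max(abs(gaussianKernel(B, 1e6) - 1)), 1e-9)
})

test_that("a sigma grid over views yields one kernel per combination", {
  set.seed(8)
  coh <- makeMultiviewCohort(simSpec(nSamples = 20L, classSizes = c(10L, 10L),
                                     nViews = 12L, dims = 6L,
                                     effectSize = 0, missingRate = 0,
                                     scale = 1, seed = 8))
  stack <- kernelGrid(coh$views)
  expect_identical(nKernels(stack), 60L)
  expect_identical(nKernels(kernelGrid(coh$views[1], sigmas = 1)), 1L)
  expect_identical(nKernels(kernelGrid(coh$views[1:4])), 20L)

  bad <- coh$views
  bad$view2 <- FeatureMatrix(values(bad$view2)[20:1, ])
  expect_error(kernelGrid(bad), "view2")
})

test_that("named kernel families reproduce hand-computed matrices", {
  I2 <- FeatureMatrix(diag(2))
  expect_equal(namedKernel(I2, KernelSpec("linear")), diag(2),
               ignore_attr = TRUE)
  expect_equal(namedKernel(I2, KernelSpec("polynomial")),
               matrix(c(4, 1, 1, 4), 2), ignore_attr = TRUE)
  expect_equal(namedKernel(I2, KernelSpec("sigmoid", alpha = 1 / 2)),
               diag(tanh(0.5), 2), ignore_attr = TRUE)
  # data-dependent defaults: gaussian sigma = N, sigmoid alpha = 1/D
  X <- FeatureMatrix(matrix(rnorm(12), 4, 3))
  expect_equal(namedKernel(X, KernelSpec("gaussian")),
               gaussianKernel(X, sigma = 4))
  expect_equal(namedKernel(X, KernelSpec("sigmoid")),
               tanh(tcrossprod(values(X)) / 3), ignore_attr = TRUE)
  expect_error(KernelSpec("spectral"), "arg")
})

test_that("kernel stacks satisfy symmetry and positive semidefiniteness", {
  set.seed(14)
  stack <- randomStack(N = 15, M = 3)
  for (K in kernelMatrices(stack)) {
    expect_lt(max(abs(K - t(K))), 1e-10)
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8 * sum(diag(K)))
    expect_true(all(K > 0 & K <= 1 + 1e-12))   # gaussian entries in (0, 1]
  }
  # mixing families over one view
  X <- list(v = FeatureMatrix(matrix(rnorm(20), 10, 2)))
  st <- kernelStack(X, list(KernelSpec("linear"), KernelSpec("polynomial"),
                            KernelSpec("sigmoid")))
  expect_identical(nKernels(st), 3L)
  expect_true(validObject(st))
})

test_that("per-sample slices extract kernel columns", {
  K1 <- matrix(c(1, .5, .5, 1), 2)
  K2 <- diag(2)
  stack <- new("KernelStack", kernels = list(K1, K2),
               specs = list(KernelSpec("gaussian", sigma = 1),
                            KernelSpec("linear")),
               viewIds = c("a", "b"), sampleIds = c("s1", "s2"))
  expect_equal(kernelSlice(stack, 1), cbind(c(1, .5), c(1, 0)))
  expect_error(kernelSlice(stack, 3), "out of range")

  # selection identity: slice times a unit weight vector picks a kernel column
  set.seed(21)
  st <- randomStack(N = 7, M = 3)
  for (i in 1:7) {
    for (m in 1:3) {
      e <- replace(numeric(3), m, 1)
      expect_equal(as.vector(kernelSlice(st, i) %*% e),
                   kernelMatrices(st)[[m]][, i], ignore_attr = TRUE)
    }
  }
})

test_that("cross-kernel slices agree with training slices on training points", {
  set.seed(30)
  ids <- sprintf("s%d", 1:8)
  views <- list(v1 = FeatureMatrix(matrix(rnorm(24), 8, 3,
                                          dimnames = list(ids, paste0("f", 1:3)))))
  stack <- kernelGrid(views, sigmas = c(0.5, 2))
  cross <- crossKernelMatrices(stack, views, views)
  slices <- crossKernelSlices(cross)
  for (i in 1:8)
    expect_equal(slices[[i]], kernelSlice(stack, i), tolerance = 1e-12)
})

test_that("median-heuristic bandwidth sits at the data scale", {
  set.seed(4)
  X <- FeatureMatrix(matrix(rnorm(200), 20, 10))
  s <- medianSigma(X)
  d <- dist(values(X))
  expect_equal(s, median(d[d > 0]))
  K <- gaussianKernel(X, s)
  off <- K[upper.tri(K)]
  expect_gt(mean(off), 0.05)   # neither identity-like ...
  expect_lt(mean(off), 0.95)   # ... nor all-ones-like
  st <- medianKernelStack(list(a = X, b = X))
  expect_identical(nKernels(st), 2L)
})
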