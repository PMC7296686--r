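test_that("the fused-kernel SVM separates separable toys and rejects one class", {
  Z <- rbind(c(0, 0), c(0, 1), c(5, 4), c(5, 5))
  y <- c("a", "a", "b", "b")
  clf <- svmTrain(Z, y)
  pr <- svmPredict(clf, Z)
  expect_identical(as.character(pr$class), y)
  expect_error(svmTrain(Z, rep("a", 4)), "single-class")

  # decision values are oriented toward the second level
  expect_gt(mean(pr$decision[y == "b"]), mean(pr$decision[y == "a"]))

  # precomputed-kernel route agrees with the embedding route on training data
  clf2 <- svmTrain(tcrossprod(scale(Z, scale = FALSE)) /
                     mean(rowSums(scale(Z, scale = FALSE)^2)),
                   y, precomputed = TRUE)
  expect_identical(as.character(svmPredict(clf2,
    tcrossprod(scale(Z, scale = FALSE)) /
      mean(rowSums(scale(Z, scale = FALSE)^2)))$class), y)
})

test_that("SVM holdout accuracy is high on a well-separated fused embedding", {
  set.seed(99)
  n <- 60
  Z <- rbind(matrix(rnorm(30 * 2), 30, 2),
             matrix(rnorm(30 * 2, mean = 4), 30, 2))
  y <- rep(c("a", "b"), each = 30)
  accs <- replicate(20, {
    tr <- sample(n, 40)
    clf <- svmTrain(Z[tr, ], y[tr])
    mean(as.character(svmPredict(clf, Z[-tr, ])$class) == y[-tr])
  })
  expect_gte(mean(accs), 0.95)
})

test_that("the t lower bound matches hand computation and its properties", {
  expect_equal(oneSampleTTestLowerBound(rep(0.9, 5)), 0.9)
  b <- oneSampleTTestLowerBound(c(0.8, 1.0), level = 0.95)
  expect_equal(b, 0.9 - qt(0.95, 1) * sd(c(0.8, 1.0)) / sqrt(2))
  expect_equal(b, 0.2686, tolerance = 1e-4)
  expect_error(oneSampleTTestLowerBound(0.5), "at least two")

  set.seed(7)
  for (k in 1:20) {
    v <- runif(8)
    expect_lte(oneSampleTTestLowerBound(v), mean(v))
    # translation equivariance: shifting every value shifts the bound
    expect_equal(oneSampleTTestLowerBound(v + 0.3),
                 oneSampleTTestLowerBound(v) + 0.3)
  }

  # the bound tightens toward the mean as n grows at fixed spread
  small <- rep(c(0.8, 1.0), 2)
  large <- rep(c(0.8, 1.0), 20)
  expect_gt(oneSampleTTestLowerBound(large), oneSampleTTestLowerBound(small))
})

test_that("rank-statistic AUC matches pair counting and handles ties", {
  expect_equal(rocAuc(c(1, 2, 3, 4), c("n", "n", "p", "p"))$auc, 1)
  expect_equal(rocAuc(rep(0.3, 6), rep(c("n", "p"), 3))$auc, 0.5)
  r <- rocAuc(c(0.9, 0.8, 0.4, 0.3), c("p", "n", "p", "n"), positive = "p")
  expect_equal(r$auc, 0.75)
  expect_equal(r$rocPoints$fpr[1], 0)
  expect_equal(tail(r$rocPoints$tpr, 1), 1)
  expect_error(rocAuc(1:3, rep("p", 3)), "both classes")

  set.seed(33)
  for (k in 1:30) {
    n <- sample(4:50, 1)
    truth <- c("n", "p", sample(c("n", "p"), n - 2, replace = TRUE))
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
    expect_equal(rocAuc(scores, truth, positive = "p")$auc,
                 bruteForceAUC(scores, truth, "p"))
  }
})

test_that("rank-statistic AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(44)
  scores <- rnorm(40)
  truth <- sample(c("n", "p"), 40, replace = TRUE, prob = c(.4, .6))
  ours <- rocAuc(scores, truth, positive = "p")$auc
  ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, levels = c("n", "p"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("repeated holdout is reproducible and degenerates gracefully", {
  coh <- makeMultiviewCohort(simSpec(nSamples = 40L, classSizes = c(20L, 20L),
                                     seed = 13))
  cfg <- pipelineConfig(sigmas = "median", P = 2, nIter = 3)
  sch <- SplitScheme(nReps = 3L, seed = 5L)
  r1 <- repeatedHoldout(coh$views, coh$labels, sch, cfg)
  r2 <- repeatedHoldout(coh$views, coh$labels, sch, cfg)
  expect_identical(perRepetition(r1), perRepetition(r2))
  expect_identical(rocPoints(r1), rocPoints(r2))
  expect_gte(bestAccuracy(r1), meanAccuracy(r1))
  expect_lte(ciLower(r1), meanAccuracy(r1))

  one <- repeatedHoldout(coh$views, coh$labels, SplitScheme(nReps = 1L, seed = 2L), cfg)
  expect_identical(nrow(perRepetition(one)), 1L)
  expect_identical(bestAccuracy(one), meanAccuracy(one))
})

test_that("the dimension scan tabulates accuracy per embedding size", {
  coh <- makeMultiviewCohort(simSpec(nSamples = 30L, classSizes = c(15L, 15L),
                                     seed = 17))
  cfg <- pipelineConfig(sigmas = "median", nIter = 2)
  sch <- SplitScheme(nReps = 2L, seed = 3L)
  tab <- dimensionScan(coh$views, coh$labels, c(2L, 4L), sch, cfg)
  expect_identical(nrow(tab), 2L)
  expect_identical(tab$f, c(2L, 4L))
  expect_identical(attr(tab, "bestF"), tab$f[which.max(tab$meanAccuracy)])

  expect_warning(
    tab2 <- dimensionScan(coh$views, coh$labels, c(2L, 500L), sch, cfg),
    "skipping")
  expect_identical(nrow(tab2), 1L)
})
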