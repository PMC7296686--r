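#' Train a C-SVC on the fused representation
#'
#' Support vector classification with cost 1 and equal class weights on a
#' precomputed kernel.  Given the fused embedding Z, the kernel presented
#' to the SVM is the inner-product (unified) kernel \eqn{Z Z^\top}; for
#' held-out points it is \eqn{Z_{new} Z_{train}^\top}, the only kernel the
#' trained embedding defines out of sample.  Because both scatter graphs
#' of the embedding are pairwise-difference forms, the embedding is defined
#' only up to a per-dimension offset (and the eigenvector normalization
#' fixes its scale arbitrarily); the harness therefore canonicalizes Z by
#' centring on the training means and rescaling to unit mean squared row
#' norm before forming the kernel, and applies the same map to held-out
#' points.  A precomputed kernel matrix may also be passed directly, in
#' which case it is used as is.
#'
#' @param Z numeric n x P embedding matrix, or a precomputed n x n kernel
#'   matrix when \code{precomputed = TRUE}.
#' @param labels class vector of length n with at least two classes.
#' @param cost soft-margin cost C (default 1).
#' @param precomputed treat \code{Z} as a kernel matrix.
#' @return an object of class \code{fmkldrSVM}; use
#'   \code{\link{svmPredict}}.
#' @export
svmTrain <- function(Z, labels, cost = 1, precomputed = FALSE) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2L) stop("single-class training set")
  center <- NULL; zscale <- 1
  if (precomputed) {
    K <- as.matrix(Z)
  } else {
    Z <- as.matrix(Z)
    center <- colMeans(Z)
    Zc <- sweep(Z, 2, center)
    msq <- mean(rowSums(Zc^2))
    zscale <- if (msq > 0) 1 / sqrt(msq) else 1
    Z <- Zc * zscale
    K <- tcrossprod(Z)
  }
  fit <- kernlab::ksvm(kernlab::as.kernelMatrix(K), labels,
                       type = "C-svc", C = cost)
  # Orient decision values so that larger means the second factor level,
  # using the fitted predictions only (never the truth).
  dec <- kernlab::predict(fit, kernlab::as.kernelMatrix(
    K[, kernlab::SVindex(fit), drop = FALSE]), type = "decision")[, 1]
  pred <- kernlab::predict(fit, kernlab::as.kernelMatrix(
    K[, kernlab::SVindex(fit), drop = FALSE]))
  pos <- pred == levels(labels)[2]
  flip <- mean(dec[pos]) < mean(dec[!pos])
  structure(list(fit = fit, levels = levels(labels),
                 Ztrain = if (precomputed) NULL else Z,
                 center = center, zscale = zscale,
                 flip = isTRUE(flip)),
            class = "fmkldrSVM")
}

#' Predict from a fused-representation SVM
#'
#' @param clf an \code{fmkldrSVM} from \code{\link{svmTrain}}.
#' @param Znew numeric n_new x P embedding matrix, or (for a classifier
#'   trained on a precomputed kernel) the n_new x n_train cross-kernel.
#' @return list with \code{class} (factor) and \code{decision} (numeric
#'   scores oriented so larger favours the second class level).
#' @export
svmPredict <- function(clf, Znew) {
  stopifnot(inherits(clf, "fmkldrSVM"))
  Kc <- if (is.null(clf$Ztrain)) {
    as.matrix(Znew)
  } else {
    Zs <- sweep(as.matrix(Znew), 2, clf$center) * clf$zscale
    tcrossprod(Zs, clf$Ztrain)
  }
  sv <- kernlab::SVindex(clf$fit)
  Ksv <- kernlab::as.kernelMatrix(Kc[, sv, drop = FALSE])
  cls <- kernlab::predict(clf$fit, Ksv)
  dec <- kernlab::predict(clf$fit, Ksv, type = "decision")[, 1]
  if (clf$flip) dec <- -dec
  list(class = factor(cls, levels = clf$levels), decision = dec)
}

#' Rank-statistic AUC and ROC points
#'
#' AUC as the probability that a random positive outscores a random
#' negative, ties counted one half (the Wilcoxon rank form).  ROC points
#' are produced at every distinct score threshold, from (0, 0) to (1, 1).
#'
#' @param decisionValues numeric scores, larger favouring the positive
#'   class.
#' @param truth class vector; \code{positive} defaults to its second
#'   factor level.
#' @param positive which truth value counts as positive.
#' @return list with \code{auc} and \code{rocPoints} (data.frame fpr, tpr).
#' @examples
#' rocAuc(c(0.9, 0.8, 0.4, 0.3), c("p", "n", "p", "n"), positive = "p")$auc
#' @export
rocAuc <- function(decisionValues, truth, positive = NULL) {
  truth <- as.factor(truth)
  if (nlevels(droplevels(truth)) < 2L)
    stop("both classes must be present in truth")
  if (is.null(positive)) positive <- levels(truth)[2]
  ispos <- truth == positive
  npos <- sum(ispos); nneg <- sum(!ispos)
  r <- rank(decisionValues, ties.method = "average")
  auc <- (sum(r[ispos]) - npos * (npos + 1) / 2) / (npos * nneg)
  thr <- sort(unique(decisionValues), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(ispos & decisionValues >= t) / npos, 0)
  fpr <- vapply(thr, function(t) sum(!ispos & decisionValues >= t) / nneg, 0)
  list(auc = auc,
       rocPoints = data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1)))
}

#' One-sided lower confidence bound of a mean
#'
#' The one-sample t bound \eqn{\bar x - t_{level,\,n-1}\, s/\sqrt{n}} over
#' repetition metrics (e.g. the 20 holdout accuracies), the
#' confidence-level row reported alongside the best repetition.  With zero
#' variance the common value is returned.
#'
#' @param values numeric vector, length at least 2.
#' @param level confidence level (default 0.95).
#' @return the lower bound.
#' @export
oneSampleTTestLowerBound <- function(values, level = 0.95) {
  n <- length(values)
  if (n < 2L) stop("at least two values are required")
  s <- stats::sd(values)
  if (s == 0) return(values[1])
  mean(values) - stats::qt(level, df = n - 1) * s / sqrt(n)
}

#' Default pipeline configuration
#'
#' Collects the tunables of the end-to-end pipeline: the Gaussian bandwidth
#' grid (one kernel per view per sigma), or explicit kernel specs; the
#' embedding dimension P; iteration count and initialization of the
#' alternating optimization; SVM cost; rescaling range; confidence level.
#'
#' @param sigmas Gaussian bandwidth grid, one kernel per view per value;
#'   or the string \code{"median"} for a single kernel per view at its
#'   median-heuristic bandwidth (recommended for rescaled data — the wide
#'   historical grid produces degenerate identity- or all-ones-like
#'   kernels once features live in [-1, 1]).  Ignored when \code{specs}
#'   is given.
#' @param specs optional list of \linkS4class{KernelSpec} applied to every
#'   view instead of the Gaussian grid.
#' @param P embedding dimension.
#' @param nIter alternating iterations.
#' @param init \code{"A"} or \code{"beta"}.
#' @param nonneg nonnegative kernel weights.
#' @param cost SVM cost.
#' @param level confidence level of the t bound.
#' @param lo,hi rescaling range.
#' @return a named list.
#' @export
pipelineConfig <- function(sigmas = c(1e-6, 1e-3, 1, 1e3, 1e6), specs = NULL,
                           P = 5L, nIter = 10L, init = "A", nonneg = TRUE,
                           cost = 1, level = 0.95, lo = -1, hi = 1) {
  list(sigmas = sigmas, specs = specs, P = as.integer(P),
       nIter = as.integer(nIter), init = init, nonneg = nonneg,
       cost = cost, level = level, lo = lo, hi = hi)
}

# One holdout repetition: full pipeline fitted on the training rows only.
.holdout_once <- function(views, labels, trainIdx, config) {
  testIdx <- setdiff(seq_along(labels), trainIdx)
  trainViews <- list(); testViews <- list()
  for (nm in names(views)) {
    X <- views[[nm]]
    Xtr <- new("FeatureMatrix", values = X@values[trainIdx, , drop = FALSE])
    Xte <- new("FeatureMatrix", values = X@values[testIdx, , drop = FALSE])
    sc <- fitScaler(Xtr, config$lo, config$hi)
    trainViews[[nm]] <- applyScaler(sc, Xtr)
    testViews[[nm]] <- applyScaler(sc, Xte)
  }
  stack <- if (!is.null(config$specs)) {
    kernelStack(trainViews, config$specs)
  } else if (identical(config$sigmas, "median")) {
    medianKernelStack(trainViews)
  } else {
    kernelGrid(trainViews, config$sigmas)
  }
  model <- trainFMKLDR(stack, labels[trainIdx], P = config$P,
                       nIter = config$nIter, init = config$init,
                       nonneg = config$nonneg)
  Ztr <- projectTraining(model, stack)
  cross <- crossKernelMatrices(stack, trainViews, testViews)
  Zte <- project(model, crossKernelSlices(cross))
  clf <- svmTrain(Ztr, labels[trainIdx], cost = config$cost)
  pr <- svmPredict(clf, Zte)
  truth <- factor(labels[testIdx], levels = clf$levels)
  acc <- mean(as.character(pr$class) == as.character(truth))
  if (nlevels(droplevels(truth)) < 2L) {
    auc <- NA_real_; roc <- data.frame(fpr = numeric(), tpr = numeric())
  } else {
    ra <- rocAuc(pr$decision, truth)
    auc <- ra$auc; roc <- ra$rocPoints
  }
  list(accuracy = acc, auc = auc, roc = roc, model = model)
}

#' Repeated random holdout evaluation
#'
#' The evaluation protocol: in each repetition a random
#' \code{trainFraction} of the cohort (default 2/3, unstratified) is used
#' to fit the entire pipeline — feature cleaning, train-only min-max
#' rescaling, kernel construction, the kernel-fusion embedding, and the
#' SVM — and the held-out remainder is scored.  Splits drawing a
#' single-class training set are redrawn (at most 100 times).  The report
#' carries per-repetition accuracy and AUC, the best and mean accuracy,
#' the one-sided lower t confidence bound of the mean, and the ROC points
#' of the best repetition.
#'
#' @param views named list of \linkS4class{FeatureMatrix} (raw; missing
#'   features are dropped here).
#' @param labels class vector aligned with the views' samples.
#' @param scheme a \linkS4class{SplitScheme}.
#' @param config list from \code{\link{pipelineConfig}}.
#' @return an \linkS4class{EvalReport}.
#' @export
repeatedHoldout <- function(views, labels, scheme = SplitScheme(),
                            config = pipelineConfig()) {
  stopifnot(is(scheme, "SplitScheme"))
  if (is.null(names(views)))
    names(views) <- paste0("view", seq_along(views))
  views <- lapply(views, dropIncompleteFeatures)
  n <- length(labels)
  nTrain <- floor(scheme@trainFraction * n)
  set.seed(scheme@seed)
  acc <- numeric(scheme@nReps); auc <- numeric(scheme@nReps)
  rocs <- vector("list", scheme@nReps)
  for (r in seq_len(scheme@nReps)) {
    trainIdx <- NULL
    for (attempt in seq_len(100L)) {
      cand <- sort(sample.int(n, nTrain))
      if (length(unique(labels[cand])) >= 2L) { trainIdx <- cand; break }
    }
    if (is.null(trainIdx))
      stop("could not draw a training split with two classes in 100 attempts")
    res <- .holdout_once(views, labels, trainIdx, config)
    acc[r] <- res$accuracy; auc[r] <- res$auc; rocs[[r]] <- res$roc
  }
  best <- which.max(acc)
  ci <- if (scheme@nReps >= 2L) oneSampleTTestLowerBound(acc, config$level)
        else acc[1]
  new("EvalReport",
      perRep = data.frame(rep = seq_len(scheme@nReps), accuracy = acc,
                          auc = auc),
      bestAccuracy = max(acc), meanAccuracy = mean(acc), ciLower = ci,
      level = config$level, rocPoints = rocs[[best]],
      nReps = scheme@nReps)
}

#' Accuracy against the reduced dimension
#'
#' Runs \code{\link{repeatedHoldout}} for each candidate embedding
#' dimension f (the reduced-dimension parameter P) and tabulates the mean
#' accuracy.  Values of f exceeding the training-set size (the order of
#' the eigenproblem pencil) are skipped with a warning.  The best f is the
#' argmax of mean accuracy, smallest f on ties; the accuracy curve need
#' not be monotone.
#'
#' @inheritParams repeatedHoldout
#' @param fValues integer vector of candidate dimensions.
#' @return data.frame with columns \code{f} and \code{meanAccuracy}, with
#'   the winning dimension in attribute \code{bestF}.
#' @export
dimensionScan <- function(views, labels, fValues, scheme = SplitScheme(),
                          config = pipelineConfig()) {
  nTrain <- floor(scheme@trainFraction * length(labels))
  out <- data.frame(f = integer(), meanAccuracy = numeric())
  for (f in fValues) {
    if (f > nTrain) {
      warning(sprintf("skipping f = %d: exceeds the pencil order %d", f, nTrain))
      next
    }
    cf <- config; cf$P <- as.integer(f)
    rep <- repeatedHoldout(views, labels, scheme, cf)
    out <- rbind(out, data.frame(f = as.integer(f),
                                 meanAccuracy = meanAccuracy(rep)))
  }
  if (nrow(out))
    attr(out, "bestF") <- out$f[which.max(out$meanAccuracy)]
  out
}
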