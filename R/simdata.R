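#' Specification of a synthetic multi-view cohort
#'
#' Defines a cohort of labelled samples observed through several views that
#' share the class structure but differ in informativeness and scale —
#' the situation multi-omic integration faces.  Each view is
#' class-conditional Gaussian: a random half of its features carries a mean
#' shift of \code{effectSize[v]} noise standard deviations between
#' consecutive classes, the rest is pure noise; the whole view is then
#' multiplied by \code{scale[v]} to emulate heterogeneous magnitudes.
#' Missingness mimics features absent in a few subjects: a
#' \code{missingRate} fraction of feature columns gets one missing cell in
#' a random subject (such features are later removed, not imputed).
#'
#' Defaults describe the reference study conditions used throughout the
#' test-suite: 90 samples in two balanced classes, two 50-feature views of
#' which only the first is informative (effect size 4), unit noise, 3
#' percent affected features, and a thousand-fold scale difference between
#' views.
#'
#' @param nSamples total cohort size.
#' @param classSizes class sizes, summing to \code{nSamples}.
#' @param nViews number of views.
#' @param dims features per view (recycled).
#' @param effectSize per-view mean shift in noise-sd units (recycled).
#' @param noiseSd noise standard deviation.
#' @param missingRate fraction of features given a missing cell.
#' @param scale per-view magnitude multiplier (recycled).
#' @param informativeFraction fraction of a view's features that carry the
#'   class shift.
#' @param seed integer seed; the generator is fully reproducible.
#' @return a list of class \code{simSpec}.
#' @export
simSpec <- function(nSamples = 90L, classSizes = c(45L, 45L), nViews = 2L,
                    dims = 50L, effectSize = c(4, 0), noiseSd = 1,
                    missingRate = 0.03, scale = c(1, 1000),
                    informativeFraction = 0.5, seed = 1L) {
  spec <- list(nSamples = as.integer(nSamples),
               classSizes = as.integer(classSizes),
               nViews = as.integer(nViews),
               dims = rep_len(as.integer(dims), nViews),
               effectSize = rep_len(effectSize, nViews),
               noiseSd = noiseSd, missingRate = missingRate,
               scale = rep_len(scale, nViews),
               informativeFraction = informativeFraction,
               seed = as.integer(seed))
  if (sum(spec$classSizes) != spec$nSamples)
    stop("classSizes must sum to nSamples")
  if (any(spec$effectSize < 0)) stop("effectSize must be nonnegative")
  if (spec$missingRate < 0 || spec$missingRate >= 1)
    stop("missingRate must be in [0, 1)")
  if (spec$noiseSd <= 0) stop("noiseSd must be positive")
  class(spec) <- "simSpec"
  spec
}

#' Generate a synthetic multi-view cohort
#'
#' @param spec a \code{\link{simSpec}}.
#' @return list with \code{views} (named list of
#'   \linkS4class{FeatureMatrix}) and \code{labels} (named character
#'   vector).
#' @export
makeMultiviewCohort <- function(spec) {
  stopifnot(inherits(spec, "simSpec"))
  set.seed(spec$seed)
  n <- spec$nSamples
  labels <- rep(paste0("c", seq_along(spec$classSizes)), spec$classSizes)
  ids <- sprintf("s%03d", seq_len(n))
  names(labels) <- ids
  classIdx <- match(labels, unique(labels))
  views <- list()
  for (v in seq_len(spec$nViews)) {
    d <- spec$dims[v]
    X <- matrix(stats::rnorm(n * d, sd = spec$noiseSd), n, d)
    nInf <- max(1L, round(spec$informativeFraction * d))
    inf <- sample.int(d, nInf)
    shift <- spec$effectSize[v] * spec$noiseSd
    X[, inf] <- X[, inf] + shift * (classIdx - 1)
    X <- X * spec$scale[v]
    nMissCols <- round(spec$missingRate * d)
    if (nMissCols > 0) {
      cols <- sample.int(d, nMissCols)
      rows <- sample.int(n, nMissCols, replace = TRUE)
      X[cbind(rows, cols)] <- NA_real_
    }
    dimnames(X) <- list(ids, sprintf("v%d_f%03d", v, seq_len(d)))
    views[[paste0("view", v)]] <- new("FeatureMatrix", values = X)
  }
  list(views = views, labels = labels)
}

#' Generate a synthetic per-region measure table
#'
#' Fixture for the individual-network construction: per-region Gaussian
#' measures around region-specific baselines, with a class-dependent shift
#' of \code{classShift} on a random half of the regions for the second
#' class.  Two balanced classes.
#'
#' @param nSubjects number of subjects.
#' @param nRegions number of regions (at least 2).
#' @param classShift mean shift added for the second class.
#' @param seed integer seed.
#' @param measureName label for the measure.
#' @return list with \code{table} (a \linkS4class{RegionMeasureTable}) and
#'   \code{labels}.
#' @export
makeRegionMeasures <- function(nSubjects = 90L, nRegions = 12L,
                               classShift = 0, seed = 1L,
                               measureName = "synthetic") {
  if (nRegions < 2L) stop("nRegions must be at least 2")
  set.seed(seed)
  n2 <- nSubjects %/% 2L
  labels <- c(rep("c1", nSubjects - n2), rep("c2", n2))
  ids <- sprintf("s%03d", seq_len(nSubjects))
  names(labels) <- ids
  baseline <- stats::runif(nRegions, 1, 5)
  X <- matrix(stats::rnorm(nSubjects * nRegions), nSubjects, nRegions)
  X <- sweep(X, 2, baseline, "+")
  if (classShift != 0) {
    sh <- sample.int(nRegions, max(1L, nRegions %/% 2L))
    X[labels == "c2", sh] <- X[labels == "c2", sh] + classShift
  }
  dimnames(X) <- list(ids, sprintf("r%02d", seq_len(nRegions)))
  list(table = RegionMeasureTable(X, measureName = measureName),
       labels = labels)
}

#' Write a simulated cohort to delimited files
#'
#' Writes each view as a TSV feature matrix and the labels as a two-column
#' TSV, the same formats the pipeline reads back.
#'
#' @param cohort list from \code{\link{makeMultiviewCohort}}.
#' @param dir output directory (created if needed).
#' @return invisibly, a named vector of the paths written.
#' @export
writeCohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  for (nm in names(cohort$views)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    writeFeatureMatrix(cohort$views[[nm]], p)
    paths[nm] <- p
  }
  lp <- file.path(dir, "labels.tsv")
  utils::write.table(data.frame(sample_id = names(cohort$labels),
                                label = unname(cohort$labels)),
                     lp, sep = "\t", quote = FALSE, row.names = FALSE)
  paths["labels"] <- lp
  invisible(paths)
}
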