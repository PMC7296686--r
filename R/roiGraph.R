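#' Edge weight between two regions
#'
#' The individual-network edge weight between regions with measure values
#' \code{mi} and \code{mj}: \eqn{w = 1/(d + 1)} with \eqn{d = |m_i - m_j|}.
#' Identical measures give weight 1; the weight decays toward 0 as the
#' measures diverge, so it always lies in (0, 1].  Vectorized.
#'
#' @param mi,mj numeric measure values.
#' @return numeric edge weight(s) in (0, 1].
#' @examples
#' edgeWeight(3, 3)    # 1
#' edgeWeight(1, 3)    # 1/3
#' @export
edgeWeight <- function(mi, mj) 1 / (abs(mi - mj) + 1)

#' Build per-subject individual-network features
#'
#' Each subject's regions form the vertices of a complete weighted graph:
#' vertex features are the region measures themselves (view \code{V}), and
#' each unordered pair of regions contributes one edge-weight feature
#' (view \code{E}) computed by \code{\link{edgeWeight}}.  Pairs are ordered
#' deterministically: (i, j) with i before j in region-column order,
#' lexicographic, so E columns align across subjects and runs.  A table of
#' n regions yields n(n-1)/2 edge features (78 regions: 3003; 12 regions:
#' 66).
#'
#' @param T a \linkS4class{RegionMeasureTable}.
#' @return a \linkS4class{ROIGraphFeatures} with views \code{V} and
#'   \code{E} plus the pair index.
#' @export
buildIndividualNetworks <- function(T) {
  stopifnot(is(T, "RegionMeasureTable"))
  v <- T@values
  nr <- ncol(v)
  if (nr < 2L) stop("at least 2 regions are required to build edges")
  pr <- utils::combn(nr, 2L)            # 2 x n_pairs, lexicographic in i then j
  E <- edgeWeight(v[, pr[1L, ], drop = FALSE], v[, pr[2L, ], drop = FALSE])
  regions <- colnames(v)
  pairIds <- paste(regions[pr[1L, ]], regions[pr[2L, ]], sep = "|")
  dimnames(E) <- list(rownames(v), pairIds)
  Vfm <- FeatureMatrix(v)
  Efm <- FeatureMatrix(E)
  pairIndex <- data.frame(region_i = regions[pr[1L, ]],
                          region_j = regions[pr[2L, ]],
                          stringsAsFactors = FALSE)
  new("ROIGraphFeatures", V = Vfm, E = Efm, pairIndex = pairIndex)
}

setMethod("show", "ROIGraphFeatures", function(object) {
  cat(sprintf("ROIGraphFeatures: %d subjects, %d vertices, %d edges\n",
              nrow(object@V@values), ncol(object@V@values),
              ncol(object@E@values)))
})

#' Write ROI-network feature views
#'
#' Emits the two delimited feature matrices (V and E) for one measure, plus
#' the pair index as a two-column sidecar table, into \code{dir} with file
#' names \code{<prefix>_V.tsv}, \code{<prefix>_E.tsv},
#' \code{<prefix>_pairs.tsv}.
#'
#' @param g a \linkS4class{ROIGraphFeatures}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix, typically the measure name.
#' @return invisibly, the three paths written.
#' @export
writeROIGraphFeatures <- function(g, dir, prefix = "measure") {
  stopifnot(is(g, "ROIGraphFeatures"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pv <- file.path(dir, paste0(prefix, "_V.tsv"))
  pe <- file.path(dir, paste0(prefix, "_E.tsv"))
  pp <- file.path(dir, paste0(prefix, "_pairs.tsv"))
  writeFeatureMatrix(g@V, pv)
  writeFeatureMatrix(g@E, pe)
  utils::write.table(g@pairIndex, pp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(V = pv, E = pe, pairs = pp))
}
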