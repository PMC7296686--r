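#' Run the full stratification pipeline from a configuration
#'
#' End-to-end driver: read the views and labels, clean and evaluate by
#' repeated random holdout (each repetition fits rescaling, kernels, the
#' kernel-fusion embedding and the SVM on its training split only), and
#' write the evaluation report, per-repetition table, ROC points of the
#' best repetition and a manifest to the output directory.
#'
#' @param config named list (or path to a JSON file holding one) with
#'   elements: \code{views} — named character vector/list of paths to
#'   delimited feature matrices; \code{labels} — path to a two-column
#'   label table; optional \code{outDir} (default \code{"."});
#'   optional \code{seed}, \code{nReps}, \code{trainFraction}; plus any
#'   override of \code{\link{pipelineConfig}} fields (\code{sigmas},
#'   \code{P}, \code{nIter}, \code{init}, \code{cost}, \code{level}, ...).
#' @return the \linkS4class{EvalReport}, invisibly; artifacts on disk.
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop(sprintf("config file not found: %s", config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  for (p in c(unlist(config$views), config$labels))
    if (!file.exists(p)) stop(sprintf("input path not found: %s", p))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  views <- stage("read views", {
    v <- lapply(unlist(config$views), readFeatureMatrix)
    names(v) <- names(unlist(config$views))
    if (is.null(names(v)) || any(names(v) == ""))
      names(v) <- paste0("view", seq_along(v))
    v
  })
  labels <- stage("read labels", {
    lab <- readLabels(config$labels)
    ids <- rownames(views[[1]]@values)
    if (!all(ids %in% names(lab)))
      stop("labels are missing for some samples")
    lab[ids]
  })
  cfgArgs <- config[intersect(names(config), names(formals(pipelineConfig)))]
  pcfg <- do.call(pipelineConfig, cfgArgs)
  scheme <- SplitScheme(
    trainFraction = if (!is.null(config$trainFraction)) config$trainFraction else 2 / 3,
    nReps = if (!is.null(config$nReps)) config$nReps else 20L,
    seed = if (!is.null(config$seed)) config$seed else 1L)
  report <- stage("evaluate", repeatedHoldout(views, labels, scheme, pcfg))
  outDir <- if (!is.null(config$outDir)) config$outDir else "."
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  stage("write artifacts", {
    jsonlite::write_json(
      list(nReps = report@nReps,
           meanAccuracy = report@meanAccuracy,
           bestAccuracy = report@bestAccuracy,
           ciLower = report@ciLower,
           level = report@level,
           meanAUC = mean(report@perRep$auc, na.rm = TRUE)),
      file.path(outDir, "report.json"), auto_unbox = TRUE, digits = NA)
    utils::write.table(report@perRep, file.path(outDir, "per_rep.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(report@rocPoints, file.path(outDir, "roc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- list(
      config = config[setdiff(names(config), "outDir")],
      seed = scheme@seed,
      package = "fmkldr",
      version = as.character(utils::packageVersion("fmkldr")))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  })
  invisible(report)
}
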