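#' Run the full coexpression / hub-screening pipeline
#'
#' Chains every stage: zero-row removal, MAD filtering, sample clustering
#' and static-cut outlier removal, soft-threshold selection, adjacency and
#' TOM construction, dynamic tree cut with eigengene merging, module-trait
#' correlation, GS/MM statistics, and the two-stage centrality hub screen
#' on the trait-significant modules. With `outDir` set, every stage result
#' is written as a TSV (plus Cytoscape edge/node files per significant
#' module) and the parameters and before/after gene and sample counts of
#' each filter are appended to `<outDir>/log.txt`, so the printed counts of
#' a run are recoverable from its log.
#'
#' @param dataset a `SummarizedExperiment` from [coexDataset()], or a list
#'   with elements `expression`, `trait` and optionally `annotation`.
#' @param config a \linkS4class{PipelineConfig}.
#' @param outDir optional output directory (created if missing).
#' @param verbose print progress messages?
#' @return a list with elements `filterReport`, `sampleTree`, `cutHeight`,
#'   `removedSamples`, `expression` (filtered genes x retained samples),
#'   `trait`, `scan` (\linkS4class{SoftThresholdScan}), `power`, `tom`,
#'   `geneTree`, `assignment` (\linkS4class{ModuleAssignment}),
#'   `eigengenes`, `moduleTrait`, `significantModules`, `geneStats`,
#'   `eigengeneNetwork`, `hubReport` (\linkS4class{HubReport} or NULL).
#' @examples
#' sim <- simulateWaxDataset(nGenes = 400, moduleSizes = c(80, 60),
#'                           traitModules = 1, zeroGeneFrac = 0.1,
#'                           lowMadFrac = 0.2, seed = 3)
#' cfg <- pipelineConfig(fitTarget = 0.8, topK = 50L)
#' res <- runWaxPipeline(sim, cfg)
#' res$assignment
#' @export
runWaxPipeline <- function(dataset, config = pipelineConfig(),
                           outDir = NULL, verbose = FALSE) {
  validObject(config)
  say <- function(...) if (verbose) message(...)
  if (methods::is(dataset, "SummarizedExperiment")) {
    expr <- SummarizedExperiment::assay(dataset, "fpkm")
    trait <- stats::setNames(dataset$wax_secretion, colnames(dataset))
    rd <- SummarizedExperiment::rowData(dataset)
    annotation <- data.frame(gene_id = rownames(dataset),
                             swissprot_id = rd$swissprot_id,
                             description = rd$description)
    annotation <- annotation[!is.na(annotation$swissprot_id), , drop = FALSE]
  } else {
    expr <- dataset$expression
    trait <- dataset$trait
    annotation <- dataset$annotation
  }
  validateExpression(expr)
  validateTrait(trait)
  logPath <- NULL
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    logPath <- file.path(outDir, "log.txt")
    if (file.exists(logPath)) file.remove(logPath)
  }
  set.seed(config@seed)

  ## -- preprocessing ------------------------------------------------------
  zr <- removeZeroGenes(expr)
  mf <- madFilter(zr$expression, topFraction = config@madFraction,
                  floor = config@madFloor,
                  scaleConstant = config@madScaleConstant,
                  nInputGenes = nrow(expr), nZeroRemoved = zr$nRemoved)
  say(sprintf("filtering: %d -> %d (zero rows) -> %d (MAD)", nrow(expr),
              nrow(zr$expression), nrow(mf$expression)))
  logStage(logPath, "filter", input_genes = nrow(expr),
           zero_removed = zr$nRemoved, after_zero = nrow(zr$expression),
           mad_fraction = config@madFraction, mad_floor = config@madFloor,
           mad_scale_constant = config@madScaleConstant,
           retained = nrow(mf$expression))

  sampleTree <- clusterSamples(mf$expression)
  cutHeight <- if (is.na(config@cutHeight)) suggestCutHeight(sampleTree)
               else config@cutHeight
  out <- removeOutlierSamples(sampleTree, mf$expression, trait, cutHeight,
                              minClusterSize = config@minClusterSize)
  say(sprintf("outlier cut at %.4g: removed %s", cutHeight,
              if (length(out$removed)) paste(out$removed, collapse = ", ")
              else "none"))
  logStage(logPath, "outliers", cut_height = cutHeight,
           min_cluster_size = config@minClusterSize,
           samples_before = ncol(mf$expression),
           samples_after = ncol(out$expression),
           removed = if (length(out$removed)) out$removed else "none")

  ## -- network ------------------------------------------------------------
  scan <- pickSoftThreshold(out$expression, powers = config@powers,
                            fitTarget = config@fitTarget,
                            mode = config@networkSign,
                            maxGenes = config@maxGenes)
  beta <- chosenPower(scan)
  say(sprintf("soft threshold: power %d (fit %.3f)", beta,
              scan@scan$fit[scan@scan$power == beta]))
  logStage(logPath, "network", power = beta, fit_target = config@fitTarget,
           reached_target = scan@reachedTarget, sign = config@networkSign)
  adj <- adjacencyFromCor(correlationMatrix(out$expression,
                                            maxGenes = config@maxGenes),
                          beta, mode = config@networkSign)
  tom <- tomSimilarity(adj)

  ## -- modules ------------------------------------------------------------
  geneTree <- clusterGenes(tom)
  rawLabels <- cutGeneTree(geneTree, diss = 1 - tom,
                           minModuleSize = config@minModuleSize,
                           deepSplit = config@deepSplit,
                           pamStage = config@pamStage)
  assign <- mergeCloseModules(out$expression, rawLabels,
                              mergeCutHeight = config@mergeCutHeight)
  say(sprintf("modules: %d (plus %d grey genes)",
              length(moduleColors(assign)),
              sum(moduleLabels(assign) == 0L)))
  logStage(logPath, "modules", n_modules = length(moduleColors(assign)),
           min_module_size = config@minModuleSize,
           deep_split = config@deepSplit,
           merge_cut_height = config@mergeCutHeight,
           sizes = moduleSizes(assign), grey = sum(moduleLabels(assign) == 0L))

  if (!length(moduleColors(assign))) {
    warning("no modules detected; stopping after module detection")
    return(list(filterReport = mf$report, sampleTree = sampleTree,
                cutHeight = cutHeight, removedSamples = out$removed,
                expression = out$expression, trait = out$trait, scan = scan,
                power = beta, tom = tom, geneTree = geneTree,
                assignment = assign, eigengenes = NULL, moduleTrait = NULL,
                significantModules = character(), geneStats = NULL,
                eigengeneNetwork = NULL, hubReport = NULL))
  }

  ## -- module-trait -------------------------------------------------------
  eig <- moduleEigengenes(out$expression, assign)
  mt <- moduleTraitRelation(eig, out$trait, pAdjust = config@pAdjust)
  sig <- selectSignificantModules(mt, alpha = config@moduleAlpha)
  gstats <- geneTraitStats(out$expression, out$trait, eig, assign)
  en <- if (ncol(eig) >= 2) eigengeneNetwork(eig) else NULL
  say(sprintf("significant modules (p < %g): %s", config@moduleAlpha,
              if (length(sig)) paste(sig, collapse = ", ") else "none"))
  logStage(logPath, "module_trait", alpha = config@moduleAlpha,
           p_adjust = config@pAdjust, significant = if (length(sig)) sig
           else "none")

  ## -- hub screen ---------------------------------------------------------
  hubReport <- NULL
  if (length(sig) && !is.null(annotation) && nrow(annotation)) {
    hubReport <- screenHubs(tom, assign, annotation, sig,
                            threshold = config@exportThreshold,
                            topK = config@topK,
                            hubFraction = config@hubFraction)
    logStage(logPath, "hubs", export_threshold = config@exportThreshold,
             top_k = config@topK, hub_fraction = config@hubFraction,
             n_hubs = nrow(hubGenes(hubReport)))
  }

  res <- list(filterReport = mf$report, sampleTree = sampleTree,
              cutHeight = cutHeight, removedSamples = out$removed,
              expression = out$expression, trait = out$trait, scan = scan,
              power = beta, tom = tom, geneTree = geneTree,
              assignment = assign, eigengenes = eig, moduleTrait = mt,
              significantModules = sig, geneStats = gstats,
              eigengeneNetwork = en, hubReport = hubReport)
  if (!is.null(outDir))
    writePipelineOutputs(res, annotation, outDir,
                         threshold = config@exportThreshold)
  res
}

## write the stage outputs of a finished run into outDir
writePipelineOutputs <- function(res, annotation, outDir, threshold = 0.02) {
  writeExpression(res$expression, file.path(outDir, "filtered_expression.tsv"))
  writeTrait(res$trait, file.path(outDir, "filtered_trait.tsv"))
  utils::write.table(scanTable(res$scan),
                     file.path(outDir, "soft_threshold_scan.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  asn <- data.frame(gene_id = names(moduleLabels(res$assignment)),
                    module_label = unname(moduleLabels(res$assignment)),
                    module_color = unname(geneColors(res$assignment)))
  utils::write.table(asn, file.path(outDir, "module_assignment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$moduleTrait))
    utils::write.table(res$moduleTrait,
                       file.path(outDir, "module_trait.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$geneStats))
    utils::write.table(res$geneStats, file.path(outDir, "gene_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  for (m in res$significantModules) {
    net <- moduleNetwork(res$tom, res$assignment, m, threshold = threshold)
    writeCytoscapeNetwork(net, file.path(outDir, sprintf("edges-%s.tsv", m)),
                          file.path(outDir, sprintf("nodes-%s.tsv", m)),
                          annotation)
  }
  if (!is.null(res$hubReport))
    utils::write.table(hubGenes(res$hubReport),
                       file.path(outDir, "hub_genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outDir)
}
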